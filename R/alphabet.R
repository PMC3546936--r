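#' @title Nucleotide alphabet helpers
#' @description Sequences are handled internally in the DNA convention
#'   (`U` is folded into `T` on input); printed miRNA sequences can be
#'   converted back with [as_rna()]. `N` is allowed but never matches.
#' @name alphabet
NULL

.BASES <- c("A", "C", "G", "T")

#' Canonicalize a sequence to the internal DNA alphabet
#'
#' Upper-cases and replaces `U` with `T`. Errors on characters outside
#' `A,C,G,T,U,N`.
#'
#' @param x character vector of sequences
#' @return character vector over `A,C,G,T,N`
#' @export
as_dna <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid sequence character in: ", x[which(bad)[1L]])
  }
  x
}

#' Convert a DNA-convention sequence to RNA (`T` to `U`)
#' @param x character vector
#' @return character vector
#' @export
as_rna <- function(x) chartr("Tt", "Uu", as_dna(x))

#' Reverse complement
#'
#' Standard complement (`A<->T/U`, `C<->G`, `N` self), reversed. Output is
#' always in the DNA convention; applying it twice returns the input
#' (DNA-canonicalized).
#'
#' @param x character vector of sequences over `A,C,G,T,U,N`
#' @return character vector of reverse complements
#' @examples
#' reverse_complement("AACCGG")
#' @export
reverse_complement <- function(x) {
  x <- as_dna(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## uniform random sequence, used throughout the simulator
.random_seq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

## integer codes for vectorized window scans (A=1,C=2,G=3,T=4,N=0)
.seq_codes <- function(x) {
  chr <- strsplit(as_dna(x), "", fixed = TRUE)[[1L]]
  m <- match(chr, .BASES)
  m[is.na(m)] <- 0L
  m
}
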