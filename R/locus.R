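#' Format a genomic locus string
#'
#' Writes `ref:start.end:strand`, the coordinate style used in the
#' published novel-miRNA tables (1-based inclusive, forward-strand
#' coordinates).
#'
#' @param ref,start,end,strand locus components (vectorized)
#' @return character vector of locus strings
#' @export
format_locus <- function(ref, start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  sprintf("%s:%d.%d:%s", ref, as.integer(start), as.integer(end), strand)
}

#' Parse a locus string
#'
#' Inverse of [format_locus()]. Tolerates the typographic variants seen in
#' published tables: the unicode ratio colon, the unicode minus sign, and
#' stray spaces.
#'
#' @param x character vector of locus strings
#' @return data.frame `ref`, `start`, `end`, `strand`
#' @export
parse_locus <- function(x) {
  x <- gsub("∶", ":", x)
  x <- gsub("−", "-", x)
  x <- gsub("[[:space:]]", "", x)
  m <- regmatches(x, regexec("^(.*):([0-9]+)\\.([0-9]+):([+-])$", x))
  bad <- vapply(m, length, integer(1L)) != 5L
  if (any(bad)) stop("unparseable locus string: ", x[which(bad)[1L]])
  data.frame(ref = vapply(m, `[`, character(1L), 2L),
             start = as.integer(vapply(m, `[`, character(1L), 3L)),
             end = as.integer(vapply(m, `[`, character(1L), 4L)),
             strand = vapply(m, `[`, character(1L), 5L),
             stringsAsFactors = FALSE)
}

#' Convert loci to BED-style coordinates
#'
#' @param df data.frame with `ref`, `start`, `end`, `strand` (1-based
#'   inclusive)
#' @return data.frame `chrom`, `chromStart` (0-based), `chromEnd`
#'   (half-open), `strand`
#' @export
locus_to_bed <- function(df) {
  data.frame(chrom = df$ref, chromStart = df$start - 1L, chromEnd = df$end,
             strand = df$strand, stringsAsFactors = FALSE)
}

#' Read a published-style novel-miRNA table
#'
#' Parses a tab-separated table with columns `mirna`, `sequence`, `reads`,
#' `locus` (locus strings as in [format_locus()]); name whitespace is
#' normalized and the locus is expanded into coordinate columns.
#'
#' @param path path to the TSV
#' @return data.frame `mirna`, `sequence`, `reads`, `locus`, `ref`,
#'   `start`, `end`, `strand`
#' @export
read_mirna_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna", "sequence", "reads", "locus") %in% names(d)))
  d$mirna <- gsub("[[:space:]]", "", d$mirna)
  d$sequence <- tolower(gsub("[[:space:]]", "", d$sequence))
  loc <- parse_locus(d$locus)
  cbind(d, loc)
}

#' Path to a bundled example/reference data file
#'
#' @param file file name under the package's `extdata`; empty lists them
#' @return file path
#' @export
mirforge_example <- function(file = "") {
  system.file("extdata", file, package = "mirforge", mustWork = file != "")
}

#' Strip member suffixes to get a miRNA family name
#'
#' Drops a trailing `-5p`/`-3p` arm tag and then trailing letter suffixes,
#' so `miR-7563a`, `miR-7563b` and `miR-7563c` all fall into family
#' `miR-7563`, and `let-7a` into `let-7`.
#'
#' @param name character vector of miRNA names
#' @return character vector of family names
#' @export
mirna_family <- function(name) {
  x <- sub("-[35]p$", "", name)
  sub("(?<=[0-9])[a-z]+$", "", x, perl = TRUE)
}
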