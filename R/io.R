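#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads data.frame `id`, `seq`
#' @param path output path
#' @param qual constant per-base quality character
#' @return `path`, invisibly
#' @export
write_reads_fastq <- function(reads, path, qual = "I") {
  x <- Biostrings::DNAStringSet(as_dna(reads$seq))
  names(x) <- reads$id
  q <- Biostrings::BStringSet(strrep(qual, nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ/FASTA read file
#'
#' @param path input path
#' @param format `"fastq"` or `"fasta"`
#' @return data.frame `id`, `seq`
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(id = unname(sub("\\s.*$", "", names(x))),
             seq = unname(as.character(x)), stringsAsFactors = FALSE)
}

#' Write collapsed tags as FASTA with `tag{serial}_x{count}` headers
#'
#' @param tags data.frame `sequence`, `count`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tags_fasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a collapsed-tag FASTA written by [write_tags_fasta()]
#'
#' @param path input path
#' @return data.frame `sequence`, `count`
#' @export
read_tags_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  cnt <- as.integer(sub("^.*_x", "", names(x)))
  if (anyNA(cnt)) stop("headers must carry _x{count} suffixes")
  data.frame(sequence = unname(as.character(x)), count = cnt,
             stringsAsFactors = FALSE)
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(vapply(seqs, as_dna, character(1L)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA into a named character vector
#' @param path input path
#' @return named character vector
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
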