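#' Trim the 3' adapter from reads
#'
#' Returns, for each read, the subsequence preceding the leftmost position
#' where the read matches a prefix of the adapter of at least `min_overlap`
#' bases; the adapter may run off the read end. Matching is exact (no
#' mismatches), which keeps the stage deterministic. Reads without such an
#' occurrence are returned as `NA` (discarded downstream).
#'
#' @param seqs character vector of read sequences
#' @param adapter3 3' adapter sequence (at least 6 nt)
#' @param min_overlap minimum adapter prefix length that must match
#' @return character vector of inserts, `NA` where no adapter was found
#' @examples
#' trim_adapter("ACGTACGTACGTACGTTGGAATTC", "TGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adapter <- function(seqs, adapter3, min_overlap = 6L) {
  adapter3 <- as_dna(adapter3)
  if (nchar(adapter3) < 6L) {
    stop("configuration error: adapter3 shorter than 6 nt")
  }
  seqs <- as_dna(seqs)
  alen <- nchar(adapter3)
  probe <- substr(adapter3, 1L, min_overlap)
  # zero-width lookahead finds overlapping candidate positions too
  pat <- paste0("(?=", probe, ")")
  vapply(seqs, function(s) {
    len <- nchar(s)
    hits <- gregexpr(pat, s, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) return(NA_character_)
    for (i in hits) {
      k <- min(alen, len - i + 1L)
      if (substr(s, i, i + k - 1L) == substr(adapter3, 1L, k)) {
        return(substr(s, 1L, i - 1L))
      }
    }
    NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Length-filter and collapse trimmed inserts into unique tags
#'
#' Applies the clean-read definition: inserts must be adapter-trimmed,
#' N-free, of length `min_len`..`max_len`, and collapse into unique tags
#' with at least `min_copies` copies. The returned accounting partitions
#' the input reads exactly (`raw = clean + removed categories`).
#'
#' @param inserts character vector from [trim_adapter()] (`NA` = no adapter)
#' @param min_len,max_len inclusive insert length bounds
#' @param min_copies minimum copies for a tag to be kept
#' @param drop_n discard inserts containing `N` (they cannot take part in
#'   one-mismatch matching downstream)
#' @return list with `tags` (data.frame `sequence`, `count`, ordered by
#'   decreasing count then sequence) and `accounting` (one-row data.frame:
#'   `raw`, `no_adapter`, `n_base`, `length_filtered`, `low_copy`, `clean`)
#' @export
filter_and_collapse <- function(inserts, min_len = 15L, max_len = 26L,
                                min_copies = 2L, drop_n = TRUE) {
  if (min_len > max_len) stop("configuration error: min_len > max_len")
  raw <- length(inserts)
  no_adapter <- sum(is.na(inserts))
  x <- as_dna(inserts[!is.na(inserts)])
  n_base <- 0L
  if (drop_n) {
    has_n <- grepl("N", x, fixed = TRUE)
    n_base <- sum(has_n)
    x <- x[!has_n]
  }
  len <- nchar(x)
  in_range <- len >= min_len & len <= max_len
  length_filtered <- sum(!in_range)
  x <- x[in_range]
  tab <- table(x)
  keep <- tab >= min_copies
  low_copy <- sum(tab[!keep])
  tags <- data.frame(sequence = names(tab[keep]),
                     count = as.integer(tab[keep]),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  accounting <- data.frame(raw = raw, no_adapter = no_adapter,
                           n_base = n_base,
                           length_filtered = length_filtered,
                           low_copy = as.integer(low_copy),
                           clean = sum(tags$count))
  stopifnot(accounting$raw == accounting$clean + accounting$no_adapter +
              accounting$n_base + accounting$length_filtered +
              accounting$low_copy)
  list(tags = tags, accounting = accounting)
}

#' Read-weighted length distribution
#'
#' @param x a tag data.frame (`sequence`, `count`) or a character vector of
#'   reads (each counted once)
#' @return data.frame `length`, `reads`, `fraction` (fractions sum to 1)
#' @export
length_histogram <- function(x) {
  if (is.character(x)) {
    if (length(x) == 0L) stop("empty input")
    x <- data.frame(sequence = x, count = 1L)
  }
  if (nrow(x) == 0L) stop("empty input")
  len <- nchar(x$sequence)
  agg <- tapply(x$count, len, sum)
  out <- data.frame(length = as.integer(names(agg)),
                    reads = as.integer(agg))
  out$fraction <- out$reads / sum(out$reads)
  out[order(out$length), , drop = FALSE]
}

#' One-call preprocessing: trim, filter and collapse
#'
#' @param reads data.frame with a `seq` column (e.g. from
#'   [simulate_reads()]) or a character vector
#' @inheritParams trim_adapter
#' @inheritParams filter_and_collapse
#' @return as [filter_and_collapse()], plus `histogram`
#' @export
preprocess_reads <- function(reads, adapter3, min_len = 15L, max_len = 26L,
                             min_copies = 2L, min_overlap = 6L,
                             drop_n = TRUE) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) stop("empty read set")
  ins <- trim_adapter(seqs, adapter3, min_overlap = min_overlap)
  res <- filter_and_collapse(ins, min_len = min_len, max_len = max_len,
                             min_copies = min_copies, drop_n = drop_n)
  res$histogram <- if (nrow(res$tags) > 0L) length_histogram(res$tags) else NULL
  res
}
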