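## Shared substitution-only matching engine. Biostrings does the candidate
## search; the seed/strand bookkeeping implements the mapping rule.

## All ungapped occurrences of `tag` in `subject` (a Biostrings::DNAString)
## with at most max_mm substitutions; returns start, end and the mismatch
## positions in tag coordinates (5'->3' of the tag as read).
.tag_hits_strand <- function(tag, subject, max_mm, minus = FALSE) {
  pat <- if (minus) reverse_complement(tag) else tag
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                max.mismatch = max_mm, with.indels = FALSE)
  if (length(m) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  mmpos <- Biostrings::mismatch(Biostrings::DNAString(pat), m)
  L <- nchar(tag)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
             mismatches = lengths(mmpos),
             seed_pos = I(lapply(mmpos, function(p) {
               if (minus) L + 1L - p else p
             })))
}

.as_ref_list <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference)) || anyNA(names(reference))) {
    stop("reference sequences must be named")
  }
  lapply(reference, function(s) Biostrings::DNAString(as_dna(s)))
}

#' Map unique tags to reference sequences with seed-tolerant mismatches
#'
#' A locus is reported where the tag aligns ungapped, on either strand
#' (minus via reverse complement), with at most `seed_mm` substitutions
#' within its first `seed_len` bases (5'->3' of the tag) and at most
#' `total_mm` substitutions overall. All qualifying loci are reported;
#' tags with more than `max_loci` loci are flagged and truncated to the
#' first `max_loci` (ordered by reference, start, strand).
#'
#' @param tags data.frame (`sequence`, `count`) or character vector
#' @param reference named character vector or `DNAStringSet`
#' @param seed_len seed length (capped at the tag length)
#' @param seed_mm,total_mm allowed substitutions in seed / overall
#' @param max_loci per-tag locus cap
#' @return list with `mapped` (data.frame `tag`, `count`, `ref`, `start`,
#'   `end`, `strand`, `mismatches`; 1-based inclusive forward-strand
#'   coordinates), `unmapped` (tag data.frame) and `flagged` (tags over the
#'   locus cap)
#' @export
map_tags <- function(tags, reference, seed_len = 18L, seed_mm = 1L,
                     total_mm = 1L, max_loci = 10L) {
  if (is.character(tags)) tags <- data.frame(sequence = tags, count = 1L)
  if (length(reference) == 0L || sum(nchar(reference)) == 0L) {
    stop("reference is empty")
  }
  subjects <- .as_ref_list(reference)
  tags$sequence <- as_dna(tags$sequence)
  rows <- list(); ri <- 0L
  flagged <- character(0)
  mapped_tag <- logical(nrow(tags))
  for (ti in seq_len(nrow(tags))) {
    tag <- tags$sequence[ti]
    sl <- min(seed_len, nchar(tag))
    loci <- list(); li <- 0L
    for (rn in names(subjects)) {
      for (minus in c(FALSE, TRUE)) {
        h <- .tag_hits_strand(tag, subjects[[rn]], total_mm, minus)
        if (nrow(h) == 0L) next
        seed_bad <- vapply(h$seed_pos, function(p) sum(p <= sl), integer(1L))
        h <- h[seed_bad <= seed_mm, , drop = FALSE]
        if (nrow(h) == 0L) next
        li <- li + 1L
        loci[[li]] <- data.frame(tag = tag, count = tags$count[ti],
                                 ref = rn, start = h$start, end = h$end,
                                 strand = if (minus) "-" else "+",
                                 mismatches = h$mismatches,
                                 stringsAsFactors = FALSE)
      }
    }
    if (li == 0L) next
    loc <- do.call(rbind, loci)
    loc <- loc[order(loc$ref, loc$start, loc$strand), , drop = FALSE]
    if (nrow(loc) > max_loci) {
      flagged <- c(flagged, tag)
      loc <- loc[seq_len(max_loci), , drop = FALSE]
    }
    mapped_tag[ti] <- TRUE
    ri <- ri + 1L
    rows[[ri]] <- loc
  }
  mapped <- if (ri > 0L) do.call(rbind, rows) else
    data.frame(tag = character(0), count = integer(0), ref = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0))
  rownames(mapped) <- NULL
  list(mapped = mapped,
       unmapped = tags[!mapped_tag, , drop = FALSE],
       flagged = flagged)
}

#' Per-reference mapping distribution
#'
#' Counts unique tags and reads per reference; a tag with loci on several
#' references contributes once to each (so the column sums can exceed the
#' number of mapped tags).
#'
#' @param mapped the `mapped` data.frame from [map_tags()]
#' @return data.frame `ref`, `unique_tags`, `reads`
#' @export
distribution_by_reference <- function(mapped) {
  if (nrow(mapped) == 0L) {
    return(data.frame(ref = character(0), unique_tags = integer(0),
                      reads = integer(0)))
  }
  u <- unique(mapped[, c("tag", "count", "ref")])
  out <- do.call(rbind, lapply(split(u, u$ref), function(d) {
    data.frame(ref = d$ref[1L], unique_tags = nrow(d), reads = sum(d$count))
  }))
  rownames(out) <- NULL
  out[order(out$ref), , drop = FALSE]
}

#' Annotate and remove ncRNA contaminant tags
#'
#' A tag is removed when it occurs as a substring of a labelled reference
#' sequence (either strand) with at most `max_mismatch` substitutions.
#' The removed and retained sets partition the input exactly, by tag and by
#' copy count. A tag hitting several classes takes the class of its
#' fewest-mismatch hit; ties go to the fixed priority
#' rRNA > tRNA > snoRNA > snRNA > other.
#'
#' @param tags data.frame (`sequence`, `count`)
#' @param reference named sequences whose names end in `|class`
#' @param max_mismatch allowed substitutions
#' @return list with `removed` (data.frame `sequence`, `count`, `ref`,
#'   `class`, `mismatches`), `retained` (tag data.frame) and `class_counts`
#'   (copy-count-weighted reads and unique tags per class)
#' @export
annotate_ncrna <- function(tags, reference, max_mismatch = 1L) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference)) || !all(grepl("\\|", names(reference)))) {
    stop("ncRNA reference records must be labelled 'id|class'")
  }
  cls <- sub("^.*\\|", "", names(reference))
  known <- c("rRNA", "tRNA", "snoRNA", "snRNA")
  cls[!cls %in% known] <- "other"
  prio <- setNames(seq_along(c(known, "other")), c(known, "other"))
  subjects <- .as_ref_list(reference)
  tags$sequence <- as_dna(tags$sequence)

  hit_rows <- list(); hi <- 0L
  removed_idx <- logical(nrow(tags))
  for (ti in seq_len(nrow(tags))) {
    tag <- tags$sequence[ti]
    best <- NULL
    for (k in seq_along(subjects)) {
      for (minus in c(FALSE, TRUE)) {
        h <- .tag_hits_strand(tag, subjects[[k]], max_mismatch, minus)
        if (nrow(h) == 0L) next
        mm <- min(h$mismatches)
        cand <- list(ref = sub("\\|[^|]*$", "", names(reference)[k]),
                     class = cls[k], mm = mm)
        if (is.null(best) || cand$mm < best$mm ||
            (cand$mm == best$mm && prio[cand$class] < prio[best$class])) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) {
      removed_idx[ti] <- TRUE
      hi <- hi + 1L
      hit_rows[[hi]] <- data.frame(sequence = tag, count = tags$count[ti],
                                   ref = best$ref, class = best$class,
                                   mismatches = best$mm,
                                   stringsAsFactors = FALSE)
    }
  }
  removed <- if (hi > 0L) do.call(rbind, hit_rows) else
    data.frame(sequence = character(0), count = integer(0),
               ref = character(0), class = character(0),
               mismatches = integer(0))
  retained <- tags[!removed_idx, , drop = FALSE]
  rownames(retained) <- NULL
  cc <- if (nrow(removed) > 0L) {
    do.call(rbind, lapply(split(removed, removed$class), function(d) {
      data.frame(class = d$class[1L], unique_tags = nrow(d),
                 reads = sum(d$count))
    }))
  } else {
    data.frame(class = character(0), unique_tags = integer(0),
               reads = integer(0))
  }
  rownames(cc) <- NULL
  list(removed = removed, retained = retained, class_counts = cc)
}
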