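#' Predict a maximum-base-pair secondary structure
#'
#' Nussinov-style base-pair maximization over AU/GC/GU pairs with a minimum
#' hairpin loop of `min_loop` unpaired bases. Among all structures with the
#' maximal number of pairs, the one with the lowest [fold_energy()] (largest
#' weighted pair score) is chosen; remaining ties are resolved by a fixed
#' deterministic traceback, so the result is reproducible.
#'
#' @param seq a single sequence (DNA or RNA convention)
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#' @return list with `structure` (dot-bracket), `paired_bases` and `energy`
#'   (the weighted pair score, negated; lower means more stable)
#' @examples
#' predict_structure("GGGAAAUCCC")
#' @export
predict_structure <- function(seq, min_loop = 3) {
  stopifnot(length(seq) == 1L, min_loop >= 0)
  s <- as_dna(seq)
  res <- nussinov_cpp(s, as.integer(min_loop))
  list(structure = res$structure,
       paired_bases = res$pairs,
       energy = -res$weight)
}

#' Simplified folding free-energy score
#'
#' Scores a structure as `-(3 * GC + 2 * AU + 1 * GU)` over its paired
#' positions; lower values indicate a more stable fold. This weighted
#' pair-count score stands behind the same contract as a thermodynamic
#' engine, which can be slotted in without changing callers.
#'
#' @param seq a single sequence
#' @param structure dot-bracket string of the same length
#' @return numeric score (0 for an unpaired sequence)
#' @examples
#' fold_energy("GGGAAACCC", "(((...)))")
#' @export
fold_energy <- function(seq, structure) {
  s <- as_dna(seq)
  if (nchar(s) != nchar(structure)) {
    stop("sequence and structure lengths differ")
  }
  pr <- structure_pairs(structure)
  if (nrow(pr) == 0L) return(0)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  w <- vapply(seq_len(nrow(pr)), function(r) {
    .pair_weight_r(ch[pr[r, 1L]], ch[pr[r, 2L]])
  }, numeric(1L))
  -sum(w)
}

.pair_weight_r <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AT", "TA")) return(2)
  if (key %in% c("GT", "TG")) return(1)
  0  # non-canonical pair in a supplied structure scores nothing
}

#' Extract base pairs from a dot-bracket structure
#'
#' @param structure dot-bracket string
#' @return two-column integer matrix of paired positions (i < j)
#' @export
structure_pairs <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  open <- integer(0)
  out <- matrix(integer(0), ncol = 2L)
  rows <- vector("list", sum(ch == ")"))
  ri <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0L) stop("unbalanced dot-bracket structure")
      ri <- ri + 1L
      rows[[ri]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) stop("unbalanced dot-bracket structure")
  if (ri == 0L) return(out)
  do.call(rbind, rows[seq_len(ri)])
}
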