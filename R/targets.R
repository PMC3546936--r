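#' Antisense search for miRNA target sites
#'
#' Scans every mRNA position for ungapped duplexes with each mature miRNA:
#' a hit needs at most `max_mm` non-GU mismatches, at most `max_gu` GU
#' wobbles, and perfect Watson-Crick complementarity at miRNA seed
#' positions 2-8. All qualifying positions are reported with the
#' [duplex_score()]. When a CDS annotation is supplied the hit is labelled
#' 5'UTR / CDS / 3'UTR by its midpoint; otherwise `unannotated`.
#'
#' @param mirnas named character vector of mature sequences
#' @param mrnas named character vector (or `DNAStringSet`) of mRNAs
#' @param max_mm maximum non-GU mismatches
#' @param max_gu maximum GU wobbles
#' @param seed_positions miRNA positions that must pair Watson-Crick
#' @param regions optional data.frame `id`, `cds_start`, `cds_end`
#' @return data.frame `mirna`, `mrna`, `start`, `end`, `region`,
#'   `mismatches`, `gu_pairs`, `seed_perfect`, `duplex_score`
#' @export
antisense_search <- function(mirnas, mrnas, max_mm = 1L, max_gu = 2L,
                             seed_positions = 2:8, regions = NULL) {
  if (methods::is(mrnas, "DNAStringSet")) {
    mrnas <- setNames(as.character(mrnas), names(mrnas))
  }
  if (length(mrnas) == 0L) stop("mRNA set is empty")
  hits <- list(); hi <- 0L
  for (mn in names(mirnas)) {
    mi <- .seq_codes(mirnas[[mn]])
    L <- length(mi)
    sp <- seed_positions[seed_positions <= L]
    for (rn in names(mrnas)) {
      rc <- .seq_codes(mrnas[[rn]])
      nw <- length(rc) - L + 1L
      if (nw < 1L) next
      mm <- integer(nw); gu <- integer(nw); seed_bad <- integer(nw)
      for (p in seq_len(L)) {
        a <- mi[p]
        b <- rc[(L - p) + seq_len(nw)]          # mRNA base opposite miRNA p
        wc <- (a + b == 5L) & a != 0L           # A=1,C=2,G=3,T=4: WC sums to 5
        wob <- (a == 3L & b == 4L) | (a == 4L & b == 3L)
        mm <- mm + as.integer(!(wc | wob))
        gu <- gu + as.integer(wob)
        if (p %in% sp) seed_bad <- seed_bad + as.integer(!wc)
      }
      ok <- which(mm <= max_mm & gu <= max_gu & seed_bad == 0L)
      for (s in ok) {
        hi <- hi + 1L
        site <- substr(as_dna(mrnas[[rn]]), s, s + L - 1L)
        mid <- s + (L - 1L) / 2
        region <- "unannotated"
        if (!is.null(regions)) {
          rr <- regions[regions$id == rn, , drop = FALSE]
          if (nrow(rr) == 1L) {
            region <- if (mid < rr$cds_start) "5'UTR" else
              if (mid > rr$cds_end) "3'UTR" else "CDS"
          }
        }
        hits[[hi]] <- data.frame(
          mirna = mn, mrna = rn, start = s, end = s + L - 1L,
          region = region, mismatches = mm[s], gu_pairs = gu[s],
          seed_perfect = TRUE,
          duplex_score = duplex_score(mirnas[[mn]], site),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (hi > 0L) do.call(rbind, hits) else
    data.frame(mirna = character(0), mrna = character(0), start = integer(0),
               end = integer(0), region = character(0),
               mismatches = integer(0), gu_pairs = integer(0),
               seed_perfect = logical(0), duplex_score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Simplified miRNA:target duplex score
#'
#' `-(3*GC + 2*AU + 1*GU)` over complementary positions plus a +1 penalty
#' per mismatch; lower is more stable. miRNA position `p` faces site
#' position `L - p + 1` (both sequences 5'->3'). This documented score
#' stands behind the same contract as a nearest-neighbor energy engine.
#'
#' @param mirna mature miRNA sequence
#' @param site mRNA site sequence of the same length
#' @return numeric score
#' @examples
#' duplex_score("GGGGG", "CCCCC")  # five GC pairs: -15
#' @export
duplex_score <- function(mirna, site) {
  a <- .seq_codes(mirna)
  b <- .seq_codes(site)
  if (length(a) != length(b)) stop("site length must equal miRNA length")
  b <- rev(b)                      # antiparallel
  wc <- a + b == 5L & a != 0L
  wob <- (a == 3L & b == 4L) | (a == 4L & b == 3L)
  w <- ifelse(wc & (a %in% c(2L, 3L)), 3,    # G:C / C:G
              ifelse(wc, 2,                  # A:T / T:A
                     ifelse(wob, 1, 0)))
  sum(-w) + sum(!(wc | wob))
}

#' Summarize target hits per miRNA and per mRNA
#'
#' @param hits data.frame from [antisense_search()]
#' @return list with `per_mirna` (`mirna`, `n_targets`, `n_sites`) and
#'   `per_mrna` (`mrna`, `n_mirnas`, `n_sites`)
#' @export
aggregate_targets <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(per_mirna = data.frame(mirna = character(0),
                                       n_targets = integer(0),
                                       n_sites = integer(0)),
                per_mrna = data.frame(mrna = character(0),
                                      n_mirnas = integer(0),
                                      n_sites = integer(0))))
  }
  per_mirna <- do.call(rbind, lapply(split(hits, hits$mirna), function(d) {
    data.frame(mirna = d$mirna[1L], n_targets = length(unique(d$mrna)),
               n_sites = nrow(d), stringsAsFactors = FALSE)
  }))
  per_mrna <- do.call(rbind, lapply(split(hits, hits$mrna), function(d) {
    data.frame(mrna = d$mrna[1L], n_mirnas = length(unique(d$mirna)),
               n_sites = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per_mirna) <- rownames(per_mrna) <- NULL
  list(per_mirna = per_mirna, per_mrna = per_mrna)
}
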