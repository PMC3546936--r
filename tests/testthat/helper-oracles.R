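# Independent brute-force oracles. These deliberately re-derive each rule
# from scratch (different recurrences / plain position loops) so they can
# check the package implementations.

# maximum base pairs by memoized recursion decomposing on the LEFT end
# (the package DP decomposes on the right end)
oracle_nussinov_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(mirforge::as_dna(seq), "")[[1L]]
  n <- length(s)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    if (i + min_loop + 1L <= j) {
      for (k in (i + min_loop + 1L):j) {
        if (can_pair(s[i], s[k])) {
          v <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
          if (v > best) best <- v
        }
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# exhaustive all-window scan implementing the seed-tolerant mapping rule
# position by position; refs is a named character vector
oracle_map_scan <- function(tag, refs, seed_len = 18L, seed_mm = 1L,
                            total_mm = 1L) {
  tag <- mirforge::as_dna(tag)
  L <- nchar(tag)
  sl <- min(seed_len, L)
  tcode <- match(strsplit(tag, "")[[1L]], c("A", "C", "G", "T"))
  out <- list(); oi <- 0L
  for (rn in names(refs)) {
    for (strand in c("+", "-")) {
      rseq <- if (strand == "+") refs[[rn]] else
        mirforge::reverse_complement(refs[[rn]])
      rcode <- match(strsplit(mirforge::as_dna(rseq), "")[[1L]],
                     c("A", "C", "G", "T"))
      n <- length(rcode)
      if (n < L) next
      nw <- n - L + 1L
      tot <- integer(nw); sd_mm <- integer(nw)
      for (k in seq_len(L)) {
        neq <- rcode[k:(n - L + k)] != tcode[k]
        neq[is.na(neq)] <- TRUE
        tot <- tot + neq
        if (k <= sl) sd_mm <- sd_mm + neq
      }
      ok <- which(tot <= total_mm & sd_mm <= seed_mm)
      for (s in ok) {
        oi <- oi + 1L
        # convert minus-strand window position back to forward coordinates
        if (strand == "+") {
          st <- s; en <- s + L - 1L
        } else {
          en <- n - s + 1L; st <- en - L + 1L
        }
        out[[oi]] <- data.frame(tag = tag, ref = rn, start = st, end = en,
                                strand = strand, mismatches = tot[s],
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (oi == 0L) {
    return(data.frame(tag = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}

# exhaustive antisense scan: slide the miRNA over every mRNA position and
# classify each opposing base pair directly
oracle_antisense <- function(mirna, mrnas, max_mm = 1L, max_gu = 2L,
                             seed_positions = 2:8) {
  mirna <- mirforge::as_dna(mirna)
  mc <- strsplit(mirna, "")[[1L]]
  L <- length(mc)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list(); oi <- 0L
  for (rn in names(mrnas)) {
    rc <- strsplit(mirforge::as_dna(mrnas[[rn]]), "")[[1L]]
    if (length(rc) < L) next
    for (s in seq_len(length(rc) - L + 1L)) {
      mm <- 0L; gu <- 0L; seed_ok <- TRUE
      for (p in seq_len(L)) {
        b <- rc[s + L - p]
        wc <- identical(comp[[mc[p]]], b)
        wob <- (mc[p] == "G" && b == "T") || (mc[p] == "T" && b == "G")
        if (!wc && p %in% seed_positions) seed_ok <- FALSE
        if (wob) gu <- gu + 1L else if (!wc) mm <- mm + 1L
      }
      if (mm <= max_mm && gu <= max_gu && seed_ok) {
        oi <- oi + 1L
        out[[oi]] <- data.frame(mrna = rn, start = s, end = s + L - 1L,
                                mismatches = mm, gu_pairs = gu,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (oi == 0L) {
    return(data.frame(mrna = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      gu_pairs = integer(0)))
  }
  do.call(rbind, out)
}

# sliding-window ncRNA membership check with both strands
oracle_ncrna_hit <- function(tag, refs, max_mm = 1L) {
  nrow(oracle_map_scan(tag, refs, seed_len = nchar(tag),
                       seed_mm = max_mm, total_mm = max_mm)) > 0L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
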