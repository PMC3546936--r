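## a tiny hand-built precursor context for constructed examples:
## 10 nt flank, 20 nt mature, then a 'G' continuation
.mk_ctx <- function() {
  mature <- "ATCGATCGATTAGCATCGAT"
  ctx <- paste0("TTTTTCCCCC", mature, "GGGGG", "ACACAC")
  list(mature = mature, ctx = ctx, m1 = 11L)
}

test_that("canonical, tailed and shifted tags classify correctly", {
  x <- .mk_ctx()
  tags <- data.frame(
    sequence = c(x$mature,                         # canonical
                 paste0(x$mature, "A"),            # NTA (context has G)
                 substr(x$ctx, 12, 31),            # +1 5' shift (templated)
                 paste0(substr(x$mature, 1, 19), "C")),  # final-base change
    count = c(100L, 20L, 10L, 5L))
  recs <- classify_isomirs(tags, x$mature, x$ctx, x$m1)
  # the final-base change reads as a 1-nt tail on a trimmed end (minimal
  # substitution decomposition), i.e. shift + NTA = mixed
  expect_equal(recs$category,
               c("canonical", "NTA", "shift", "mixed"))
  expect_equal(recs$nta, c("", "A", "", "C"))
  expect_equal(recs$offset5, c(0L, 0L, 1L, 0L))
  expect_equal(recs$offset3[4], -1L)
  # counts conserved
  expect_equal(sum(recs$count), sum(tags$count))
})

test_that("a trailing mismatch followed by matches is a substitution", {
  x <- .mk_ctx()
  v <- x$mature
  substr(v, 17, 17) <- setdiff(c("A","C","G","T"), substr(v, 17, 17))[1]
  recs <- classify_isomirs(data.frame(sequence = v, count = 3L),
                           x$mature, x$ctx, x$m1)
  expect_equal(recs$category, "substitution")
  expect_equal(recs$n_subs, 1L)
  expect_match(recs$substitutions, "^17:")
})

test_that("unalignable tags are skipped with a warning", {
  x <- .mk_ctx()
  expect_warning(
    recs <- classify_isomirs(data.frame(sequence = random_dna(20),
                                        count = 1L),
                             x$mature, x$ctx, x$m1),
    "skipped")
  expect_equal(nrow(recs), 0L)
})

test_that("decomposition round-trips every simulated mature-arm tag", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors[1, ]
  tags <- truth_tags(fx$truth, pr$name, "mature")
  recs <- classify_isomirs(tags, pr$mature_seq, pr$context_seq,
                           pr$context_mature_start, parent = pr$name)
  expect_equal(sum(recs$count), sum(tags$count))
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    n <- nchar(r$sequence); t <- nchar(r$nta)
    templ <- substr(pr$context_seq, r$ctx_start, r$ctx_start + n - t - 1L)
    if (r$n_subs > 0) {
      for (sub in strsplit(r$substitutions, ";")[[1]]) {
        p <- regmatches(sub, regexec("^([0-9]+):(.)>(.)$", sub))[[1]]
        pos <- as.integer(p[2]) - r$offset5   # back to read coordinates
        expect_equal(substr(templ, pos, pos), p[3])
        substr(templ, pos, pos) <- p[4]
      }
    }
    expect_identical(paste0(templ, r$nta), r$sequence)
  }
})

test_that("planted edit rates are recovered within 3 SE", {
  fx <- sim_fixture(42)  # substitution_rate .05, nta_rate .10
  pr <- fx$sim$precursors
  recs <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
    classify_isomirs(truth_tags(fx$truth, pr$name[i], "mature"),
                     pr$mature_seq[i], pr$context_seq[i],
                     pr$context_mature_start[i], parent = pr$name[i])
  }))
  n <- sum(recs$count)
  expect_gte(n, 5000)
  sub_rate <- sum(recs$count[recs$n_subs > 0]) / n
  p <- fx$cfg$substitution_rate
  expect_lt(abs(sub_rate - p), 3 * sqrt(p * (1 - p) / n))
  nta_rate <- sum(recs$count[nchar(recs$nta) > 0]) / n
  q <- fx$cfg$nta_rate
  expect_lt(abs(nta_rate - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("tail base composition is recovered within 3 SE (multinomial)", {
  w <- c(A = 0.6, C = 0.1, G = 0, U = 0.3)
  fx <- sim_fixture(55, nta_rate = 1, nta_base_weights = w,
                    substitution_rate = 0, n_reads = 8000)
  pr <- fx$sim$precursors
  recs <- do.call(rbind, lapply(seq_len(nrow(pr)), function(i) {
    classify_isomirs(truth_tags(fx$truth, pr$name[i], "mature"),
                     pr$mature_seq[i], pr$context_seq[i],
                     pr$context_mature_start[i])
  }))
  bc <- nta_base_counts(recs)
  n <- sum(bc$reads)
  expect_gte(n, 5000)
  for (b in c("A", "C", "U")) {
    ph <- bc$read_fraction[bc$base == b]
    pw <- w[[b]]
    expect_lt(abs(ph - pw), 3 * sqrt(pw * (1 - pw) / n))
  }
  expect_equal(bc$reads[bc$base == "G"], 0)
})

test_that("substitution spectrum sums to one over observed classes", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors[1, ]
  recs <- classify_isomirs(truth_tags(fx$truth, pr$name, "mature"),
                           pr$mature_seq, pr$context_seq,
                           pr$context_mature_start)
  sp <- substitution_spectrum(recs)
  expect_equal(nrow(sp), 12L)
  expect_equal(sum(sp$read_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(sp$tag_fraction), 1, tolerance = 1e-12)
})

test_that("dominant cleavage sites follow the read-weighted mode", {
  recs <- data.frame(offset5 = c(0L, 1L), offset3 = c(0L, 0L),
                     count = c(100L, 5L), nta = "", n_subs = 0L)
  cs <- infer_cleavage_sites(recs)
  expect_equal(cs$dominant5, 0L)
  expect_equal(cs$dominant3, 0L)
  # planted +1-shift majority moves the dominant 5' site
  fx <- sim_fixture(66, end_shift_probs = c(`-2` = 0, `-1` = 0, `0` = 0.2,
                                            `1` = 0.8, `2` = 0),
                    substitution_rate = 0, nta_rate = 0, n_reads = 3000)
  pr <- fx$sim$precursors[1, ]
  recs2 <- classify_isomirs(truth_tags(fx$truth, pr$name, "mature"),
                            pr$mature_seq, pr$context_seq,
                            pr$context_mature_start)
  cs2 <- infer_cleavage_sites(recs2)
  expect_equal(cs2$dominant5, 1L)
  expect_equal(cs2$dominant3, 1L)
  expect_error(infer_cleavage_sites(recs2[0, ]), "no isomiR")
})

test_that("star detection finds planted duplexes with 2-nt overhangs", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors[fx$sim$precursors$status == "novel", ]
  found <- 0L
  for (i in seq_len(nrow(pr))) {
    fs <- predict_structure(pr$precursor_seq[i])
    hp <- list(precursor = pr$precursor_seq[i], structure = fs$structure,
               mature_start = pr$loc_mature_start[i],
               mature_end = pr$loc_mature_end[i])
    st <- detect_star(hp, truth_tags(fx$truth, pr$name[i]))
    if (is.null(st)) next
    found <- found + 1L
    expect_equal(unname(st$overhangs), c(2, 2))
    expect_equal(st$mature, pr$mature_seq[i])
    expect_equal(st$star, pr$star_seq[i])
    expect_false(st$star_dominant)
  }
  expect_gte(found, 4L)  # star reads may be absent for a weak precursor
  # no reads on the opposite arm: no duplex
  one <- pr[1, ]
  fs <- predict_structure(one$precursor_seq)
  hp <- list(precursor = one$precursor_seq, structure = fs$structure,
             mature_start = one$loc_mature_start,
             mature_end = one$loc_mature_end)
  expect_null(detect_star(hp, truth_tags(fx$truth, one$name, "mature")))
  # star-dominant flag from raw counts
  st2 <- detect_star(hp, data.frame(sequence = c(one$mature_seq,
                                                 one$star_seq),
                                    count = c(100L, 150L)))
  expect_equal(st2$ratio, 1.5)
  expect_true(st2$star_dominant)
})

test_that("seed conservation scores identity over aligned columns", {
  s <- c(ref = "TGAGGTAGTAGGTTGTATAGTT")
  same <- c(s, a = s[[1]], b = s[[1]])
  res <- seed_conservation(same)
  expect_true(all(res$profile$identity == 1))
  expect_equal(res$seed_identity, 1)
  # changes outside the seed leave seed identity at 1
  v <- s[[1]]
  substr(v, 15, 15) <- "C"; substr(v, 20, 20) <- "A"
  res2 <- seed_conservation(c(s, v = v))
  expect_equal(res2$seed_identity, 1)
  expect_lt(mean(res2$profile$identity), 1)
  # two seed mutations in one of four sequences: hand-counted identity
  w <- s[[1]]
  substr(w, 3, 3) <- "C"; substr(w, 5, 5) <- "A"
  res3 <- seed_conservation(c(s, a = s[[1]], b = s[[1]], w = w))
  expect_equal(res3$seed_identity, (5 * 1 + 2 * (2 / 3)) / 7,
               tolerance = 1e-12)
  expect_error(seed_conservation(s), "two sequences")
})
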