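test_that("configuration invariants are enforced", {
  expect_error(sim_config(substitution_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(nta_base_weights = c(A = 0.5, C = 0.5, G = 0.5,
                                               U = 0.5)), "sum to 1")
  expect_error(sim_config(length_range = c(10, 26)), "16, 30")
  expect_error(sim_config(adapter3 = "ACGT"), "adapter3")
  expect_error(sim_config(n_precursors = 10, genome_len = 1000), "genome_len")
})

test_that("an empty configuration yields a genome with no planted hairpins", {
  cfg <- sim_config(seed = 5, n_precursors = 0, n_catalogue = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$precursors), 0L)
  expect_equal(sum(nchar(sim$genome)), cfg$genome_len)
})

test_that("every planted precursor folds with >= 18 pairs (DP oracle)", {
  fx <- sim_fixture(42)
  expect_equal(nrow(fx$sim$precursors), 8L)  # 5 novel + 3 catalogue
  for (s in fx$sim$precursors$precursor_seq) {
    expect_lte(nchar(s), 60L)
    expect_gte(oracle_nussinov_pairs(s), 18L)
  }
})

test_that("planted mature arms are recoverable from the genome", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors
  for (i in seq_len(nrow(pr))) {
    refs <- if (pr$source[i] == "genome") fx$sim$genome else fx$sim$est
    g <- substr(refs[[pr$ref[i]]], pr$start[i], pr$end[i])
    if (pr$strand[i] == "-") g <- reverse_complement(g)
    expect_identical(g, pr$precursor_seq[i])
    expect_identical(substr(pr$precursor_seq[i], pr$loc_mature_start[i],
                            pr$loc_mature_end[i]), pr$mature_seq[i])
  }
})

test_that("catalogue family members are relatives sharing their seed", {
  fx <- sim_fixture(42)
  cat_rows <- fx$sim$precursors[fx$sim$precursors$status == "catalogue", ]
  fam <- split(cat_rows$mature_seq, mirna_family(cat_rows$name))
  multi <- fam[lengths(fam) > 1]
  expect_gte(length(multi), 1L)
  for (m in multi) {
    expect_equal(length(unique(substr(m, 2, 8))), 1L)   # shared seed
    expect_gt(length(unique(m)), 1L)                    # but not identical
  }
})

test_that("identical seeds give byte-identical simulations", {
  cfg <- sim_config(seed = 9, n_reads = 500)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(a, b)
  ra <- simulate_reads(a); rb <- simulate_reads(b)
  expect_identical(ra, rb)
})

test_that("read provenance partitions the read set", {
  fx <- sim_fixture(42)
  expect_equal(nrow(fx$truth), fx$cfg$n_reads)
  expect_true(all(table(fx$truth$category) > 0))
  expect_equal(sum(table(fx$truth$category)), fx$cfg$n_reads)
  expect_false(anyNA(fx$truth$insert))
})

test_that("degenerate edit rates give exact canonical reads", {
  fx <- sim_fixture(11, substitution_rate = 0, nta_rate = 0,
                    end_shift_probs = c(`-2` = 0, `-1` = 0, `0` = 1,
                                        `1` = 0, `2` = 0),
                    n_reads = 1000)
  tr <- fx$truth[fx$truth$category == "precursor", ]
  pr <- fx$sim$precursors
  canon <- ifelse(tr$arm == "mature",
                  pr$mature_seq[match(tr$precursor, pr$name)],
                  pr$star_seq[match(tr$precursor, pr$name)])
  expect_identical(tr$insert, canon)
})

test_that("a forced A-tail appears on every precursor-derived read", {
  fx <- sim_fixture(12, nta_rate = 1,
                    nta_base_weights = c(A = 1, C = 0, G = 0, U = 0),
                    n_reads = 800)
  tr <- fx$truth[fx$truth$category == "precursor", ]
  expect_true(all(nchar(tr$nta) >= 1))
  expect_true(all(grepl("^A+$", tr$nta)))
  expect_true(all(substr(tr$insert, nchar(tr$insert), nchar(tr$insert)) == "A"))
})

test_that("realized substitution frequency is within 3 binomial SE", {
  fx <- sim_fixture(42)  # substitution_rate 0.05, n_reads 10000
  tr <- fx$truth[fx$truth$category == "precursor", ]
  p <- fx$cfg$substitution_rate
  phat <- mean(!is.na(tr$sub_pos))
  se <- sqrt(p * (1 - p) / nrow(tr))
  expect_lt(abs(phat - p), 3 * se)
})

test_that("planted 3' tails are non-templated by construction", {
  # guaranteed for non-trimmed 3' ends, where the continuation is the
  # zero-weight base planted after each arm; a tail over a trimmed end sits
  # against arm sequence and can coincide with it (inherent ambiguity)
  fx <- sim_fixture(42)
  tr <- fx$truth[fx$truth$category == "precursor" & nchar(fx$truth$nta) > 0 &
                   fx$truth$offset3 >= 0, ]
  pr <- fx$sim$precursors
  for (i in seq_len(nrow(tr))) {
    row <- pr[pr$name == tr$precursor[i], ]
    a1 <- if (tr$arm[i] == "mature") row$context_mature_start else
      row$context_star_start
    first_tail_pos <- a1 + tr$offset5[i] +
      (nchar(tr$insert[i]) - nchar(tr$nta[i]))
    cont <- substr(row$context_seq, first_tail_pos, first_tail_pos)
    expect_false(substr(tr$nta[i], 1, 1) == cont)
  }
})

test_that("Ct simulation honours planted effects exactly at zero noise", {
  cfg <- sim_config(seed = 3, ct_noise_sd = 0)
  one <- simulate_ct_table("m1", tissues = "liver", config = cfg,
                           delta_ct = matrix(0, 1, 1))
  ct5 <- one$ct$ct[one$ct$mirna == "5S_rRNA"]
  ctm <- one$ct$ct[one$ct$mirna == "m1"]
  expect_equal(ctm, ct5)
  three <- simulate_ct_table("m1", tissues = "liver", config = cfg,
                             delta_ct = matrix(3, 1, 1))
  expect_equal(unname(relative_expression(three$ct)[1, 1]), 0.125)
})

test_that("the Ct table has the full profiling dimensions", {
  cfg <- sim_config(seed = 4)
  res <- simulate_ct_table(sprintf("novel-mir-%d", 1:45), config = cfg)
  expect_equal(length(unique(res$ct$tissue)), 10L)
  expect_equal(length(setdiff(unique(res$ct$mirna), "5S_rRNA")), 45L)
  expect_equal(nrow(res$ct), 10L * 3L * 46L)
  expect_equal(dim(res$truth$delta_ct), c(45L, 10L))
})
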