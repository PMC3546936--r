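test_that("conserved calling matches tags to catalogue matures", {
  set.seed(3)
  cat <- c(`ipu-let-7a` = random_dna(22), `ipu-let-7b` = random_dna(22),
           `ipu-miR-9` = random_dna(21))
  mut <- function(x, i) {
    substr(x, i, i) <- setdiff(c("A","C","G","T"), substr(x, i, i))[1]
    x
  }
  tags <- data.frame(
    sequence = c(cat[[1]],                        # identical
                 mut(cat[[2]], 5),                # one substitution
                 substr(cat[[3]], 2, 21),         # end-shifted isomiR
                 mut(mut(random_dna(22), 1), 2)), # unrelated
    count = c(50L, 10L, 8L, 6L))
  res <- call_conserved(tags, cat)
  expect_setequal(res$calls$name, names(cat))
  expect_equal(res$calls$status, rep("conserved", 3))
  expect_equal(nrow(res$leftover), 1L)
  # family aggregation: let-7a/b fold into one family
  fam <- setNames(res$families$members, res$families$family)
  expect_equal(fam[["ipu-let-7"]], 2L)
  expect_equal(fam[["ipu-miR-9"]], 1L)
  # two substitutions against everything stays leftover
  t2 <- mut(mut(cat[[1]], 4), 9)
  res2 <- call_conserved(data.frame(sequence = t2, count = 3L), cat)
  expect_equal(nrow(res2$calls), 0L)
  expect_equal(nrow(res2$leftover), 1L)
  expect_error(call_conserved(tags, setNames(cat, c("a", "a", "b"))),
               "duplicate")
})

test_that("the most abundant qualifying tag becomes the call sequence", {
  set.seed(4)
  m <- random_dna(22)
  v <- m; substr(v, 6, 6) <- setdiff(c("A","C","G","T"), substr(v, 6, 6))[1]
  res <- call_conserved(data.frame(sequence = c(m, v), count = c(10L, 90L)),
                        c(mirX = m))
  expect_equal(res$calls$mature, v)
  expect_equal(res$calls$reads, 100L)
})

test_that("planted hairpins pass excision and random windows do not", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors[fx$sim$precursors$source == "genome", ]
  for (i in seq_len(nrow(pr))) {
    if (pr$strand[i] == "+") {
      g1 <- pr$start[i] + pr$loc_mature_start[i] - 1L
      g2 <- pr$start[i] + pr$loc_mature_end[i] - 1L
    } else {
      g1 <- pr$end[i] - pr$loc_mature_end[i] + 1L
      g2 <- pr$end[i] - pr$loc_mature_start[i] + 1L
    }
    cand <- excise_and_fold(fx$sim$genome, pr$ref[i], g1, g2, pr$strand[i])
    expect_false(is.null(cand))
    expect_gte(cand$paired_bases, 18L)
    expect_lte(cand$energy, -25)
  }
  # a tag inside an unstructured window folds below threshold: no candidate
  flat <- c(flat = paste0(strrep("A", 70), strrep("ACA", 8), strrep("A", 70)))
  expect_null(excise_and_fold(flat, "flat", 71, 94))
  expect_error(excise_and_fold(flat, "flat", 71, 94, flank = 10), "flank")
})

test_that("novel calling recovers all planted precursors exactly", {
  fx <- sim_fixture(42)
  pp <- preprocess_reads(fx$reads, fx$cfg$adapter3)
  ann <- annotate_ncrna(pp$tags, fx$sim$ncrna)
  cons <- call_conserved(ann$retained, fx$sim$catalogue)
  nov <- call_novel(cons$leftover, fx$sim$genome, fx$sim$est,
                    known_matures = fx$sim$catalogue)
  truth <- fx$sim$precursors[fx$sim$precursors$status == "novel", ]
  expect_equal(nrow(nov$calls), nrow(truth))
  loc <- parse_locus(nov$calls$locus)
  hit <- function(i) any(loc$ref == truth$ref[i] &
                           loc$start <= truth$end[i] &
                           loc$end >= truth$start[i])
  expect_true(all(vapply(seq_len(nrow(truth)), hit, logical(1))))
  # each call's mature is a planted arm sequence
  expect_true(all(nov$calls$mature %in% c(truth$mature_seq, truth$star_seq)))
  # conserved and novel tag sets are disjoint
  expect_length(intersect(cons$assignments$tag,
                          unlist(lapply(nov$details,
                                        function(d) d$members$sequence))), 0L)
  # serial naming follows descending read count
  expect_equal(nov$calls$reads, sort(nov$calls$reads, decreasing = TRUE))
  expect_equal(nov$calls$name, sprintf("novel-mir-%d", seq_len(nrow(nov$calls))))
})

test_that("tags mapping nowhere yield no novel calls", {
  set.seed(11)
  g <- c(chr = random_dna(3000))
  res <- call_novel(data.frame(sequence = random_dna(22), count = 5L), g)
  expect_equal(nrow(res$calls), 0L)
})

test_that("tags on both arms of one precursor merge into one call", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors[fx$sim$precursors$status == "novel", ][1, ]
  tags <- data.frame(sequence = c(pr$mature_seq, pr$star_seq),
                     count = c(30L, 5L))
  res <- call_novel(tags, fx$sim$genome)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$mature, pr$mature_seq)
  expect_equal(res$calls$reads, 35L)
  expect_equal(res$calls$n_tags, 2L)
})

test_that("EST/GSS references recover precursors absent from the genome", {
  fx <- sim_fixture(77, n_est_precursors = 2, n_reads = 4000)
  truth <- fx$sim$precursors
  est_truth <- truth[truth$source == "est", ]
  tags <- data.frame(sequence = est_truth$mature_seq, count = 10L)
  res <- call_novel(tags, fx$sim$genome, fx$sim$est)
  expect_equal(nrow(res$calls), 2L)
  expect_true(all(res$calls$source == "EST/GSS"))
  expect_true(all(parse_locus(res$calls$locus)$ref %in% est_truth$ref))
})
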