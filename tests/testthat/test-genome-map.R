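test_that("reverse complement is correct and involutive", {
  expect_identical(reverse_complement("AACCGG"), "CCGGTT")
  expect_identical(reverse_complement("UGGCUCAGUUCAGCAGGAAC"),
                   "GTTCCTGCTGAACTGAGCCA")
  set.seed(2)
  for (i in 1:20) {
    x <- random_dna(sample(10:40, 1))
    expect_identical(reverse_complement(reverse_complement(x)), x)
    # cross-check against Biostrings
    expect_identical(
      reverse_complement(x),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))))
  }
  expect_error(reverse_complement("ACGX"), "invalid")
})

test_that("exact and near-exact tags map to their planted loci", {
  set.seed(5)
  g <- c(chrA = random_dna(2000))
  tag <- substr(g[[1]], 500, 521)
  res <- map_tags(tag, g)
  expect_equal(nrow(res$mapped), 1L)
  expect_equal(res$mapped$start, 500L)
  expect_equal(res$mapped$end, 521L)
  expect_equal(res$mapped$strand, "+")
  expect_equal(res$mapped$mismatches, 0L)
  # minus strand via reverse complement
  res2 <- map_tags(reverse_complement(tag), g)
  expect_equal(res2$mapped$strand, "-")
  expect_equal(res2$mapped$start, 500L)
  # two substitutions: unmapped
  bad <- tag
  substr(bad, 2, 2) <- setdiff(c("A","C","G","T"), substr(bad, 2, 2))[1]
  substr(bad, 21, 21) <- setdiff(c("A","C","G","T"), substr(bad, 21, 21))[1]
  res3 <- map_tags(bad, g)
  expect_equal(nrow(res3$mapped), 0L)
  expect_equal(nrow(res3$unmapped), 1L)
})

test_that("the seed rule distinguishes seed from tail mismatches", {
  set.seed(6)
  g <- c(chrA = random_dna(1000))
  tag <- substr(g[[1]], 300, 323)  # 24 nt
  mut <- function(x, i) {
    substr(x, i, i) <- setdiff(c("A","C","G","T"), substr(x, i, i))[1]
    x
  }
  # two mismatches beyond the 18-nt seed: rejected when total_mm = 1,
  # accepted when total_mm = 2 (seed still clean)
  t2 <- mut(mut(tag, 20), 23)
  expect_equal(nrow(map_tags(t2, g)$mapped), 0L)
  expect_equal(nrow(map_tags(t2, g, total_mm = 2)$mapped), 1L)
  # two mismatches inside the seed: rejected even with total_mm = 2
  t3 <- mut(mut(tag, 3), 10)
  expect_equal(nrow(map_tags(t3, g, total_mm = 2)$mapped), 0L)
})

test_that("mapping equals the exhaustive window scan on random tags", {
  set.seed(8)
  g <- c(chr1 = random_dna(4000), chr2 = random_dna(3000))
  mut1 <- function(x) {
    i <- sample(nchar(x), 1)
    substr(x, i, i) <- sample(setdiff(c("A","C","G","T"),
                                      substr(x, i, i)), 1)
    x
  }
  tags <- c(
    vapply(1:10, function(i) {
      s <- sample(3800, 1); substr(g[[1]], s, s + sample(19:25, 1))
    }, character(1)),
    vapply(1:10, function(i) {
      s <- sample(2800, 1)
      mut1(substr(g[[2]], s, s + sample(19:25, 1)))
    }, character(1)),
    vapply(1:10, function(i) {
      s <- sample(2800, 1)
      reverse_complement(substr(g[[2]], s, s + sample(19:25, 1)))
    }, character(1)),
    vapply(1:10, function(i) random_dna(22), character(1)))
  res <- map_tags(data.frame(sequence = tags, count = 1L), g,
                  max_loci = 1000L)
  got <- res$mapped[order(res$mapped$tag, res$mapped$ref, res$mapped$start,
                          res$mapped$strand),
                    c("tag", "ref", "start", "end", "strand", "mismatches")]
  want <- do.call(rbind, lapply(unique(tags), oracle_map_scan, refs = g))
  want <- want[order(want$tag, want$ref, want$start, want$strand), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("strand symmetry: mapping rc(tag) swaps strands only", {
  set.seed(9)
  g <- c(chr = random_dna(1500))
  tag <- substr(g[[1]], 700, 721)
  a <- map_tags(tag, g)$mapped
  b <- map_tags(reverse_complement(tag), g)$mapped
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_setequal(c(a$strand, b$strand), c("+", "-"))
})

test_that("locus strings round-trip and convert to BED exactly", {
  df <- data.frame(ref = c("2", "gi|204069919|gb|FD326800.1|FD326800"),
                   start = c(33623651L, 128L), end = c(33623708L, 187L),
                   strand = c("+", "-"))
  s <- format_locus(df$ref, df$start, df$end, df$strand)
  expect_equal(parse_locus(s), df)
  # tolerant of published typography
  expect_equal(parse_locus("24∶10720304.10720362: −")$strand, "-")
  bed <- locus_to_bed(df)
  expect_equal(bed$chromStart, df$start - 1L)
  expect_equal(bed$chromEnd, df$end)
})

test_that("per-reference distribution matches planted chromosome counts", {
  fx <- sim_fixture(42)
  pr <- fx$sim$precursors[fx$sim$precursors$source == "genome", ]
  tags <- data.frame(sequence = pr$mature_seq, count = 2L)
  res <- map_tags(tags, fx$sim$genome)
  dist <- distribution_by_reference(res$mapped)
  # every planted chromosome appears, and the unique-tag total is at least
  # the number of distinct matures (multi-mapping counts once per reference)
  expect_true(all(unique(pr$ref) %in% dist$ref))
  expect_gte(sum(dist$unique_tags), length(unique(pr$mature_seq)))
  expect_error(map_tags(tags, character(0)), "empty")
})
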