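# Shared synthetic fixtures, built once per test run and memoized, so the
# heavier end-to-end objects are not regenerated in every test file.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function(seed = 101L, ...) {
  key <- paste0("sim_", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(seed = seed, ...)
    sim <- simulate_genome(cfg)
    reads <- simulate_reads(sim)
    .fixture_env[[key]] <- list(cfg = cfg, sim = sim, reads = reads$reads,
                                truth = reads$truth)
  }
  .fixture_env[[key]]
}

# collapse truth inserts of one precursor/arm into a tag table
truth_tags <- function(truth, precursor = NULL, arm = NULL) {
  d <- truth[truth$category == "precursor", , drop = FALSE]
  if (!is.null(precursor)) d <- d[d$precursor == precursor, , drop = FALSE]
  if (!is.null(arm)) d <- d[d$arm == arm, , drop = FALSE]
  tab <- table(d$insert)
  data.frame(sequence = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
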