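#' Staged read-accounting table
#'
#' Builds the pipeline summary in the canonical reporting order (raw ->
#' unique -> clean -> ncRNA-removed -> retained -> mapped -> calls).
#' `retained` is always derived from the two upstream stages as
#' `clean - ncrna_removed`.
#'
#' @param raw raw read count
#' @param unique_tags unique sequences among raw reads
#' @param clean clean reads after trimming/length/copy filters
#' @param ncrna_removed reads removed as rRNA/tRNA/snoRNA/snRNA
#' @param mapped_reads,mapped_unique reads / unique tags mapped
#' @param conserved,novel call counts
#' @return data.frame `stage`, `value` (NA rows dropped)
#' @export
accounting_table <- function(raw = NA, unique_tags = NA, clean = NA,
                             ncrna_removed = NA, mapped_reads = NA,
                             mapped_unique = NA, conserved = NA, novel = NA) {
  retained <- if (!is.na(clean) && !is.na(ncrna_removed)) {
    clean - ncrna_removed
  } else {
    NA
  }
  out <- data.frame(
    stage = c("raw_reads", "unique_tags", "clean_reads",
              "ncrna_removed_reads", "retained_reads", "mapped_reads",
              "mapped_unique_tags", "conserved_mirnas", "novel_mirnas"),
    value = c(raw, unique_tags, clean, ncrna_removed, retained,
              mapped_reads, mapped_unique, conserved, novel))
  out[!is.na(out$value), , drop = FALSE]
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full small-RNA analysis pipeline
#'
#' Orchestrates preprocess -> ncRNA annotation -> conserved calling ->
#' novel calling (genome, then EST/GSS) -> isomiR and miRNA* analysis per
#' novel precursor, plus optional expression profiling (when a Ct table is
#' given) and target prediction (when mRNAs are given). Any stage error
#' aborts with the stage name; results computed so far are attached to the
#' error condition's `partial` field.
#'
#' @param reads data.frame (`id`, `seq`) or a FASTQ path
#' @param adapter3 3' adapter sequence
#' @param ncrna_ref labelled ncRNA reference (`id|class` names)
#' @param genome named genome sequences
#' @param est optional EST/GSS contigs
#' @param known_matures optional named mature catalogue
#' @param ct optional Ct table (see [relative_expression()])
#' @param mrnas optional mRNA set for target prediction
#' @param params named list overriding stage parameters (`min_len`,
#'   `max_len`, `min_copies`, `max_mismatch`, `seed_len`, `seed_mm`,
#'   `total_mm`, `flank`, `min_pairs`, `energy_threshold`,
#'   `specificity_threshold`, `max_mm_target`, `max_gu`)
#' @return list with `tags`, `preprocess_accounting`, `annotation`,
#'   `conserved`, `novel`, `isomirs`, `duplexes`, `expression`,
#'   `specificity`, `targets` and the ordered `accounting` table
#' @export
run_pipeline <- function(reads, adapter3, ncrna_ref, genome, est = NULL,
                         known_matures = NULL, ct = NULL, mrnas = NULL,
                         params = list()) {
  p <- modifyList(list(min_len = 15L, max_len = 26L, min_copies = 2L,
                       max_mismatch = 1L, seed_len = 18L, seed_mm = 1L,
                       total_mm = 1L, flank = 70L, min_pairs = 18L,
                       energy_threshold = -25, specificity_threshold = 0.5,
                       max_mm_target = 1L, max_gu = 2L), params)
  if (is.character(reads) && length(reads) == 1L) reads <- read_reads(reads)

  pre <- .stage("preprocess", {
    if (NROW(reads) == 0L) stop("empty read file")
    preprocess_reads(reads, adapter3, min_len = p$min_len,
                     max_len = p$max_len, min_copies = p$min_copies)
  })
  n_unique_raw <- length(unique(if (is.data.frame(reads)) reads$seq else reads))

  ann <- .stage("annotate", {
    annotate_ncrna(pre$tags, ncrna_ref, max_mismatch = p$max_mismatch)
  })

  cons <- .stage("conserved", {
    if (is.null(known_matures) || length(known_matures) == 0L) {
      list(calls = data.frame(), families = data.frame(),
           leftover = ann$retained, assignments = data.frame())
    } else {
      call_conserved(ann$retained, known_matures)
    }
  })

  nov <- .stage("novel", {
    call_novel(cons$leftover, genome, est, known_matures = known_matures,
               seed_len = p$seed_len, seed_mm = p$seed_mm,
               total_mm = p$total_mm, flank = p$flank,
               min_pairs = p$min_pairs,
               energy_threshold = p$energy_threshold)
  })

  iso <- .stage("isomir", {
    out <- list()
    for (nm in names(nov$details)) {
      det <- nov$details[[nm]]
      cand <- det$candidate
      mature <- nov$calls$mature[nov$calls$name == nm]
      recs <- suppressWarnings(classify_isomirs(
        det$members, mature, cand$precursor, cand$mature_start, parent = nm))
      star <- detect_star(cand, det$members)
      out[[nm]] <- list(records = recs, star = star)
    }
    out
  })
  isomirs <- do.call(rbind, c(lapply(iso, `[[`, "records"),
                              list(make.row.names = FALSE)))
  duplexes <- Filter(Negate(is.null), lapply(iso, `[[`, "star"))

  mapped_reads <- sum(nov$calls$reads) + sum(cons$calls$reads %||% 0)
  mapped_unique <- sum(nov$calls$n_tags) + sum(cons$calls$n_tags %||% 0)

  expression <- NULL; specificity <- NULL
  if (!is.null(ct)) {
    expression <- .stage("express", relative_expression(ct))
    specificity <- .stage("express", {
      tissue_specificity(expression, threshold = p$specificity_threshold)
    })
  }

  targets <- NULL
  if (!is.null(mrnas) && nrow(nov$calls) > 0L) {
    targets <- .stage("targets", {
      hits <- antisense_search(setNames(nov$calls$mature, nov$calls$name),
                               mrnas, max_mm = p$max_mm_target,
                               max_gu = p$max_gu)
      c(list(hits = hits), aggregate_targets(hits))
    })
  }

  acc <- accounting_table(
    raw = pre$accounting$raw,
    unique_tags = n_unique_raw,
    clean = pre$accounting$clean,
    ncrna_removed = sum(ann$removed$count),
    mapped_reads = mapped_reads,
    mapped_unique = mapped_unique,
    conserved = NROW(cons$calls),
    novel = nrow(nov$calls))

  list(tags = pre$tags, preprocess_accounting = pre$accounting,
       annotation = ann, conserved = cons, novel = nov,
       isomirs = isomirs, duplexes = duplexes,
       expression = expression, specificity = specificity,
       targets = targets, accounting = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Thin wrapper so a whole run is reproducible from one file; sections map
#' to [run_pipeline()]'s `params`.
#'
#' @param path YAML file path
#' @return named list
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  yaml::read_yaml(path)
}
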