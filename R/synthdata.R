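#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic small-RNA-seq
#' generator. Defaults describe a size-selected (16-30 nt) library from a
#' pooled-tissue sample: a handful of planted hairpin precursors (novel plus
#' catalogue), 10% ncRNA contamination, a small unmappable background, and
#' isomiR structure (end shifts, one internal substitution per affected
#' read, 3' non-template tails drawn from an A/U/C-biased distribution).
#'
#' @param seed integer RNG seed; all generator randomness derives from it
#' @param n_precursors number of planted novel precursors
#' @param n_catalogue number of planted precursors whose matures go into the
#'   known-miRNA catalogue (conserved calls)
#' @param n_est_precursors novel precursors planted on EST/GSS-style contigs
#'   instead of the genome
#' @param n_chromosomes chromosomes the genome is split into
#' @param genome_len total genome length (nt); default
#'   `10 * 150 * (n_precursors + n_catalogue)`, at least 20 kb
#' @param n_reads total sequenced reads
#' @param read_len instrument read length; inserts are adapter-filled to it
#' @param adapter3 3' adapter sequence ligated to every insert
#' @param substitution_rate per-read probability of one internal substitution
#' @param nta_rate per-read probability of a 3' non-template tail
#' @param nta_base_weights named distribution over `A,C,G,U` for tail bases
#' @param nta_len_probs distribution over tail lengths 1..3
#' @param end_shift_probs named distribution over 5'/3' end offsets -2..2
#' @param ncrna_fraction proportion of reads drawn from the contaminant set
#' @param bg_fraction proportion of unmappable background reads
#' @param star_fraction proportion of precursor-derived reads from the star arm
#' @param length_range size-selection window, within 16-30 nt
#' @param n_ncrna_species number of abundant contaminant fragment species
#' @param expr_geom_prob geometric parameter for precursor expression
#'   weights (long-tailed, so edited variants can be singletons)
#' @param ct_noise_sd replicate noise (Ct units) for the qPCR simulator
#' @param specific_tissue tissue carrying the planted tissue-specific effect
#' @param specific_effect Ct decrease in `specific_tissue` for the first
#'   profiled miRNA (5 Ct = 32-fold enrichment)
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_precursors = 5L,
                       n_catalogue = 3L,
                       n_est_precursors = 0L,
                       n_chromosomes = 3L,
                       genome_len = NULL,
                       n_reads = 10000L,
                       read_len = 36L,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       substitution_rate = 0.05,
                       nta_rate = 0.10,
                       nta_base_weights = c(A = 0.45, C = 0.14, G = 0, U = 0.41),
                       nta_len_probs = c(0.70, 0.25, 0.05),
                       end_shift_probs = c(`-2` = 0.02, `-1` = 0.08, `0` = 0.80,
                                           `1` = 0.08, `2` = 0.02),
                       ncrna_fraction = 0.10,
                       bg_fraction = 0.03,
                       star_fraction = 0.15,
                       length_range = c(16L, 30L),
                       n_ncrna_species = 20L,
                       expr_geom_prob = 0.35,
                       ct_noise_sd = 0.25,
                       specific_tissue = "stomach",
                       specific_effect = 5) {
  cfg <- list(seed = as.integer(seed),
              n_precursors = as.integer(n_precursors),
              n_catalogue = as.integer(n_catalogue),
              n_est_precursors = as.integer(n_est_precursors),
              n_chromosomes = as.integer(n_chromosomes),
              genome_len = genome_len,
              n_reads = as.integer(n_reads),
              read_len = as.integer(read_len),
              adapter3 = as_dna(adapter3),
              substitution_rate = substitution_rate,
              nta_rate = nta_rate,
              nta_base_weights = nta_base_weights,
              nta_len_probs = nta_len_probs,
              end_shift_probs = end_shift_probs,
              ncrna_fraction = ncrna_fraction,
              bg_fraction = bg_fraction,
              star_fraction = star_fraction,
              length_range = as.integer(length_range),
              n_ncrna_species = as.integer(n_ncrna_species),
              expr_geom_prob = expr_geom_prob,
              ct_noise_sd = ct_noise_sd,
              specific_tissue = specific_tissue,
              specific_effect = specific_effect)
  n_tot <- cfg$n_precursors + cfg$n_catalogue
  if (is.null(cfg$genome_len)) {
    cfg$genome_len <- max(10L * 150L * max(n_tot, 1L), 20000L)
  }
  cfg$genome_len <- as.integer(cfg$genome_len)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Validate a simulation configuration
#' @param cfg a `sim_config` list
#' @return the config, invisibly; errors describe the violated constraint
#' @export
validate_sim_config <- function(cfg) {
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || any(p < 0) || any(p > 1)) {
      stop("configuration error: ", what, " must be in [0, 1]")
    }
  }
  chk_prob(cfg$substitution_rate, "substitution_rate")
  chk_prob(cfg$nta_rate, "nta_rate")
  chk_prob(cfg$ncrna_fraction, "ncrna_fraction")
  chk_prob(cfg$bg_fraction, "bg_fraction")
  chk_prob(cfg$star_fraction, "star_fraction")
  if (cfg$ncrna_fraction + cfg$bg_fraction > 1) {
    stop("configuration error: ncrna_fraction + bg_fraction exceeds 1")
  }
  chk_dist <- function(w, what, nms = NULL) {
    chk_prob(w, what)
    if (abs(sum(w) - 1) > 1e-8) {
      stop("configuration error: ", what, " must sum to 1")
    }
    if (!is.null(nms) && !identical(names(w), nms)) {
      stop("configuration error: ", what, " must be named ",
           paste(nms, collapse = ","))
    }
  }
  chk_dist(cfg$nta_base_weights, "nta_base_weights", c("A", "C", "G", "U"))
  chk_dist(cfg$nta_len_probs, "nta_len_probs")
  chk_dist(cfg$end_shift_probs, "end_shift_probs",
           c("-2", "-1", "0", "1", "2"))
  lr <- cfg$length_range
  if (length(lr) != 2L || lr[1L] > lr[2L] || lr[1L] < 16L || lr[2L] > 30L) {
    stop("configuration error: length_range must lie within [16, 30]")
  }
  if (nchar(cfg$adapter3) < 6L) {
    stop("configuration error: adapter3 shorter than 6 nt")
  }
  n_tot <- cfg$n_precursors + cfg$n_catalogue
  if (n_tot > 0L && cfg$genome_len < 10L * 150L * n_tot) {
    stop("configuration error: genome_len must be at least 10 * 150 * ",
         "number of genome-planted precursors")
  }
  invisible(cfg)
}

## Catalogue names used for planted conserved miRNAs; letter suffixes give
## call_conserved() real families to aggregate.
.CATALOGUE_NAMES <- c("ipu-let-7a", "ipu-let-7b", "ipu-miR-21", "ipu-miR-9",
                      "ipu-miR-144", "ipu-miR-181a", "ipu-miR-181b",
                      "ipu-miR-462")

## Build one hairpin precursor: 5' arm A (L nt), loop, 3' arm B with
## B[1..L-2] = rc(A)[3..L] so the duplex has L-2 >= 18 base pairs and a
## 2-nt 3' overhang on both strands. The 5 bases following each arm's 3'
## end (loop start for the 5p arm, downstream flank for the 3p arm) are set
## to the zero-weight tail base so that planted 3' tails are unambiguously
## non-templated even under the maximal +2 end shift.
.build_precursor <- function(cont_base, arm5_seq = NULL) {
  L <- if (is.null(arm5_seq)) sample(20:23, 1L) else nchar(arm5_seq)
  repeat {
    arm5 <- if (is.null(arm5_seq)) .random_seq(L) else arm5_seq
    rc5 <- reverse_complement(arm5)
    arm3 <- paste0(substr(rc5, 3L, L), .random_seq(2L))
    loop_len <- sample(9:14, 1L)
    loop <- paste0(strrep(cont_base, 5L), .random_seq(loop_len - 5L))
    # avoid a run of cont_base at the arm boundary mimicking a templated tail
    if (substr(arm5, L, L) != cont_base && substr(arm3, 1L, 1L) != cont_base) {
      break
    }
    if (!is.null(arm5_seq)) {
      stop("supplied arm conflicts with the tail-base convention")
    }
  }
  prec <- paste0(arm5, loop, arm3)
  list(seq = prec, L = L, loop_len = loop_len,
       arm5_start = 1L, arm5_end = L,
       arm3_start = L + loop_len + 1L, arm3_end = 2L * L + loop_len)
}

.replace_substr <- function(x, start, value) {
  paste0(substr(x, 1L, start - 1L), value,
         substr(x, start + nchar(value), nchar(x)))
}

#' Generate a synthetic genome with planted miRNA precursors
#'
#' Plants `n_precursors + n_catalogue` hairpin precursors at random
#' non-overlapping loci (either strand) in a random genome, plus optional
#' EST/GSS-style contigs, a labelled ncRNA contaminant reference, and the
#' known-mature catalogue. Each planted precursor has a mature arm (5p or
#' 3p) and a star arm in duplex geometry with 2-nt 3' overhangs, and its
#' maximum-pairing structure carries at least 18 base pairs (arm length 20-23
#' gives an 18-21 bp planted stem).
#'
#' @param config a [sim_config()]
#' @return object of class `mirf_sim`: list with `genome`, `est`, `ncrna`
#'   (named character vectors; ncRNA names carry `|class` suffixes),
#'   `catalogue` (named mature sequences), `ncrna_pool`, `precursors`
#'   (ground-truth data frame) and `config`
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  wmin <- which.min(config$nta_base_weights)
  cont_base <- chartr("U", "T", names(config$nta_base_weights)[wmin])

  ## genome scaffold
  n_chr <- config$n_chromosomes
  chr_len <- rep(config$genome_len %/% n_chr, n_chr)
  chr_len[n_chr] <- chr_len[n_chr] + config$genome_len %% n_chr
  genome <- setNames(vapply(chr_len, .random_seq, character(1L)),
                     paste0("chr", seq_len(n_chr)))

  n_tot <- config$n_precursors + config$n_catalogue
  n_est <- config$n_est_precursors
  status <- c(rep("novel", config$n_precursors),
              rep("catalogue", config$n_catalogue),
              rep("novel", n_est))
  source <- c(rep("genome", n_tot), rep("est", n_est))
  names_all <- character(n_tot + n_est)
  ni <- 0L; ci <- 0L
  for (i in seq_len(n_tot + n_est)) {
    if (status[i] == "catalogue") {
      ci <- ci + 1L
      names_all[i] <- .CATALOGUE_NAMES[((ci - 1L) %% length(.CATALOGUE_NAMES)) + 1L]
    } else {
      ni <- ni + 1L
      names_all[i] <- sprintf("planted-novel-%d", ni)
    }
  }

  est <- character(0)
  if (n_est > 0L) {
    est_len <- sample(300:600, n_est, replace = TRUE)
    est <- setNames(vapply(est_len, .random_seq, character(1L)),
                    sprintf("gi|9%08d|gb|SYN%05d.1|SYN%05d",
                            seq_len(n_est), seq_len(n_est), seq_len(n_est)))
  }

  occupied <- lapply(seq_len(n_chr), function(i) matrix(numeric(0), ncol = 2L))
  rows <- vector("list", n_tot + n_est)
  fam_mature <- list()  # family name -> mature of the first member
  for (i in seq_len(n_tot + n_est)) {
    if (status[i] == "catalogue") {
      ## catalogue members of one family are sequence relatives: same seed
      ## (positions 2-8), two substitutions in the 3' half — so conserved
      ## calling sees real families and conservation profiling sees a
      ## shared seed. Catalogue matures sit on the 5p arm.
      fam <- mirna_family(names_all[i])
      if (!is.null(fam_mature[[fam]])) {
        m <- fam_mature[[fam]]
        for (p in sample(9:(nchar(m) - 4L), 2L)) {
          substr(m, p, p) <- sample(setdiff(.BASES, substr(m, p, p)), 1L)
        }
        hp <- .build_precursor(cont_base, arm5_seq = m)
      } else {
        hp <- .build_precursor(cont_base)
        fam_mature[[fam]] <- substr(hp$seq, hp$arm5_start, hp$arm5_end)
      }
      arm <- "5p"
    } else {
      hp <- .build_precursor(cont_base)
      arm <- sample(c("5p", "3p"), 1L)
    }
    plen <- nchar(hp$seq)
    strand <- sample(c("+", "-"), 1L)
    block <- paste0(hp$seq, strrep(cont_base, 5L))  # 3p-arm 3' continuation

    if (source[i] == "genome") {
      ## find a free slot with 30 nt clearance
      repeat {
        chr <- sample.int(n_chr, 1L, prob = chr_len)
        pos <- sample.int(chr_len[chr] - nchar(block) - 60L, 1L) + 30L
        iv <- c(pos - 30L, pos + nchar(block) + 30L)
        occ <- occupied[[chr]]
        if (nrow(occ) == 0L ||
            all(iv[2L] < occ[, 1L] | iv[1L] > occ[, 2L])) break
      }
      occupied[[chr]] <- rbind(occupied[[chr]], iv)
      ins <- if (strand == "+") block else reverse_complement(block)
      genome[chr] <- .replace_substr(genome[chr], pos, ins)
      ref <- names(genome)[chr]
      p1 <- if (strand == "+") pos else pos + 5L
      p2 <- p1 + plen - 1L
      refseq <- genome[chr]
    } else {
      ei <- i - n_tot
      pos <- 30L
      ins <- if (strand == "+") block else reverse_complement(block)
      est[ei] <- .replace_substr(est[ei], pos, ins)
      ref <- names(est)[ei]
      p1 <- if (strand == "+") pos else pos + 5L
      p2 <- p1 + plen - 1L
      refseq <- est[ei]
    }

    mature_loc <- if (arm == "5p") c(hp$arm5_start, hp$arm5_end) else
      c(hp$arm3_start, hp$arm3_end)
    star_loc <- if (arm == "5p") c(hp$arm3_start, hp$arm3_end) else
      c(hp$arm5_start, hp$arm5_end)
    mature_seq <- substr(hp$seq, mature_loc[1L], mature_loc[2L])
    star_seq <- substr(hp$seq, star_loc[1L], star_loc[2L])

    ## oriented precursor context: precursor +/- 10 nt in transcript sense
    if (strand == "+") {
      ctx <- substr(refseq, p1 - 10L, p2 + 10L)
    } else {
      ctx <- reverse_complement(substr(refseq, p1 - 10L, p2 + 10L))
    }

    rows[[i]] <- data.frame(
      name = names_all[i], status = status[i], source = source[i],
      ref = ref, start = p1, end = p2, strand = strand, arm = arm,
      loc_mature_start = mature_loc[1L], loc_mature_end = mature_loc[2L],
      loc_star_start = star_loc[1L], loc_star_end = star_loc[2L],
      precursor_seq = hp$seq, mature_seq = mature_seq, star_seq = star_seq,
      context_seq = ctx,
      context_mature_start = mature_loc[1L] + 10L,
      context_star_start = star_loc[1L] + 10L,
      stringsAsFactors = FALSE)
  }
  precursors <- if (n_tot + n_est > 0L) do.call(rbind, rows) else
    data.frame(name = character(0), status = character(0),
               source = character(0), ref = character(0), start = integer(0),
               end = integer(0), strand = character(0), arm = character(0),
               loc_mature_start = integer(0), loc_mature_end = integer(0),
               loc_star_start = integer(0), loc_star_end = integer(0),
               precursor_seq = character(0), mature_seq = character(0),
               star_seq = character(0), context_seq = character(0),
               context_mature_start = integer(0),
               context_star_start = integer(0),
               stringsAsFactors = FALSE)

  ## long-tailed expression weights (geometric)
  precursors$expr_weight <- if (nrow(precursors) > 0L) {
    rgeom(nrow(precursors), config$expr_geom_prob) + 1L
  } else {
    integer(0)
  }

  ## catalogue: planted catalogue matures plus decoys never planted,
  ## so conserved calling has true negatives
  cat_rows <- precursors[precursors$status == "catalogue", , drop = FALSE]
  catalogue <- setNames(cat_rows$mature_seq, cat_rows$name)
  if (length(catalogue) > 0L) {
    decoys <- setNames(vapply(rep(22L, 2L), .random_seq, character(1L)),
                       c("ipu-miR-9901", "ipu-miR-9902"))
    catalogue <- c(catalogue, decoys)
  }

  ## ncRNA contaminant reference with class-labelled headers
  ncrna <- setNames(
    vapply(c(120L, 300L, 75L, 100L, 100L), .random_seq, character(1L)),
    c("5S_rRNA|rRNA", "18S_frag|rRNA", "tRNA-Ala|tRNA",
      "SNORD-like|snoRNA", "U6-like|snRNA"))

  ## abundant contaminant fragment species (degradation hotspots), so
  ## contaminant tags survive the min-copies filter
  ns <- config$n_ncrna_species
  pool_ref <- sample(names(ncrna), ns, replace = TRUE)
  pool_len <- sample(18:25, ns, replace = TRUE)
  pool_start <- vapply(seq_len(ns), function(i) {
    sample.int(nchar(ncrna[[pool_ref[i]]]) - pool_len[i], 1L)
  }, integer(1L))
  ncrna_pool <- data.frame(
    ref = pool_ref, start = pool_start, len = pool_len,
    weight = rgeom(ns, 0.3) + 1L,
    seq = vapply(seq_len(ns), function(i) {
      substr(ncrna[[pool_ref[i]]], pool_start[i],
             pool_start[i] + pool_len[i] - 1L)
    }, character(1L)),
    class = sub("^.*\\|", "", pool_ref),
    stringsAsFactors = FALSE)

  structure(list(genome = genome, est = est, ncrna = ncrna,
                 catalogue = catalogue, ncrna_pool = ncrna_pool,
                 precursors = precursors, config = config),
            class = "mirf_sim")
}

#' Simulate adapter-ligated small-RNA reads with ground-truth provenance
#'
#' Each read is drawn i.i.d.: a contaminant fragment (probability
#' `ncrna_fraction`), a uniform-random background read (`bg_fraction`), or a
#' precursor-derived read (precursor chosen by expression weight, star arm
#' with probability `star_fraction`) carrying templated end shifts, at most
#' one internal substitution, and possibly a 3' non-template tail. The 3'
#' adapter is appended and the read clipped to `read_len`.
#'
#' @param sim a `mirf_sim` object from [simulate_genome()]
#' @param config configuration; defaults to the one inside `sim`
#' @return list with `reads` (data.frame `id`, `seq`) and `truth`
#'   (per-read provenance: category, precursor, arm, offsets, substitution,
#'   tail, and the un-adapted insert)
#' @export
simulate_reads <- function(sim, config = sim$config) {
  if (!inherits(sim, "mirf_sim")) stop("sim must come from simulate_genome()")
  if (sum(nchar(sim$genome)) == 0L) stop("empty genome")
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  n <- config$n_reads
  has_prec <- nrow(sim$precursors) > 0L
  p_nc <- config$ncrna_fraction
  p_bg <- config$bg_fraction
  p_pre <- if (has_prec) 1 - p_nc - p_bg else 0
  if (!has_prec) p_bg <- 1 - p_nc
  category <- sample(c("ncrna", "background", "precursor"), n, replace = TRUE,
                     prob = c(p_nc, p_bg, p_pre))

  truth <- data.frame(id = sprintf("read%06d", seq_len(n)),
                      category = category,
                      class = NA_character_, precursor = NA_character_,
                      arm = NA_character_,
                      offset5 = NA_integer_, offset3 = NA_integer_,
                      sub_pos = NA_integer_, sub_from = NA_character_,
                      sub_to = NA_character_,
                      nta = "", insert = NA_character_,
                      stringsAsFactors = FALSE)

  idx_nc <- which(category == "ncrna")
  if (length(idx_nc) > 0L) {
    sp <- sample.int(nrow(sim$ncrna_pool), length(idx_nc), replace = TRUE,
                     prob = sim$ncrna_pool$weight)
    truth$insert[idx_nc] <- sim$ncrna_pool$seq[sp]
    truth$class[idx_nc] <- sim$ncrna_pool$class[sp]
  }

  idx_bg <- which(category == "background")
  if (length(idx_bg) > 0L) {
    lens <- sample(config$length_range[1L]:config$length_range[2L],
                   length(idx_bg), replace = TRUE)
    truth$insert[idx_bg] <- vapply(lens, .random_seq, character(1L))
  }

  idx_pr <- which(category == "precursor")
  if (length(idx_pr) > 0L) {
    pr <- sim$precursors
    pick <- sample.int(nrow(pr), length(idx_pr), replace = TRUE,
                       prob = pr$expr_weight)
    is_star <- runif(length(idx_pr)) < config$star_fraction
    shifts <- as.integer(names(config$end_shift_probs))
    off5 <- sample(shifts, length(idx_pr), replace = TRUE,
                   prob = config$end_shift_probs)
    off3 <- sample(shifts, length(idx_pr), replace = TRUE,
                   prob = config$end_shift_probs)
    do_sub <- runif(length(idx_pr)) < config$substitution_rate
    do_nta <- runif(length(idx_pr)) < config$nta_rate
    tail_bases <- chartr("U", "T", names(config$nta_base_weights))

    for (k in seq_along(idx_pr)) {
      i <- idx_pr[k]
      row <- pr[pick[k], ]
      arm <- if (is_star[k]) "star" else "mature"
      ctx <- row$context_seq
      a1 <- if (is_star[k]) row$context_star_start else row$context_mature_start
      alen <- nchar(if (is_star[k]) row$star_seq else row$mature_seq)
      s <- a1 + off5[k]
      e <- a1 + alen - 1L + off3[k]
      insert <- substr(ctx, s, e)
      len <- nchar(insert)
      sub_pos <- NA_integer_; sub_from <- NA_character_; sub_to <- NA_character_
      if (do_sub[k] && len >= 6L) {
        sub_pos <- sample(3:(len - 3L), 1L)
        sub_from <- substr(insert, sub_pos, sub_pos)
        sub_to <- sample(setdiff(.BASES, sub_from), 1L)
        substr(insert, sub_pos, sub_pos) <- sub_to
      }
      nta <- ""
      if (do_nta[k]) {
        tl <- sample(1:3, 1L, prob = config$nta_len_probs)
        nta <- paste(sample(tail_bases, tl, replace = TRUE,
                            prob = config$nta_base_weights), collapse = "")
        insert <- paste0(insert, nta)
      }
      truth$precursor[i] <- row$name
      truth$arm[i] <- arm
      truth$offset5[i] <- off5[k]
      truth$offset3[i] <- off3[k]
      truth$sub_pos[i] <- sub_pos
      truth$sub_from[i] <- sub_from
      truth$sub_to[i] <- sub_to
      truth$nta[i] <- nta
      truth$insert[i] <- insert
    }
  }

  full <- paste0(truth$insert, config$adapter3)
  seqs <- substr(full, 1L, pmin(nchar(full), config$read_len))
  list(reads = data.frame(id = truth$id, seq = seqs,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' The ten profiled tissues
#' @return character vector of tissue names
#' @export
catfish_tissues <- function() {
  c("liver", "gill", "head_kidney", "spleen", "heart", "brain", "muscle",
    "stomach", "intestines", "skin")
}

#' Simulate a stem-loop RT-PCR Ct table
#'
#' Produces triplicate Ct values per miRNA and tissue plus the 5S rRNA
#' normalizer rows, with planted per-tissue `dCt` effects recorded as ground
#' truth. The first miRNA receives a planted tissue-specific effect
#' (`specific_effect` Ct lower in `specific_tissue`, i.e.
#' 2^`specific_effect`-fold enrichment); all others get mild random tissue
#' variation.
#'
#' @param mirnas character vector of miRNA names (at least 1)
#' @param tissues character vector of tissues (at least 1)
#' @param config a [sim_config()]; `ct_noise_sd`, `specific_tissue` and
#'   `specific_effect` are used
#' @param delta_ct optional planted `dCt` matrix (miRNA x tissue) overriding
#'   the random effects
#' @param n_replicates technical replicates per reaction
#' @return list with `ct` (data.frame `mirna`, `tissue`, `replicate`, `ct`;
#'   normalizer rows keyed `5S_rRNA`) and `truth` (the planted `dCt` matrix
#'   and the designated specific miRNA/tissue)
#' @export
simulate_ct_table <- function(mirnas, tissues = catfish_tissues(),
                              config = sim_config(), delta_ct = NULL,
                              n_replicates = 3L) {
  if (length(mirnas) < 1L || length(tissues) < 1L) {
    stop("need at least one miRNA and one tissue")
  }
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  nm <- length(mirnas); nt <- length(tissues)
  if (is.null(delta_ct)) {
    base <- runif(nm, 3, 10)
    delta_ct <- matrix(base, nm, nt) + matrix(rnorm(nm * nt, 0, 1), nm, nt)
    sp_t <- match(config$specific_tissue, tissues)
    specific <- NA_character_
    if (!is.na(sp_t)) {
      delta_ct[1L, ] <- base[1L] + 1  # flat elsewhere
      delta_ct[1L, sp_t] <- base[1L] + 1 - config$specific_effect
      specific <- mirnas[1L]
    }
  } else {
    stopifnot(nrow(delta_ct) == nm, ncol(delta_ct) == nt)
    specific <- NA_character_
  }
  dimnames(delta_ct) <- list(mirnas, tissues)

  ct5s <- matrix(15 + rnorm(nt, 0, 0.3), nt, n_replicates) +
    matrix(rnorm(nt * n_replicates, 0, config$ct_noise_sd), nt, n_replicates)
  rows <- list(); ri <- 0L
  for (t in seq_len(nt)) {
    for (r in seq_len(n_replicates)) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        mirna = c("5S_rRNA", mirnas), tissue = tissues[t], replicate = r,
        ct = c(ct5s[t, r],
               ct5s[t, r] + delta_ct[, t] +
                 rnorm(nm, 0, config$ct_noise_sd)),
        stringsAsFactors = FALSE)
    }
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  list(ct = ct,
       truth = list(delta_ct = delta_ct, specific_mirna = specific,
                    specific_tissue = config$specific_tissue))
}
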