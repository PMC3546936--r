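#' Call conserved miRNAs against a known-mature catalogue
#'
#' A tag is conserved when its best ungapped alignment to a catalogue
#' mature — allowing the tag's ends to sit within `end_tol` nt of the
#' mature's ends, as isomiR end variation requires — has at most `max_mm`
#' substitutions over the overlap. Each qualifying tag is assigned to its
#' single best mature (fewest mismatches, then smallest end shift); per
#' mature, the most abundant assigned tag becomes the call's sequence and
#' the call's read count sums all assigned tags. Families aggregate call
#' names via [mirna_family()].
#'
#' @param tags data.frame (`sequence`, `count`)
#' @param known_matures named character vector of mature sequences
#'   (miRBase-style names; duplicates are an error)
#' @param max_mm allowed substitutions
#' @param end_tol allowed shift of either tag end versus the mature ends
#' @return list with `calls` (data.frame `name`, `mature`, `status`,
#'   `family`, `reads`, `n_tags`), `families` (family, members, reads),
#'   `leftover` (tags matching nothing) and `assignments` (per-tag best hit)
#' @export
call_conserved <- function(tags, known_matures, max_mm = 1L, end_tol = 3L) {
  if (length(known_matures) == 0L) stop("known mature catalogue is empty")
  if (anyDuplicated(names(known_matures))) {
    stop("duplicate mature names in catalogue")
  }
  mat <- vapply(known_matures, as_dna, character(1L))
  tags$sequence <- as_dna(tags$sequence)

  best_of <- function(tag) {
    tl <- nchar(tag)
    best <- NULL
    for (mi in seq_along(mat)) {
      m <- mat[[mi]]
      ml <- nchar(m)
      for (s in -end_tol:end_tol) {      # tag start minus mature start
        if (abs(s + tl - ml) > end_tol) next
        o1 <- max(1L, 1L + s); o2 <- min(ml, s + tl)   # overlap in mature coords
        if (o2 - o1 + 1L < ml - end_tol) next
        tpos <- (o1 - s):(o2 - s)
        mm <- sum(strsplit(substr(tag, tpos[1L], tpos[length(tpos)]), "")[[1L]] !=
                    strsplit(substr(m, o1, o2), "")[[1L]])
        if (mm <= max_mm &&
            (is.null(best) || mm < best$mm ||
             (mm == best$mm && abs(s) < abs(best$shift)))) {
          best <- list(mature = names(mat)[mi], mm = mm, shift = s)
        }
      }
    }
    best
  }

  hits <- lapply(tags$sequence, best_of)
  got <- !vapply(hits, is.null, logical(1L))
  assignments <- if (any(got)) {
    data.frame(tag = tags$sequence[got], count = tags$count[got],
               mature = vapply(hits[got], `[[`, character(1L), "mature"),
               mismatches = vapply(hits[got], `[[`, numeric(1L), "mm"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tag = character(0), count = integer(0),
               mature = character(0), mismatches = integer(0))
  }

  calls <- do.call(rbind, lapply(split(assignments, assignments$mature),
                                 function(d) {
    top <- d[order(-d$count, d$tag), ][1L, ]
    data.frame(name = d$mature[1L], mature = top$tag, status = "conserved",
               family = mirna_family(d$mature[1L]),
               reads = sum(d$count), n_tags = nrow(d),
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- data.frame(name = character(0), mature = character(0),
                        status = character(0), family = character(0),
                        reads = integer(0), n_tags = integer(0))
  }
  rownames(calls) <- NULL
  families <- if (nrow(calls) > 0L) {
    do.call(rbind, lapply(split(calls, calls$family), function(d) {
      data.frame(family = d$family[1L], members = nrow(d),
                 reads = sum(d$reads), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(family = character(0), members = integer(0), reads = integer(0))
  }
  rownames(families) <- NULL
  leftover <- tags[!got, , drop = FALSE]
  rownames(leftover) <- NULL
  list(calls = calls, families = families, leftover = leftover,
       assignments = assignments)
}

## oriented window extraction: returns the window in transcript sense with
## the tag's local coordinates; windows running off the reference are
## trimmed, not errors
.oriented_window <- function(refseq, start, end, strand, up, down) {
  rlen <- nchar(refseq)
  if (strand == "+") {
    w1 <- max(1L, start - up); w2 <- min(rlen, end + down)
    list(seq = substr(refseq, w1, w2),
         tag_start = start - w1 + 1L, tag_end = end - w1 + 1L,
         g_start = w1, g_end = w2)
  } else {
    w1 <- max(1L, start - down); w2 <- min(rlen, end + up)
    list(seq = reverse_complement(substr(refseq, w1, w2)),
         tag_start = w2 - end + 1L, tag_end = w2 - start + 1L,
         g_start = w1, g_end = w2)
  }
}

## tag-in-one-arm test on a predicted structure. A mature miRNA arm pairs
## predominantly with the opposite arm across the loop; base-pair
## maximization on a real window also produces a few spurious pairs, so a
## majority rule is used: at least `min_arm_pairs` tag bases must pair with
## partners on one side of the tag, and at most `max_discordant` tag bases
## may pair the other way or within the tag itself.
.tag_arm <- function(pairs, t1, t2, min_arm_pairs = 12L, max_discordant = 3L) {
  if (nrow(pairs) == 0L) return(NULL)
  inside <- pairs[, 1L] >= t1 & pairs[, 1L] <= t2 &
    pairs[, 2L] >= t1 & pairs[, 2L] <= t2
  n_int <- 2L * sum(inside)
  down <- sum(pairs[!inside, 1L] >= t1 & pairs[!inside, 1L] <= t2)
  up <- sum(pairs[!inside, 2L] >= t1 & pairs[!inside, 2L] <= t2)
  maj <- max(down, up)
  if (maj < min_arm_pairs || min(down, up) + n_int > max_discordant) {
    return(NULL)
  }
  if (down >= up) "5p" else "3p"
}

#' Excise candidate precursor windows around a locus and fold them
#'
#' Two asymmetric windows are excised around the mapped tag — tag-as-5p-arm
#' (`tag - 10 nt ... tag + flank`) and tag-as-3p-arm (mirror image) — and
#' folded by [predict_structure()]. The better window is returned as a
#' hairpin candidate when the structure has at least `min_pairs` base
#' pairs, the tag lies wholly in one arm (no self-pairing, all partners on
#' one side), and the fold energy is at or below `energy_threshold`;
#' otherwise `NULL`.
#'
#' @param reference named sequences (the one named by `ref` is used)
#' @param ref,start,end,strand the tag locus (1-based inclusive, forward
#'   coordinates)
#' @param flank window extension on the far side of the tag (nt)
#' @param min_pairs minimum paired bases for a stem-loop
#' @param energy_threshold maximum accepted [fold_energy()]
#' @param min_loop minimum hairpin loop
#' @return a `hairpin_candidate` list (`precursor`, `structure`,
#'   `paired_bases`, `energy`, `arm`, `mature_start`, `mature_end` local to
#'   the precursor, `locus` components of the window) or `NULL`
#' @export
excise_and_fold <- function(reference, ref, start, end, strand = "+",
                            flank = 70L, min_pairs = 18L,
                            energy_threshold = -25, min_loop = 3L) {
  if (flank < 20L) stop("flank must be at least 20")
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  refseq <- as_dna(reference[[ref]])
  best <- NULL
  for (mode in c("5p", "3p")) {
    w <- if (mode == "5p") {
      .oriented_window(refseq, start, end, strand, up = 10L, down = flank)
    } else {
      .oriented_window(refseq, start, end, strand, up = flank, down = 10L)
    }
    fs <- predict_structure(w$seq, min_loop = min_loop)
    if (fs$paired_bases < min_pairs || fs$energy > energy_threshold) next
    arm <- .tag_arm(structure_pairs(fs$structure), w$tag_start, w$tag_end)
    if (is.null(arm)) next
    cand <- list(precursor = w$seq, structure = fs$structure,
                 paired_bases = fs$paired_bases, energy = fs$energy,
                 arm = arm, mature_start = w$tag_start,
                 mature_end = w$tag_end,
                 locus = list(ref = ref, start = w$g_start, end = w$g_end,
                              strand = strand))
    if (is.null(best) || cand$paired_bases > best$paired_bases ||
        (cand$paired_bases == best$paired_bases &&
         cand$energy < best$energy)) {
      best <- cand
    }
  }
  if (!is.null(best)) class(best) <- "hairpin_candidate"
  best
}

## does the excised window contain a catalogue mature (either orientation,
## <= 1 substitution)?
.window_has_known_mature <- function(window, known_matures) {
  subj <- Biostrings::DNAString(as_dna(window))
  for (m in known_matures) {
    m <- as_dna(m)
    if (nrow(.tag_hits_strand(m, subj, 1L)) > 0L ||
        nrow(.tag_hits_strand(m, subj, 1L, minus = TRUE)) > 0L) {
      return(TRUE)
    }
  }
  FALSE
}

#' Call novel miRNAs from leftover tags
#'
#' Leftover tags (not conserved) are mapped to the genome and, where they
#' fail to map there, to EST/GSS contigs, with the [map_tags()] rule. Tag
#' loci on the same reference and strand within `merge_gap` nt are grouped
#' into one candidate precursor region; the group's most abundant tag is
#' excised and folded, and groups whose window passes the hairpin criteria
#' become novel calls (most abundant tag = mature, read count = all grouped
#' tags). Names `novel-mir-{serial}` are assigned in descending read-count
#' order.
#'
#' Because a hairpin and its reverse complement are both hairpins — and a
#' mature arm read maps antisense onto the star arm — loci are grouped
#' ignoring strand, and the excised strand follows the group's most
#' abundant tag. Groups whose excised window contains a known mature
#' (within one substitution) are precursors of conserved miRNAs — their
#' opposite-arm tags are miRNA* candidates, not novel miRNAs — and are
#' dropped when `known_matures` is supplied.
#'
#' @param leftover tag data.frame (`sequence`, `count`)
#' @param genome named genome sequences
#' @param est optional named EST/GSS sequences
#' @param known_matures optional catalogue used to screen out conserved
#'   precursor loci
#' @param seed_len,seed_mm,total_mm mapping rule parameters
#' @param flank,min_pairs,energy_threshold,min_loop hairpin parameters
#' @param merge_gap loci closer than this are one precursor
#' @return list with `calls` (data.frame `name`, `mature`, `status`,
#'   `reads`, `n_tags`, `source`, `locus`) and `details` (per call: the
#'   `hairpin_candidate` and the member tag data.frame)
#' @export
call_novel <- function(leftover, genome, est = NULL, known_matures = NULL,
                       seed_len = 18L, seed_mm = 1L, total_mm = 1L,
                       flank = 70L, min_pairs = 18L, energy_threshold = -25,
                       min_loop = 3L, merge_gap = 40L) {
  empty <- list(calls = data.frame(name = character(0), mature = character(0),
                                   status = character(0), reads = integer(0),
                                   n_tags = integer(0), source = character(0),
                                   locus = character(0)),
                details = list())
  if (nrow(leftover) == 0L) return(empty)
  mg <- map_tags(leftover, genome, seed_len, seed_mm, total_mm)
  mapped <- mg$mapped
  if (!is.null(mapped) && nrow(mapped) > 0L) mapped$source <- "genome"
  if (!is.null(est) && length(est) > 0L && nrow(mg$unmapped) > 0L) {
    me <- map_tags(mg$unmapped, est, seed_len, seed_mm, total_mm)
    if (nrow(me$mapped) > 0L) {
      me$mapped$source <- "EST/GSS"
      mapped <- rbind(mapped, me$mapped)
    }
  }
  if (is.null(mapped) || nrow(mapped) == 0L) return(empty)

  ## group loci into precursor regions per reference, ignoring strand
  mapped <- mapped[order(mapped$ref, mapped$start), , drop = FALSE]
  grp <- integer(nrow(mapped)); g <- 0L
  last_ref <- ""; last_end <- -Inf
  for (i in seq_len(nrow(mapped))) {
    if (mapped$ref[i] != last_ref || mapped$start[i] > last_end + merge_gap) {
      g <- g + 1L
      last_end <- mapped$end[i]
    } else {
      last_end <- max(last_end, mapped$end[i])
    }
    last_ref <- mapped$ref[i]
    grp[i] <- g
  }

  refsets <- list(genome = genome, `EST/GSS` = est)
  calls <- list(); details <- list(); ci <- 0L
  for (gi in unique(grp)) {
    d <- mapped[grp == gi, , drop = FALSE]
    ## one row per tag (a tag may have several loci in the group)
    tagrows <- d[!duplicated(d$tag), , drop = FALSE]
    top <- d[order(-d$count, d$tag, d$start), ][1L, ]
    cand <- excise_and_fold(refsets[[top$source]], top$ref, top$start,
                            top$end, top$strand, flank = flank,
                            min_pairs = min_pairs,
                            energy_threshold = energy_threshold,
                            min_loop = min_loop)
    if (is.null(cand)) next
    if (!is.null(known_matures) &&
        .window_has_known_mature(cand$precursor, known_matures)) {
      next
    }
    ci <- ci + 1L
    members <- data.frame(sequence = tagrows$tag, count = tagrows$count,
                          stringsAsFactors = FALSE)
    calls[[ci]] <- data.frame(
      name = NA_character_, mature = top$tag, status = "novel",
      reads = sum(members$count), n_tags = nrow(members),
      source = top$source,
      locus = format_locus(cand$locus$ref, cand$locus$start,
                           cand$locus$end, cand$locus$strand),
      stringsAsFactors = FALSE)
    details[[ci]] <- list(candidate = cand, members = members)
  }
  if (ci == 0L) return(empty)
  calls <- do.call(rbind, calls)
  ord <- order(-calls$reads, calls$locus)
  calls <- calls[ord, , drop = FALSE]
  details <- details[ord]
  calls$name <- sprintf("novel-mir-%d", seq_len(nrow(calls)))
  names(details) <- calls$name
  rownames(calls) <- NULL
  list(calls = calls, details = details)
}
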