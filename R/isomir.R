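#' Classify isomiRs of one mature miRNA
#'
#' Each tag is aligned ungapped to the precursor context at every start
#' within `max_shift` nt of the reference mature 5' end and decomposed into
#' 5'/3' end offsets (templated), internal substitutions, and a maximal 3'
#' non-template tail: the trailing run of mismatches against the templated
#' continuation, up to `max_tail` nt (a trailing mismatch followed by
#' matching bases is a substitution, not a tail). The alignment minimizing
#' internal substitutions wins (ties: shorter tail, then smaller |5'
#' offset|, then the 5'-most start). Tags needing more than `max_subs`
#' internal substitutions are skipped with a warning.
#'
#' @param tags data.frame (`sequence`, `count`)
#' @param mature reference mature sequence
#' @param context precursor context sequence containing the mature and
#'   enough flank for shifts
#' @param context_mature_start 1-based start of the mature within `context`
#' @param parent name recorded in the output
#' @param max_shift alignment search radius around the mature 5' end
#' @param max_tail maximum non-template tail length
#' @param max_subs maximum internal substitutions before a tag is skipped
#' @return data.frame, one row per classified tag: `parent`, `sequence`,
#'   `count`, `offset5`, `offset3`, `substitutions`
#'   (`maturePos:ref>read` semicolon-joined), `n_subs`, `nta`, `category`
#'   (`canonical`, `shift`, `substitution`, `NTA` or `mixed`), `ctx_start`
#' @export
classify_isomirs <- function(tags, mature, context, context_mature_start,
                             parent = "miRNA", max_shift = 5L,
                             max_tail = 3L, max_subs = 2L) {
  mature <- as_dna(mature)
  context <- as_dna(context)
  m1 <- as.integer(context_mature_start)
  m2 <- m1 + nchar(mature) - 1L
  ctx_chars <- strsplit(context, "", fixed = TRUE)[[1L]]
  clen <- length(ctx_chars)

  rows <- list(); ri <- 0L
  for (ti in seq_len(nrow(tags))) {
    tag <- as_dna(tags$sequence[ti])
    tchars <- strsplit(tag, "", fixed = TRUE)[[1L]]
    n <- length(tchars)
    best <- NULL
    for (s in (m1 - max_shift):(m1 + max_shift)) {
      if (s < 1L || s + n - 1L > clen) next
      mm <- tchars != ctx_chars[s:(s + n - 1L)]
      ## trailing mismatch run, capped at max_tail
      t_run <- 0L
      for (p in n:1L) {
        if (!mm[p]) break
        t_run <- t_run + 1L
      }
      t_len <- min(t_run, max_tail)
      internal <- which(mm[seq_len(n - t_len)])
      cand <- list(s = s, t = t_len, internal = internal,
                   n_int = length(internal))
      if (is.null(best) ||
          cand$n_int < best$n_int ||
          (cand$n_int == best$n_int && cand$t < best$t) ||
          (cand$n_int == best$n_int && cand$t == best$t &&
           abs(cand$s - m1) < abs(best$s - m1))) {
        best <- cand
      }
    }
    if (is.null(best) || best$n_int > max_subs) {
      warning("tag not alignable within the isomiR window, skipped: ", tag)
      next
    }
    off5 <- best$s - m1
    off3 <- (best$s + n - 1L - best$t) - m2
    subs <- ""
    if (best$n_int > 0L) {
      mpos <- best$internal + off5          # position in mature coordinates
      subs <- paste(sprintf("%d:%s>%s", mpos,
                            ctx_chars[best$s + best$internal - 1L],
                            tchars[best$internal]), collapse = ";")
    }
    nta <- if (best$t > 0L) substr(tag, n - best$t + 1L, n) else ""
    kinds <- c(shift = off5 != 0L || off3 != 0L,
               substitution = best$n_int > 0L,
               NTA = best$t > 0L)
    category <- if (!any(kinds)) "canonical" else
      if (sum(kinds) > 1L) "mixed" else names(kinds)[kinds]
    ri <- ri + 1L
    rows[[ri]] <- data.frame(parent = parent, sequence = tag,
                             count = tags$count[ti],
                             offset5 = off5, offset3 = off3,
                             substitutions = subs, n_subs = best$n_int,
                             nta = nta, category = category,
                             ctx_start = best$s,
                             stringsAsFactors = FALSE)
  }
  out <- if (ri > 0L) do.call(rbind, rows) else
    data.frame(parent = character(0), sequence = character(0),
               count = integer(0), offset5 = integer(0),
               offset3 = integer(0), substitutions = character(0),
               n_subs = integer(0), nta = character(0),
               category = character(0), ctx_start = integer(0))
  rownames(out) <- NULL
  out
}

#' Directed substitution spectrum of an isomiR set
#'
#' Tallies the 12 directed substitution classes (`A>C`, `A>G`, ...), both
#' read-weighted (each substitution counted by the tag's copy count — the
#' convention used for published percentages) and tag-weighted.
#'
#' @param records output of [classify_isomirs()]
#' @return data.frame `class`, `reads`, `tags`, `read_fraction`,
#'   `tag_fraction` (12 rows, zero-filled)
#' @export
substitution_spectrum <- function(records) {
  bases <- c("A", "C", "G", "U")
  classes <- as.vector(outer(bases, bases, function(a, b) paste0(a, ">", b)))
  classes <- classes[substr(classes, 1L, 1L) != substr(classes, 3L, 3L)]
  reads <- setNames(numeric(12L), sort(classes))
  tagsw <- reads
  withs <- records[records$n_subs > 0L, , drop = FALSE]
  if (nrow(withs) > 0L) {
    for (i in seq_len(nrow(withs))) {
      for (part in strsplit(withs$substitutions[i], ";", fixed = TRUE)[[1L]]) {
        ft <- sub("^[0-9]+:", "", part)
        key <- chartr("T", "U", ft)
        reads[key] <- reads[key] + withs$count[i]
        tagsw[key] <- tagsw[key] + 1L
      }
    }
  }
  data.frame(class = names(reads), reads = as.numeric(reads),
             tags = as.numeric(tagsw),
             read_fraction = if (sum(reads) > 0) reads / sum(reads) else reads,
             tag_fraction = if (sum(tagsw) > 0) tagsw / sum(tagsw) else tagsw,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 3' non-template addition base usage
#'
#' Counts each tail base occurrence, read-weighted and tag-weighted.
#'
#' @param records output of [classify_isomirs()]
#' @return data.frame `base` (`A,C,G,U`), `reads`, `tags`, `read_fraction`
#' @export
nta_base_counts <- function(records) {
  bases <- c("A", "C", "G", "U")
  reads <- setNames(numeric(4L), bases); tagsw <- reads
  withs <- records[nchar(records$nta) > 0L, , drop = FALSE]
  if (nrow(withs) > 0L) {
    for (i in seq_len(nrow(withs))) {
      for (b in strsplit(chartr("T", "U", withs$nta[i]), "")[[1L]]) {
        reads[b] <- reads[b] + withs$count[i]
        tagsw[b] <- tagsw[b] + 1L
      }
    }
  }
  data.frame(base = bases, reads = as.numeric(reads),
             tags = as.numeric(tagsw),
             read_fraction = if (sum(reads) > 0) reads / sum(reads) else reads,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer dominant Drosha/Dicer cleavage sites from isomiR end usage
#'
#' The dominant 5' (3') site is the read-count-weighted mode of the 5' (3')
#' end offsets; non-template tail bases are excluded from 3' ends by
#' construction of the records. Ties break toward the reference mature end
#' (offset 0, then the smaller absolute offset, then the 5'-extended one).
#'
#' @param records output of [classify_isomirs()]
#' @return list with `dominant5`, `dominant3` (offsets relative to the
#'   reference mature ends) and the supporting `table5`, `table3`
#' @export
infer_cleavage_sites <- function(records) {
  if (nrow(records) == 0L) stop("no isomiR records")
  pick <- function(off, cnt) {
    tab <- tapply(cnt, off, sum)
    o <- as.integer(names(tab))
    ord <- order(-as.numeric(tab), abs(o), o)
    data.frame(offset = o[ord], reads = as.numeric(tab)[ord])
  }
  t5 <- pick(records$offset5, records$count)
  t3 <- pick(records$offset3, records$count)
  list(dominant5 = t5$offset[1L], dominant3 = t3$offset[1L],
       table5 = t5, table3 = t3)
}

#' Detect a miRNA:miRNA* duplex on a hairpin
#'
#' Positions the given tags on the precursor (ungapped, up to one
#' substitution), takes the most abundant tag on the arm opposite the
#' mature, and accepts the pair when the precursor structure pairs the two
#' arms with 3' overhangs of 2 +/- `overhang_tol` nt at both duplex ends.
#'
#' @param hairpin a `hairpin_candidate` (or a list with `precursor`,
#'   `structure`, `mature_start`, `mature_end`)
#' @param tags data.frame (`sequence`, `count`) of tags on the precursor
#' @param overhang_tol accepted deviation from the canonical 2-nt overhang
#' @return list (`mature`, `star`, `mature_count`, `star_count`, `ratio`,
#'   `overhangs`, `star_dominant`) or `NULL` when no qualifying star exists
#' @export
detect_star <- function(hairpin, tags, overhang_tol = 2L) {
  prec <- as_dna(hairpin$precursor)
  pairs <- structure_pairs(hairpin$structure)
  if (nrow(pairs) == 0L) return(NULL)
  m1 <- hairpin$mature_start; m2 <- hairpin$mature_end

  ## position each tag on the precursor
  pos <- lapply(tags$sequence, function(s) {
    h <- .tag_hits_strand(as_dna(s), Biostrings::DNAString(prec), 1L)
    if (nrow(h) == 0L) return(NULL)
    c(h$start[1L], h$end[1L])
  })
  ok <- !vapply(pos, is.null, logical(1L))
  if (!any(ok)) return(NULL)
  placed <- data.frame(sequence = tags$sequence[ok], count = tags$count[ok],
                       start = vapply(pos[ok], `[`, numeric(1L), 1L),
                       end = vapply(pos[ok], `[`, numeric(1L), 2L))

  ## the mature tag: most abundant tag overlapping the mature region
  on_mature <- placed$start <= m2 & placed$end >= m1
  if (!any(on_mature)) return(NULL)
  mat <- placed[on_mature, ][order(-placed$count[on_mature]), ][1L, ]

  ## loop midpoint from the inter-arm pairs enclosing the mature
  opp <- placed[!on_mature & (placed$start > m2 | placed$end < m1), ,
                drop = FALSE]
  if (nrow(opp) == 0L) return(NULL)
  star <- opp[order(-opp$count, opp$sequence), ][1L, ]

  a <- c(min(mat$start, star$start), min(mat$end, star$end))
  left <- if (mat$start < star$start) mat else star
  right <- if (mat$start < star$start) star else mat
  sel <- pairs[, 1L] >= left$start & pairs[, 1L] <= left$end &
    pairs[, 2L] >= right$start & pairs[, 2L] <= right$end
  if (!any(sel)) return(NULL)
  ip <- pairs[sel, , drop = FALSE]
  oh_loop <- (left$end - max(ip[, 1L])) - (min(ip[, 2L]) - right$start)
  oh_outer <- (right$end - max(ip[, 2L])) - (min(ip[, 1L]) - left$start)
  if (abs(oh_loop - 2L) > overhang_tol || abs(oh_outer - 2L) > overhang_tol) {
    return(NULL)
  }
  ratio <- star$count / mat$count
  list(mature = mat$sequence, star = star$sequence,
       mature_count = mat$count, star_count = star$count,
       ratio = ratio, overhangs = c(loop = oh_loop, outer = oh_outer),
       star_dominant = ratio > 1)
}

#' Seed-conservation profile across orthologous matures
#'
#' Globally aligns every sequence to the first (reference) sequence with
#' match +1, mismatch -1, linear gap -2, and reports per-reference-position
#' identity plus the mean identity over the seed columns (reference
#' positions 2-8 by default). Gapped columns count as non-identical.
#'
#' @param seqs named character vector (>= 2 sequences; first = reference)
#' @param seed reference positions defining the seed
#' @return list with `profile` (data.frame `position`, `ref_base`,
#'   `identity`) and `seed_identity`
#' @export
seed_conservation <- function(seqs, seed = 2:8) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  seqs <- vapply(seqs, as_dna, character(1L))
  ref <- seqs[[1L]]
  others <- seqs[-1L]
  rl <- nchar(ref)
  idmat <- matrix(FALSE, length(others), rl)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  for (i in seq_along(others)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(others[[i]]), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    rpos <- cumsum(s != "-")
    keep <- s != "-"
    idmat[i, rpos[keep]] <- p[keep] == s[keep]
  }
  profile <- data.frame(position = seq_len(rl),
                        ref_base = strsplit(chartr("T", "U", ref), "")[[1L]],
                        identity = colMeans(idmat))
  seed <- seed[seed <= rl]
  list(profile = profile, seed_identity = mean(profile$identity[seed]))
}
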