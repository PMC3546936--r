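#!/usr/bin/env Rscript
# Stage 5 — isomiR spectra, cleavage sites and miRNA:miRNA* duplexes.
#
# Member tags of each novel call are decomposed against their precursor
# window into end shifts, internal substitutions and 3' non-template
# tails; read-weighted summaries give the substitution spectrum, the tail
# base usage and the dominant Drosha/Dicer cleavage sites. Each hairpin is
# then screened for a star strand in duplex geometry (2-nt 3' overhangs).

library(mirforge)

details <- read.delim("results/novel_precursors.tsv")
members <- read.delim("results/novel_members.tsv")
calls <- read.delim("results/novel_calls.tsv")

recs <- list(); duplexes <- list(); cleavage <- list()
for (i in seq_len(nrow(details))) {
  nm <- details$name[i]
  tags <- members[members$name == nm, c("sequence", "count")]
  mature <- calls$mature[calls$name == nm]
  r <- suppressWarnings(classify_isomirs(
    tags, mature, details$precursor[i], details$mature_start[i],
    parent = nm))
  recs[[nm]] <- r
  if (nrow(r) > 0) {
    cs <- infer_cleavage_sites(r)
    cleavage[[nm]] <- data.frame(name = nm, dominant5 = cs$dominant5,
                                 dominant3 = cs$dominant3)
  }
  hp <- list(precursor = details$precursor[i],
             structure = details$structure[i],
             mature_start = details$mature_start[i],
             mature_end = details$mature_end[i])
  st <- detect_star(hp, tags)
  if (!is.null(st)) {
    duplexes[[nm]] <- data.frame(
      name = nm, mature = st$mature, star = st$star,
      mature_count = st$mature_count, star_count = st$star_count,
      ratio = st$ratio, overhang_loop = st$overhangs[["loop"]],
      overhang_outer = st$overhangs[["outer"]],
      star_dominant = st$star_dominant)
  }
}
recs <- do.call(rbind, recs)

write.table(recs, "results/isomirs.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(substitution_spectrum(recs), "results/isomir_spectrum.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(nta_base_counts(recs), "results/isomir_nta_bases.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(do.call(rbind, cleavage), "results/cleavage_sites.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(do.call(rbind, duplexes), "results/duplexes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("classified %d isomiR records (%d reads) on %d precursors\n",
            nrow(recs), sum(recs$count), nrow(details)))
print(table(recs$category))
nta <- nta_base_counts(recs)
cat("3' addition base usage (reads):",
    sprintf("%s=%d", nta$base, as.integer(nta$reads)), "\n")
cat(sprintf("duplexes detected: %d of %d precursors\n",
            length(duplexes), nrow(details)))

## seed conservation across the planted let-7 family members
catalogue <- read_fasta("results/sim/matures.fa")
fam <- catalogue[startsWith(names(catalogue), "ipu-let-7")]
if (length(fam) >= 2) {
  sc <- seed_conservation(fam)
  write.table(sc$profile, "results/seed_conservation.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("let-7 family seed identity: %.2f\n", sc$seed_identity))
}
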