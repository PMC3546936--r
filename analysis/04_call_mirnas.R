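#!/usr/bin/env Rscript
# Stage 4 — conserved and novel miRNA calling.
#
# Retained tags are first matched against the known-mature catalogue
# (<= 1 substitution, ends within 3 nt); leftovers are mapped to the
# genome and EST/GSS contigs, grouped into precursor regions, excised with
# asymmetric windows and folded. Regions whose best window carries >= 18
# base pairs, an arm-confined tag and a passing fold energy become novel
# calls.

library(mirforge)

tags <- read_tags_fasta("results/tags_retained.fa")
genome <- read_fasta("results/sim/genome.fa")
catalogue <- read_fasta("results/sim/matures.fa")
est <- if (file.exists("results/sim/est.fa")) {
  read_fasta("results/sim/est.fa")
} else {
  NULL
}

cons <- call_conserved(tags, catalogue)
write.table(cons$calls, "results/conserved_calls.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cons$families, "results/conserved_families.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("conserved: %d miRNAs in %d families (%d reads)\n",
            nrow(cons$calls), nrow(cons$families), sum(cons$calls$reads)))

nov <- call_novel(cons$leftover, genome, est, known_matures = catalogue)
write.table(nov$calls, "results/novel_calls.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

## persist what stage 5 needs: precursor windows with structures, and the
## member tags of each call
details <- do.call(rbind, lapply(names(nov$details), function(nm) {
  cand <- nov$details[[nm]]$candidate
  data.frame(name = nm, precursor = cand$precursor,
             structure = cand$structure, paired_bases = cand$paired_bases,
             energy = cand$energy, arm = cand$arm,
             mature_start = cand$mature_start,
             mature_end = cand$mature_end,
             locus = format_locus(cand$locus$ref, cand$locus$start,
                                  cand$locus$end, cand$locus$strand))
}))
members <- do.call(rbind, lapply(names(nov$details), function(nm) {
  cbind(name = nm, nov$details[[nm]]$members)
}))
write.table(details, "results/novel_precursors.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(members, "results/novel_members.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_fasta(setNames(details$precursor, details$name),
            "results/novel_precursors.fa")

cat(sprintf("novel: %d calls (%d-%d reads), %d on EST/GSS\n",
            nrow(nov$calls), min(nov$calls$reads), max(nov$calls$reads),
            sum(nov$calls$source == "EST/GSS")))
truth <- read.delim("results/sim/truth_precursors.tsv")
truth <- truth[truth$status == "novel", ]
loc <- parse_locus(nov$calls$locus)
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(loc$ref == truth$ref[i] & loc$start <= truth$end[i] &
        loc$end >= truth$start[i])
}, logical(1))
cat(sprintf("planted-precursor recall: %.2f\n", mean(hit)))
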