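#!/usr/bin/env Rscript
# Stage 7 — antisense target prediction for the novel miRNAs.
#
# A synthetic transcriptome stands in for a reference RNA set: each novel
# mature gets two perfectly antisense sites planted in random transcripts
# (one transcript deliberately carries sites for several miRNAs, the
# multi-targeting case). Hits need <= 1 non-GU mismatch, <= 2 GU wobbles
# and a perfect seed (miRNA positions 2-8).

library(mirforge)

set.seed(4242)
calls <- read.delim("results/novel_calls.tsv")
mirs <- setNames(calls$mature, calls$name)

n_tx <- 8
mrnas <- setNames(vapply(seq_len(n_tx), function(i) {
  paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
}, character(1)), sprintf("tx%02d", seq_len(n_tx)))

plant <- function(tx, site) {
  pos <- sample(nchar(mrnas[[tx]]) - nchar(site), 1)
  s <- mrnas[[tx]]
  mrnas[[tx]] <<- paste0(substr(s, 1, pos - 1), site,
                         substr(s, pos + nchar(site), nchar(s)))
}
for (nm in names(mirs)) {
  for (k in 1:2) plant(sample(n_tx - 1, 1), reverse_complement(mirs[[nm]]))
}
for (nm in head(names(mirs), 4)) {       # the multi-targeted transcript
  plant(n_tx, reverse_complement(mirs[[nm]]))
}

hits <- antisense_search(mirs, mrnas)
agg <- aggregate_targets(hits)

write.table(hits, "results/target_hits.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(agg$per_mirna, "results/targets_per_mirna.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(agg$per_mrna, "results/targets_per_mrna.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("%d target sites across %d transcripts for %d miRNAs\n",
            nrow(hits), length(unique(hits$mrna)), length(mirs)))
cat(sprintf("every miRNA has >= 2 sites: %s\n",
            all(agg$per_mirna$n_sites >= 2)))
multi <- agg$per_mrna[which.max(agg$per_mrna$n_mirnas), ]
cat(sprintf("most multi-targeted transcript: %s (%d miRNAs)\n",
            multi$mrna, multi$n_mirnas))
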