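#!/usr/bin/env Rscript
# Stage 3 — ncRNA annotation and genome mapping.
#
# Tags matching the labelled rRNA/tRNA/snoRNA/snRNA reference (substring,
# <= 1 substitution, either strand) are removed; the rest are mapped to the
# genome under the seed-tolerant rule (<= 1 mismatch in the first 18 nt,
# <= 1 overall, both strands, all loci reported).

library(mirforge)

tags <- read_tags_fasta("results/tags.fa")
ncrna <- read_fasta("results/sim/ncrna.fa")
genome <- read_fasta("results/sim/genome.fa")

ann <- annotate_ncrna(tags, ncrna)
write.table(ann$removed, "results/ncrna_annotation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(ann$class_counts, "results/ncrna_class_counts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_tags_fasta(ann$retained, "results/tags_retained.fa")
cat(sprintf("ncRNA screen: %d tags / %d reads removed (%.1f%% of clean)\n",
            nrow(ann$removed), sum(ann$removed$count),
            100 * sum(ann$removed$count) / sum(tags$count)))

mp <- map_tags(ann$retained, genome)
write.table(mp$mapped, "results/mapping.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
dist <- distribution_by_reference(mp$mapped)
write.table(dist, "results/mapping_distribution.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("mapped %d of %d retained tags (%d loci); %d tags unmapped\n",
            length(unique(mp$mapped$tag)), nrow(ann$retained),
            nrow(mp$mapped), nrow(mp$unmapped)))
print(dist)
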