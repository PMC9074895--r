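#!/usr/bin/env Rscript
# Stage 3: annotate mRNA 3' ends from tag 3'-coordinates.
#
# Greedy iterative peak assignment with a 21-nt window on tags with
# tails >= 11 nt, retaining ends that carry >= 10% of a gene's tags, and
# scoring the calls against the planted isoform ends.

suppressPackageStartupMessages(library(tailscape))

truth <- read_tsv("results/data/tag_truth.tsv")
calls <- read_tsv("results/tail_calls.tsv")
iso <- read_tsv("results/data/isoform_truth.tsv")

tags <- data.frame(gene = truth$gene, coord = truth$coord,
                   tail_length = calls$tail_length[match(truth$tag_id,
                                                         calls$tag_id)])
tags <- tags[!is.na(tags$gene), ]
ends <- annotate_ends_by_gene(tags)
write_tsv(ends, "results/three_prime_ends.tsv")

m <- merge(ends, iso, by = "gene")
near <- tapply(abs(m$coord - m$end_offset) <= 1, paste(m$gene, m$coord), any)
cat(sprintf("Annotated %d 3' ends across %d genes; %.1f%% within 1 nt of a planted isoform end.\n",
            nrow(ends), length(unique(ends$gene)), 100 * mean(near)))
cat(sprintf("Genes with two annotated ends: %d (planted: %d).\n",
            sum(table(ends$gene) == 2),
            sum(table(iso$gene) == 2)))
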