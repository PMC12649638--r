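#!/usr/bin/env Rscript
# Stage 4: differential-expression screening.
#
# Counts are CPM-normalized (log2(CPM+1)), per-gene log2(Feeding/Control)
# fold changes and Welch-t p-values are computed, BH-adjusted, and screened
# with the strict rule |log2FC| > 1 and q < 0.05.

library(polypnet)

out <- "results/04_de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

md <- read_metadata("results/data/metadata.csv")
counts <- read_expression("results/data/counts.tsv", md)
norm <- normalize_counts(counts)
tab <- de_table(norm, md$group)
scr <- de_screen(tab)

write.table(tab, file.path(out, "volcano.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scr$selected, file.path(out, "degs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d / %d genes pass the screen (%d up in feeding, %d up in control)\n",
            nrow(scr$selected), nrow(tab),
            scr$n_feeding_up, scr$n_control_up))
cat(sprintf("genes at nominal p < 0.05: %d; smallest q: %.3g\n",
            sum(tab$p_value < 0.05), min(tab$q_value)))
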