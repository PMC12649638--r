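#!/usr/bin/env Rscript
# Stage 5: co-expression module detection and module-trait inference.
#
# Pearson correlations across all network genes are converted to the
# unsigned distance 1-|r|, clustered with Ward.D2, cut into minimum-size
# modules, and merged while any eigengene pair correlates above r = 0.75.
# Module eigengenes are then correlated against the feeding indicator and
# the physiological traits with BH adjustment, and node/edge tables are
# exported. Module recovery is scored against the planted truth.

library(polypnet)

out <- "results/05_network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

md <- read_metadata("results/data/metadata.csv")
expr <- read_expression("results/data/expression.tsv", md)
physio <- read.csv("results/data/physiology.csv")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

res <- detect_modules(expr, top_n = 5000L, min_size = 30L)
sizes <- sort(table(res$labels[res$labels != "grey"]), decreasing = TRUE)
cat(sprintf("%d modules over %d network genes (%d grey); largest %s (%d, %.1f%%)\n",
            length(sizes), nrow(res$matrix), sum(res$labels == "grey"),
            names(sizes)[1], sizes[1], sizes[1] / nrow(res$matrix) * 100))

truth_net <- truth$gene_module[match(rownames(res$matrix),
                                     sprintf("gene%05d", seq_along(truth$gene_module)))]
cat(sprintf("adjusted Rand index vs planted modules: %.3f\n",
            mclust::adjustedRandIndex(res$labels, truth_net)))

traits <- cbind(data.frame(group = as.numeric(md$group == "feeding")),
                physio[vapply(physio, is.numeric, logical(1))])
mt <- module_trait(res$eigengenes, traits)
write.table(mt, file.path(out, "module_trait.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- mt[mt$significant, ]
cat(sprintf("%d / %d module-trait pairs significant at q < 0.05\n",
            nrow(sig), nrow(mt)))
if (nrow(sig)) print(sig[, c("module", "trait", "pearson_r", "q_value")],
                     digits = 3)
top <- mt[which.min(mt$q_value), ]
cat(sprintf("top module-trait pair: %s ~ %s (r = %.2f, p = %.3g, q = %.3g)\n",
            top$module, top$trait, top$pearson_r, top$p_value, top$q_value))

own <- res$kme[cbind(seq_along(res$labels),
                     match(res$labels, colnames(res$kme)))]
write.table(data.frame(gene = rownames(res$matrix), module = res$labels,
                       kme = ifelse(res$labels == "grey", NA, own)),
            file.path(out, "module_assignment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
nw <- export_network(res$R, res$labels, res$kme, edge_min_abs_r = 0.6)
write_network(nw, out)
cat(sprintf("exported %d nodes and %d edges (|r| >= 0.6)\n",
            nrow(nw$nodes), nrow(nw$edges)))
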