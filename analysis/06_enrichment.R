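#!/usr/bin/env Rscript
# Stage 6: hypergeometric term enrichment of the trait-associated module.
#
# A synthetic gene-term annotation (random background terms plus one term
# concentrated in the module most associated with feeding) stands in for a
# GO-style annotation; over-representation is tested with the
# hypergeometric upper tail and BH adjustment.

library(polypnet)

out <- "results/06_enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

md <- read_metadata("results/data/metadata.csv")
expr <- read_expression("results/data/expression.tsv", md)
assign_tab <- read.delim("results/05_network/module_assignment.tsv",
                         comment.char = "#")
mt <- read.delim("results/05_network/module_trait.tsv", comment.char = "#")

top_module <- mt$module[which.min(mt$q_value)]
query <- assign_tab$gene[assign_tab$module == top_module]
cat(sprintf("querying %d genes of module '%s'\n", length(query), top_module))

set.seed(99)
universe <- rownames(expr)
terms <- do.call(rbind, lapply(1:25, function(i)
  data.frame(gene = sample(universe, sample(50:300, 1)),
             term = sprintf("TERM%03d", i))))
focus <- data.frame(gene = unique(c(sample(query, ceiling(0.6 * length(query))),
                                    sample(universe, 40))),
                    term = "TERM_GROWTH")
ann <- annotation_map(rbind(terms, focus), universe = universe)

res <- enrich(query, ann)
write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("top terms:\n")
print(head(res, 5), digits = 3)
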