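#!/usr/bin/env Rscript
# Stage 1: generate the simulated study inputs.
#
# Emulates the feeding experiment's data layout: a 19,397-gene expression
# matrix (continuous log-scale plus Poisson counts) for 2 groups x 5
# replicates, with 5,000 genes carrying 13 planted co-expression modules in
# the reported size profile and one module tracking the feeding indicator;
# a physiological table drawn from the reported group means/SDs; and
# colorimetric assay plates with known standard curves.

library(polypnet)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
cfg <- sim_config(seed = seed)
print(cfg)

sim <- simulate_expression(cfg, counts = TRUE)
write_expression(sim$expr, file.path(out, "expression.tsv"))
write_expression(sim$counts, file.path(out, "counts.tsv"))
write.csv(sim$metadata, file.path(out, "metadata.csv"), row.names = FALSE)
jsonlite::write_json(list(gene_module = unname(sim$truth$gene_module),
                          de_genes = sim$truth$de_genes),
                     file.path(out, "truth.json"), digits = NA)

physio <- simulate_physiology(cfg)
write.csv(physio, file.path(out, "physiology.csv"), row.names = FALSE)

carb <- simulate_assay_plate(2, 0.1,
                             unknowns_conc = rnorm(10, 0.18, 0.02),
                             noise_sd = 0.004, seed = seed + 12L)
lipid <- simulate_assay_plate(1.5, 0.05,
                              unknowns_conc = rnorm(10, 0.22, 0.02),
                              noise_sd = 0.004, seed = seed + 13L)
write.csv(carb, file.path(out, "plate_carbohydrate.csv"), row.names = FALSE)
write.csv(lipid, file.path(out, "plate_lipid.csv"), row.names = FALSE)

cat(sprintf("wrote %d genes x %d samples and %d physiological traits to %s\n",
            nrow(sim$expr), ncol(sim$expr),
            sum(vapply(physio, is.numeric, logical(1))), out))
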