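#!/usr/bin/env Rscript
# Stage 3: routed two-group inference and PCA over the physiology table.
#
# Every trait is first checked for normality (Shapiro-Wilk, per group) and
# homogeneity of variance (Levene); conforming traits get a pooled-variance
# Student t, the rest a Mann-Whitney U. PCA summarizes the trait space.

library(polypnet)

physio <- read.csv("results/data/physiology.csv")
out <- "results/03_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- compare_groups_table(physio)
write.csv(tab, file.path(out, "group_tests.csv"), row.names = FALSE)
cat("routed comparisons:\n")
print(tab[, c("trait", "route", "p_value", "stars")], digits = 3)

traits <- physio[vapply(physio, is.numeric, logical(1))]
pca <- pca_traits(traits, standardize = TRUE)
print(pca)
write.csv(data.frame(component = seq_along(pca$variance_explained),
                     variance_explained_pct = pca$variance_explained),
          file.path(out, "pca_variance.csv"), row.names = FALSE)
write.csv(data.frame(variable = rownames(pca$loadings), pca$loadings),
          file.path(out, "pca_loadings.csv"), row.names = FALSE)
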