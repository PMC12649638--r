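#!/usr/bin/env Rscript
# Stage 2: physiological calculators and the cellular energy budget.
#
# Converts raw-style measurements into the reported quantities: symbiont
# density (cells cm-2), per-cell chlorophyll a+c2, the caspase-3 activation
# ratio, and the Ea/Ec/CEA chain quantified against the simulated standard
# curves.

library(polypnet)

data_dir <- "results/data"
out <- "results/02_physiology"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

physio <- read.csv(file.path(data_dir, "physiology.csv"))

caspase <- caspase_activation(physio$a405_host[physio$group == "feeding"],
                              physio$a405_host[physio$group == "control"])
cat(sprintf("caspase-3 activation level (feeding/control): %.3f\n", caspase))

# energy budget per sample from the shared plates (one unknown well each)
carb <- read.csv(file.path(data_dir, "plate_carbohydrate.csv"))
lipid <- read.csv(file.path(data_dir, "plate_lipid.csv"))
n_std <- sum(carb$role == "standard")
budgets <- do.call(rbind, lapply(seq_len(nrow(physio)), function(i) {
  cp <- carb[carb$role == "standard" | seq_len(nrow(carb)) == n_std + i, ]
  lp <- lipid[lipid$role == "standard" | seq_len(nrow(lipid)) == n_std + i, ]
  eb <- energy_budget(cp, lp, protein_mg = 0.5,
                      ets_slope = 0.016, ets_volume_l = 3e-4,
                      basis = "area_cm2", basis_value = 2)
  cbind(physio[i, c("sample", "group")], eb)
}))
write.csv(budgets, file.path(out, "energy_budget.csv"), row.names = FALSE)

cat(sprintf("mean Ea: control %.2f J, feeding %.2f J; mean CEA %.3g\n",
            mean(budgets$ea_joule[budgets$group == "control"]),
            mean(budgets$ea_joule[budgets$group == "feeding"]),
            mean(budgets$cea)))
writeLines(sprintf("caspase_activation\t%.6f", caspase),
           file.path(out, "caspase.tsv"))
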