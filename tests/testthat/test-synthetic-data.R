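test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 10, module_sizes = c(8, 8)), "n_genes")
  expect_error(sim_config(n_per_group = 1), "replicates")
  expect_error(sim_config(loading_range = c(0, 0.5)), "loading_range")
  expect_error(sim_config(loading_range = c(0.9, 0.5)), "loading_range")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(driven_module_index = 99), "driven_module_index")
})

test_that("zero-noise unit loadings give perfect within-module correlation", {
  cfg <- sim_config(n_genes = 40, module_sizes = c(10, 10), n_per_group = 4,
                    loading_range = c(1, 1), noise_sd = 0,
                    driven_module_index = 1, seed = 3)
  s <- simulate_expression(cfg)
  for (m in 1:2) {
    idx <- which(s$truth$gene_module == m)
    R <- cor(t(s$expr[idx, ]))
    expect_equal(abs(R), matrix(1, length(idx), length(idx)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # background genes are pure noise with zero planted loading
  expect_true(all(s$truth$gene_loading[s$truth$gene_module == 0] == 0))
})

test_that("default module size profile reproduces the reported fractions", {
  sizes <- default_module_sizes()
  expect_length(sizes, 13L)
  expect_identical(sum(sizes), 5000L)
  frac <- sizes / 5000 * 100
  expect_equal(frac[1:3], c(25.1, 24.52, 22.6), tolerance = 1e-8)
  expect_equal(frac[13], 0.96, tolerance = 1e-8)
  expect_true(all(diff(sizes) <= 0))
})

test_that("empirical gene-latent correlation matches the planted loading", {
  cfg <- sim_config(n_genes = 30, module_sizes = c(25L), n_per_group = 250,
                    loading_range = c(0.8, 0.8), trait_effect = 0,
                    driven_module_index = 1, seed = 11)
  s <- simulate_expression(cfg)
  e <- s$truth$eigengene_trajectories[1, ]
  r <- cor(t(s$expr[s$truth$gene_module == 1, ]), e)
  expect_true(all(abs(r - 0.8) < 0.05))
})

test_that("driven module latent is shifted between groups", {
  cfg <- sim_config(n_genes = 100, module_sizes = c(30, 30), n_per_group = 200,
                    trait_effect = 2, driven_module_index = 2, seed = 5)
  s <- simulate_expression(cfg)
  e <- s$truth$eigengene_trajectories
  shift2 <- mean(e[2, s$metadata$group == "feeding"]) -
    mean(e[2, s$metadata$group == "control"])
  shift1 <- mean(e[1, s$metadata$group == "feeding"]) -
    mean(e[1, s$metadata$group == "control"])
  expect_equal(shift2, 2, tolerance = 0.3)
  expect_equal(shift1, 0, tolerance = 0.3)
  expect_setequal(s$truth$de_genes,
                  names(which(s$truth$gene_module == 2)))
})

test_that("a fixed seed fixes every emitted table bit-for-bit", {
  cfg <- sim_config(n_genes = 200, module_sizes = c(40, 30), n_per_group = 5,
                    driven_module_index = 1, seed = 42)
  a <- simulate_expression(cfg, counts = TRUE)
  b <- simulate_expression(cfg, counts = TRUE)
  expect_identical(a, b)
  expect_identical(simulate_physiology(cfg), simulate_physiology(cfg))
  expect_identical(
    simulate_assay_plate(2, 0.1, unknowns_conc = 0.2, noise_sd = 0.01, seed = 9),
    simulate_assay_plate(2, 0.1, unknowns_conc = 0.2, noise_sd = 0.01, seed = 9))
})

test_that("physiology draws follow the configured group means", {
  cfg <- sim_config(n_genes = 10, module_sizes = 5L, n_per_group = 5,
                    driven_module_index = 1, seed = 2)
  tp <- default_trait_params()
  # degenerate normals collapse onto the group mean
  tp0 <- transform(tp, sd = 0)
  ph0 <- simulate_physiology(cfg, tp0)
  expect_equal(unique(ph0$diameter_d30[ph0$group == "feeding"]), 2650.70)
  expect_equal(unique(ph0$ea_host[ph0$group == "control"]), 26.92)
  # CLT bound at large n
  cfg_big <- sim_config(n_genes = 10, module_sizes = 5L, n_per_group = 10000,
                        driven_module_index = 1, seed = 2)
  ph <- simulate_physiology(cfg_big, tp)
  row <- tp[tp$trait == "diameter_d30" & tp$group == "feeding", ]
  expect_lt(abs(mean(ph$diameter_d30[ph$group == "feeding"]) - row$mean),
            3 * row$sd / 100)
  # the defaults carry the printed feeding-group diameter
  expect_true(any(tp$trait == "diameter_d30" & tp$group == "feeding" &
                    tp$mean == 2650.70 & tp$sd == 163.42))
  expect_error(simulate_physiology(cfg, data.frame(
    trait = "x", group = "treated", mean = 1, sd = 1)), "unknown group")
  expect_error(simulate_physiology(cfg, data.frame(
    trait = "x", group = "control", mean = 1, sd = -1)), "sd")
})

test_that("assay plates evaluate the true line and round-trip the fit", {
  p <- simulate_assay_plate(2, 0.1, unknowns_conc = 0.16, noise_sd = 0, seed = 1)
  expect_equal(p$absorbance[p$role == "unknown"], 0.42)
  expect_identical(sum(p$role == "standard"), 5L)
  expect_equal(p$true_concentration[p$role == "standard"],
               c(0, 0.08, 0.16, 0.24, 0.32))
  std <- p[p$role == "standard", ]
  curve <- fit_standard_curve(std$true_concentration, std$absorbance)
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 0.1, tolerance = 1e-12)
  expect_error(simulate_assay_plate(2, 0.1, noise_sd = -1), "noise_sd")
  expect_error(simulate_assay_plate(2, 0.1, standards = numeric(0)),
               "non-empty")
})

test_that("count emission is Poisson around the exponentiated signal", {
  cfg <- sim_config(n_genes = 500, module_sizes = 100L, n_per_group = 5,
                    driven_module_index = 1, seed = 8)
  s <- simulate_expression(cfg, counts = TRUE, count_log_mean = log(50))
  expect_true(all(s$counts >= 0))
  expect_true(all(s$counts == round(s$counts)))
  expect_equal(mean(s$counts), mean(exp(s$expr + log(50))), tolerance = 0.1)
})
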