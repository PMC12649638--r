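test_that("standard curves recover exact lines and report fit quality", {
  conc <- c(0, 0.08, 0.16, 0.24, 0.32)
  curve <- fit_standard_curve(conc, c(0.10, 0.26, 0.42, 0.58, 0.74))
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 0.10, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)

  two <- fit_standard_curve(c(0, 1), c(0, 1))
  expect_equal(two$slope, 1, tolerance = 1e-12)
  expect_equal(two$intercept, 0, tolerance = 1e-12)

  # adding a constant shifts only the intercept
  ab <- c(0.10, 0.26, 0.43, 0.55, 0.74)
  c1 <- fit_standard_curve(conc, ab)
  c2 <- fit_standard_curve(conc, ab + 0.5)
  expect_equal(c2$slope, c1$slope, tolerance = 1e-12)
  expect_equal(c2$intercept, c1$intercept + 0.5, tolerance = 1e-12)

  expect_error(fit_standard_curve(c(0.1, 0.1), c(1, 2)), "identical")
  expect_error(fit_standard_curve(0.1, 1), "two standard")
})

test_that("quantification inverts the fitted line", {
  curve <- fit_standard_curve(c(0, 0.08, 0.16, 0.24, 0.32),
                              c(0.10, 0.26, 0.42, 0.58, 0.74))
  expect_equal(quantify(curve, curve$intercept), 0)
  expect_equal(quantify(curve, 0.42), 0.16, tolerance = 1e-12)
  expect_equal(quantify(curve, 0.42, dilution_factor = 10), 1.6,
               tolerance = 1e-12)
  expect_warning(q <- quantify(curve, 0.05), "clamped")
  expect_identical(q, 0)
  bad <- curve; bad$slope <- 0
  expect_error(quantify(bad, 0.42), "zero")
})

test_that("Ea combines masses through the combustion enthalpies", {
  expect_identical(energy_available(0, 0, 0), 0)
  expect_equal(energy_available(1e-3, 1e-3, 1e-3), 81.0)
  a <- c(2e-3, 1e-3, 5e-4); b <- c(1e-3, 3e-3, 2e-3)
  expect_equal(energy_available(a[1], a[2], a[3]) +
                 energy_available(b[1], b[2], b[3]),
               energy_available(a[1] + b[1], a[2] + b[2], a[3] + b[3]))
  expect_error(energy_available(-1e-3, 0, 0), "non-negative")
  # constants are configuration, not hard-coded
  expect_equal(energy_available(1e-3, 0, 0,
                                energy_constants(carbohydrate = 20000)), 20)
})

test_that("Ec converts the kinetic slope through formazan stoichiometry", {
  expect_identical(energy_consumption(0, 3e-4), 0)
  # slope 0.0159 AU/min, V 3e-4 L, eps 0.0159 -> 3e-4 umol formazan/min,
  # 1.5e-4 umol O2/min, * 60 * 0.484 J/umol = 4.356e-3 J/h
  expect_equal(energy_consumption(0.0159, 3e-4, 1, 0.0159), 4.356e-3,
               tolerance = 1e-12)
  expect_equal(energy_consumption(0.0318, 3e-4, 1, 0.0159),
               2 * energy_consumption(0.0159, 3e-4, 1, 0.0159))
  expect_error(energy_consumption(-0.01, 3e-4), "negative")
  expect_error(energy_consumption(0.01, 0), "positive")
})

test_that("CEA is the Ea/Ec quotient and normalization cancels in it", {
  expect_equal(cea(10, 2), 5)
  expect_identical(cea(0, 2), 0)
  expect_error(cea(10, 0), "positive")
  ea <- 61.02; ec <- 0.004356
  for (basis_value in c(1, 2, 7.5)) {
    expect_equal(cea(as.numeric(normalize_energy(ea, basis_value)),
                     as.numeric(normalize_energy(ec, basis_value))),
                 cea(ea, ec))
  }
})

test_that("normalization divides by the basis and tags units", {
  v <- normalize_energy(61.02, 2, "area_cm2")
  expect_equal(as.numeric(v), 30.51)
  expect_identical(attr(v, "unit"), "J cm-2")
  p <- normalize_energy(12, 4, "polyps")
  expect_identical(attr(p, "unit"), "J polyp-1")
  expect_equal(as.numeric(normalize_energy(5, 1)), 5)
  expect_equal(
    as.numeric(normalize_energy(as.numeric(normalize_energy(30, 2)), 3)),
    as.numeric(normalize_energy(30, 6)))
  expect_error(normalize_energy(1, 0), "positive")
})

test_that("a noiseless simulated plate round-trips concentrations exactly", {
  unknowns <- c(0.05, 0.12, 0.21, 0.30)
  p <- simulate_assay_plate(1.8, 0.07, unknowns_conc = unknowns,
                            noise_sd = 0, seed = 4)
  std <- p[p$role == "standard", ]
  curve <- fit_standard_curve(std$true_concentration, std$absorbance)
  got <- quantify(curve, p$absorbance[p$role == "unknown"])
  expect_equal(got, unknowns, tolerance = 1e-9)
})

test_that("energy_budget chains plates to CEA per sample", {
  carb <- simulate_assay_plate(2, 0.1, unknowns_conc = 0.16, noise_sd = 0,
                               seed = 1)
  lipid <- simulate_assay_plate(1.5, 0.05, unknowns_conc = 0.20, noise_sd = 0,
                                seed = 2)
  eb <- energy_budget(carb, lipid, protein_mg = 0.5, assay_volume_ml = 1,
                      ets_slope = 0.0159, ets_volume_l = 3e-4,
                      basis = "area_cm2", basis_value = 2)
  expect_equal(eb$carbohydrate_mg, 0.16, tolerance = 1e-9)
  expect_equal(eb$lipid_mg, 0.20, tolerance = 1e-9)
  expect_equal(eb$ea_joule,
               energy_available(0.16e-3, 0.20e-3, 0.5e-3), tolerance = 1e-9)
  expect_equal(eb$ec_joule_per_h, 4.356e-3, tolerance = 1e-9)
  expect_equal(eb$cea, eb$ea_joule / eb$ec_joule_per_h)
  expect_equal(eb$ea_normalized, eb$ea_joule / 2)
})
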