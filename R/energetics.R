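#' Energetic conversion constants
#'
#' Combustion enthalpies for the three macromolecule classes (J per gram)
#' and the oxyenthalpic equivalent of oxygen (kJ per mol O2) used by the
#' cellular-energy-allocation calculations. All four are configurable.
#'
#' @param carbohydrate,lipid,protein combustion enthalpies, J g^-1.
#' @param oxygen_kj_mol oxyenthalpic equivalent, kJ mol^-1 O2.
#' @return named list of constants.
#' @export
energy_constants <- function(carbohydrate = 17500, lipid = 39500,
                             protein = 24000, oxygen_kj_mol = 484) {
  list(carbohydrate = carbohydrate, lipid = lipid, protein = protein,
       oxygen_kj_mol = oxygen_kj_mol)
}

#' Fit a colorimetric standard curve
#'
#' Ordinary least squares of absorbance on concentration, intercept
#' included (the blank well is part of the standard series).
#'
#' @param concentrations standard concentrations, mg mL^-1.
#' @param absorbances measured absorbances, AU.
#' @return object of class \code{standard_curve}: slope, intercept,
#'   r_squared, and the input points.
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances))
    stop("concentrations and absorbances must have equal length")
  if (length(concentrations) < 2L)
    stop("need at least two standard points")
  if (length(unique(concentrations)) < 2L)
    stop("standard concentrations are all identical; cannot fit a line")
  fit <- stats::lm(absorbances ~ concentrations)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 concentrations = concentrations,
                 absorbances = absorbances),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: absorbance = %.6g * conc + %.6g (r^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, length(x$concentrations)))
  invisible(x)
}

#' Quantify an unknown against a standard curve
#'
#' Inverts the fitted line; negative concentration estimates are clamped to
#' zero with a warning.
#'
#' @param curve a \code{standard_curve}.
#' @param absorbance unknown-well absorbance(s), AU.
#' @param dilution_factor multiplier restoring the pre-dilution
#'   concentration.
#' @return concentration(s), mg mL^-1.
#' @export
quantify <- function(curve, absorbance, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve slope is zero")
  conc <- dilution_factor * (absorbance - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative concentration estimate clamped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Energy available (Ea)
#'
#' Combined energetic value of the carbohydrate, lipid and protein reserves
#' via combustion-enthalpy conversion.
#'
#' @param carbohydrate_g,lipid_g,protein_g masses in grams.
#' @param constants see \code{\link{energy_constants}}.
#' @return Ea in joules.
#' @export
energy_available <- function(carbohydrate_g, lipid_g, protein_g,
                             constants = energy_constants()) {
  if (any(c(carbohydrate_g, lipid_g, protein_g) < 0))
    stop("masses must be non-negative")
  constants$carbohydrate * carbohydrate_g +
    constants$lipid * lipid_g +
    constants$protein * protein_g
}

#' Energy consumption (Ec) from ETS activity
#'
#' Converts the kinetic INT-formazan absorbance slope to an oxygen
#' consumption rate (2 formazan per O2) and then to joules per hour via the
#' oxyenthalpic equivalent.
#'
#' @param kinetic_slope absorbance increase, AU min^-1.
#' @param reaction_volume_l reaction volume in litres.
#' @param path_cm optical path length, cm.
#' @param epsilon molar absorptivity of INT-formazan in AU L umol^-1 cm^-1
#'   (default 0.0159, i.e. 15,900 L mol^-1 cm^-1).
#' @param constants see \code{\link{energy_constants}} (uses
#'   \code{oxygen_kj_mol}).
#' @return Ec in J h^-1.
#' @export
energy_consumption <- function(kinetic_slope, reaction_volume_l,
                               path_cm = 1, epsilon = 0.0159,
                               constants = energy_constants()) {
  if (any(kinetic_slope < 0))
    stop("negative kinetic slope: check the order of the kinetic reads")
  if (epsilon <= 0 || path_cm <= 0 || any(reaction_volume_l <= 0))
    stop("epsilon, path and volume must be positive")
  formazan_umol_min <- kinetic_slope * reaction_volume_l / (epsilon * path_cm)
  o2_umol_min <- formazan_umol_min / 2
  # umol/min * 60 min/h * (kJ/mol = J/mmol = 1e-3 J/umol)
  o2_umol_min * 60 * constants$oxygen_kj_mol * 1e-3
}

#' Cellular energy allocation (CEA)
#'
#' @param ea_joule energy available, J.
#' @param ec_joule_per_h energy consumption, J h^-1.
#' @return the ratio Ea/Ec.
#' @export
cea <- function(ea_joule, ec_joule_per_h) {
  if (any(ec_joule_per_h <= 0)) stop("Ec must be positive")
  ea_joule / ec_joule_per_h
}

#' Normalize an energetic quantity to a reference basis
#'
#' @param value the quantity (e.g. Ea in J).
#' @param basis_value surface area in cm^2 or polyp count.
#' @param basis \code{"area_cm2"} or \code{"polyps"}.
#' @return value / basis_value, with a \code{"unit"} attribute
#'   (\code{"J cm-2"} or \code{"J polyp-1"} for joule inputs).
#' @export
normalize_energy <- function(value, basis_value,
                             basis = c("area_cm2", "polyps")) {
  basis <- match.arg(basis)
  if (any(basis_value <= 0)) stop("basis_value must be positive")
  out <- value / basis_value
  attr(out, "unit") <- if (basis == "area_cm2") "J cm-2" else "J polyp-1"
  out
}

#' Energy budget from plate tables
#'
#' Convenience wrapper running the full quantification chain for one
#' sample: fit curves from standard wells, quantify unknowns, convert to
#' Ea/Ec/CEA and normalize.
#'
#' @param carb_plate,lipid_plate plate data.frames with columns role,
#'   true_concentration (standards), absorbance (see
#'   \code{\link{simulate_assay_plate}}).
#' @param protein_mg protein mass, mg (kit output consumed as-is).
#' @param assay_volume_ml volume of sample assayed, mL, used to convert
#'   concentration to mass.
#' @param ets_slope,ets_volume_l ETS kinetic slope (AU/min) and reaction
#'   volume (L).
#' @param basis,basis_value normalization basis, see
#'   \code{\link{normalize_energy}}.
#' @param constants see \code{\link{energy_constants}}.
#' @return one-row data.frame: masses (mg), ea_joule, ec_joule_per_h, cea,
#'   normalized values, basis.
#' @export
energy_budget <- function(carb_plate, lipid_plate, protein_mg,
                          assay_volume_ml = 1,
                          ets_slope, ets_volume_l,
                          basis = "area_cm2", basis_value = 1,
                          constants = energy_constants()) {
  read_plate_side <- function(plate) {
    std <- plate[plate$role == "standard", ]
    unk <- plate[plate$role == "unknown", ]
    if (nrow(unk) == 0L) stop("plate has no unknown wells")
    curve <- fit_standard_curve(std$true_concentration, std$absorbance)
    mean(quantify(curve, unk$absorbance))
  }
  carb_mg <- read_plate_side(carb_plate) * assay_volume_ml
  lipid_mg <- read_plate_side(lipid_plate) * assay_volume_ml
  ea <- energy_available(carb_mg * 1e-3, lipid_mg * 1e-3, protein_mg * 1e-3,
                         constants)
  ec <- energy_consumption(ets_slope, ets_volume_l, constants = constants)
  data.frame(carbohydrate_mg = carb_mg, lipid_mg = lipid_mg,
             protein_mg = protein_mg,
             ea_joule = ea, ec_joule_per_h = ec,
             cea = cea(ea, ec),
             ea_normalized = as.numeric(normalize_energy(ea, basis_value, basis)),
             ec_normalized = as.numeric(normalize_energy(ec, basis_value, basis)),
             basis = basis, basis_value = basis_value,
             stringsAsFactors = FALSE)
}
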