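#' Symbiont density per unit coral surface area
#'
#' @param total_cells symbiont cells counted, scaled to the whole
#'   homogenate; aliquot scaling is the caller's responsibility.
#' @param surface_area colony surface area in cm^2.
#' @return density in cells cm^-2.
#' @export
symbiont_density <- function(total_cells, surface_area) {
  if (any(surface_area <= 0)) stop("surface_area must be positive")
  if (any(total_cells < 0)) stop("cell counts cannot be negative")
  total_cells / surface_area
}

#' Spectrophotometric chlorophyll coefficients
#'
#' Dinoflagellate (chlorophyll a + c2) coefficients for acetone extracts:
#' chl a = 11.43 OD663 - 0.64 OD630, chl c2 = 27.09 OD630 - 3.63 OD663
#' (ug/mL). Exposed so alternative calibrations (e.g. for a different
#' solvent strength) can be substituted.
#'
#' @param a_663,a_630 chlorophyll-a equation coefficients on OD663, OD630.
#' @param c2_630,c2_663 chlorophyll-c2 equation coefficients.
#' @return named list of the four coefficients.
#' @export
chl_coefficients <- function(a_663 = 11.43, a_630 = -0.64,
                             c2_630 = 27.09, c2_663 = -3.63) {
  list(a_663 = a_663, a_630 = a_630, c2_630 = c2_630, c2_663 = c2_663)
}

#' Per-cell chlorophyll a + c2 content
#'
#' Converts two absorbance readings of an acetone extract to total
#' chlorophyll a + c2 and normalizes by the symbiont count. Negative
#' per-equation estimates (possible for near-blank readings) are clamped to
#' zero with a warning.
#'
#' @param od630,od663 absorbances of the extract.
#' @param extract_volume extract volume in mL.
#' @param cell_count symbiont cells the extract derives from.
#' @param coefficients see \code{\link{chl_coefficients}}.
#' @return chlorophyll content in pg cell^-1.
#' @export
chlorophyll_per_cell <- function(od630, od663, extract_volume, cell_count,
                                 coefficients = chl_coefficients()) {
  if (any(cell_count <= 0)) stop("cell_count must be positive")
  if (any(extract_volume <= 0)) stop("extract_volume must be positive")
  if (any(od630 < 0) || any(od663 < 0)) stop("absorbances must be non-negative")
  chl_a  <- coefficients$a_663 * od663 + coefficients$a_630 * od630
  chl_c2 <- coefficients$c2_630 * od630 + coefficients$c2_663 * od663
  if (any(chl_a < 0) || any(chl_c2 < 0)) {
    warning("negative chlorophyll estimate clamped to 0")
    chl_a <- pmax(chl_a, 0)
    chl_c2 <- pmax(chl_c2, 0)
  }
  # ug/mL * mL = ug; * 1e6 = pg
  (chl_a + chl_c2) * extract_volume * 1e6 / cell_count
}

#' Caspase-3 activation level
#'
#' Ratio of the mean A405 of the feeding group to the mean A405 of the
#' control group; values below 1 indicate suppressed apoptotic activity
#' under feeding.
#'
#' @param feeding_a405,control_a405 per-replicate A405 readings.
#' @return the activation ratio (unitless).
#' @export
caspase_activation <- function(feeding_a405, control_a405) {
  if (length(feeding_a405) == 0L || length(control_a405) == 0L)
    stop("both groups must be non-empty")
  mc <- mean(control_a405)
  if (mc <= 0) stop("control group mean A405 must be positive")
  mean(feeding_a405) / mc
}

#' Derive reported physiological quantities from a raw measurement table
#'
#' Batch wrapper: given one row per colony with raw fields, computes
#' symbiont density and per-cell chlorophyll; caspase activation is a
#' group-level quantity and is returned as an attribute.
#'
#' @param raw data.frame with columns colony, group, symbiont_count,
#'   surface_area, od630, od663, extract_volume, chl_cell_count, a405.
#' @return data.frame of derived per-colony quantities with the group-level
#'   caspase activation ratio attached as attribute
#'   \code{"caspase_activation"}.
#' @export
derive_physiology <- function(raw) {
  req <- c("colony", "group", "symbiont_count", "surface_area",
           "od630", "od663", "extract_volume", "chl_cell_count", "a405")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    colony = raw$colony,
    group = raw$group,
    symbiont_density_cells_cm2 = symbiont_density(raw$symbiont_count,
                                                  raw$surface_area),
    chlorophyll_pg_cell = chlorophyll_per_cell(raw$od630, raw$od663,
                                               raw$extract_volume,
                                               raw$chl_cell_count),
    stringsAsFactors = FALSE)
  attr(out, "caspase_activation") <-
    caspase_activation(raw$a405[raw$group == "feeding"],
                       raw$a405[raw$group == "control"])
  out
}
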