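#' Default planted module size profile
#'
#' Sizes of the 13 planted co-expression modules in the default simulation,
#' summing to the 5,000 genes that enter the network. The three largest
#' (1255, 1226, 1130) and the smallest (48) reproduce the reported size
#' profile of the study system; the intermediate nine are filled in as a
#' strictly decreasing sequence so the totals balance.
#'
#' @return Integer vector of 13 module sizes.
#' @export
default_module_sizes <- function() {
  c(1255L, 1226L, 1130L, 380L, 260L, 180L, 130L, 100L, 85L, 75L, 68L, 63L, 48L)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' study design: 2 groups x 5 replicates, 19,397 detected genes of which
#' 5,000 carry planted module structure, 13 modules with the reported size
#' profile, and one module whose latent trajectory is shifted between groups
#' so that it tracks the feeding indicator.
#'
#' @param n_genes total number of genes emitted.
#' @param module_sizes integer vector of planted module sizes; genes beyond
#'   \code{sum(module_sizes)} are unassigned background noise.
#' @param n_per_group replicates per group (control and feeding).
#' @param loading_range length-2 numeric in (0, 1]: per-gene loadings
#'   \code{a_g} are drawn uniformly from this interval.
#' @param trait_effect standardized mean shift of the driven module's latent
#'   eigengene trajectory in the feeding group (units of latent SD).
#' @param driven_module_index which module tracks the feeding indicator.
#' @param noise_sd scale of the residual term; 1 preserves the factor-model
#'   identity cor(x_g, e_m) = a_g, 0 makes within-module genes exact
#'   multiples of their latent.
#' @param background_sd amplitude of unassigned background genes (pure
#'   noise). The default 0.3 gives co-regulated genes markedly higher
#'   expression variance than flat background genes, so a
#'   top-variance filter selects the module-bearing genes into the
#'   network, as in real expression data.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 19397L,
                       module_sizes = default_module_sizes(),
                       n_per_group = 5L,
                       loading_range = c(0.6, 0.95),
                       trait_effect = 2,
                       driven_module_index = 4L,
                       noise_sd = 1,
                       background_sd = 0.3,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  module_sizes <- as.integer(module_sizes)
  n_per_group <- as.integer(n_per_group)
  if (any(module_sizes < 1L)) stop("module sizes must be positive")
  if (sum(module_sizes) > n_genes)
    stop("module_sizes sum to more than n_genes")
  if (n_per_group < 2L) stop("need at least 2 replicates per group")
  if (length(loading_range) != 2L ||
      loading_range[1] <= 0 || loading_range[2] > 1 ||
      loading_range[1] > loading_range[2])
    stop("loading_range must satisfy 0 < low <= high <= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (background_sd < 0) stop("background_sd must be non-negative")
  if (driven_module_index < 1L || driven_module_index > length(module_sizes))
    stop("driven_module_index out of range")
  structure(list(n_genes = n_genes,
                 module_sizes = module_sizes,
                 n_per_group = n_per_group,
                 loading_range = as.numeric(loading_range),
                 trait_effect = as.numeric(trait_effect),
                 driven_module_index = as.integer(driven_module_index),
                 noise_sd = as.numeric(noise_sd),
                 background_sd = as.numeric(background_sd),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genes: %d (%d in %d planted modules)\n",
              x$n_genes, sum(x$module_sizes), length(x$module_sizes)))
  cat(sprintf("  design: %d + %d samples (control + feeding)\n",
              x$n_per_group, x$n_per_group))
  cat(sprintf("  loadings U[%.2f, %.2f], residual sd %.2f\n",
              x$loading_range[1], x$loading_range[2], x$noise_sd))
  cat(sprintf("  driven module %d shifted %.1f SD in feeding group\n",
              x$driven_module_index, x$trait_effect))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Single-factor model per module: gene g in module m has, in sample s,
#' \deqn{x_{gs} = a_g e_{ms} + \sqrt{1 - a_g^2}\, \sigma \epsilon_{gs}}
#' with latent module trajectory e_m drawn standard normal per sample and
#' shifted by \code{trait_effect} in feeding samples for the driven module.
#' Background genes are pure noise. With \code{noise_sd = 1} the population
#' correlation between a gene and its latent equals its loading a_g, and the
#' within-module gene-gene correlation equals a_g a_h.
#'
#' @param config a \code{sim_config}.
#' @param counts if TRUE, additionally emit a count matrix via
#'   \code{Poisson(exp(x + count_log_mean))}.
#' @param count_log_mean baseline natural-log mean expression used only when
#'   \code{counts = TRUE}.
#' @return List with \code{expr} (genes x samples matrix), \code{metadata}
#'   (data.frame sample/group), \code{truth} (gene_module, gene_loading,
#'   eigengene_trajectories, de_genes) and, when requested, \code{counts}.
#' @export
simulate_expression <- function(config, counts = FALSE, count_log_mean = log(50)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_group
  samples <- c(sprintf("Control-%d", seq_len(config$n_per_group)),
               sprintf("Feeding-%d", seq_len(config$n_per_group)))
  group <- rep(c("control", "feeding"), each = config$n_per_group)
  k <- length(config$module_sizes)

  gene_module <- integer(config$n_genes)
  gene_module[seq_len(sum(config$module_sizes))] <-
    rep(seq_len(k), times = config$module_sizes)

  loading <- numeric(config$n_genes)
  in_mod <- gene_module > 0L
  loading[in_mod] <- stats::runif(sum(in_mod),
                                  config$loading_range[1],
                                  config$loading_range[2])

  # latent trajectories, one row per module
  e <- matrix(stats::rnorm(k * n), nrow = k, ncol = n)
  e[config$driven_module_index, group == "feeding"] <-
    e[config$driven_module_index, group == "feeding"] + config$trait_effect

  x <- matrix(stats::rnorm(config$n_genes * n), nrow = config$n_genes,
              ncol = n)
  x[!in_mod, ] <- config$background_sd * x[!in_mod, , drop = FALSE]
  x[in_mod, ] <- sqrt(1 - loading[in_mod]^2) * config$noise_sd * x[in_mod, ] +
    loading[in_mod] * e[gene_module[in_mod], , drop = FALSE]

  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  dimnames(x) <- list(genes, samples)
  rownames(e) <- sprintf("module%02d", seq_len(k))
  colnames(e) <- samples

  truth <- list(gene_module = stats::setNames(gene_module, genes),
                gene_loading = stats::setNames(loading, genes),
                eigengene_trajectories = e,
                de_genes = genes[gene_module == config$driven_module_index])
  out <- list(expr = x,
              metadata = data.frame(sample = samples, group = group,
                                    stringsAsFactors = FALSE),
              truth = truth)
  if (counts) {
    cm <- matrix(stats::rpois(length(x), exp(x + count_log_mean)),
                 nrow = nrow(x), dimnames = dimnames(x))
    out$counts <- cm
  }
  out
}

#' Default physiological trait parameter table
#'
#' Group means and SDs used by \code{\link{simulate_physiology}}; the values
#' are the printed control/feeding summaries of the feeding experiment
#' (diameter and polyp counts at the stated days, skeleton weight, symbiont
#' density, chlorophyll content, and host/symbiont energy reserves).
#' The printed "mean +/- x" values are treated as mean and SD.
#'
#' @return data.frame with columns trait, group, mean, sd, unit.
#' @export
default_trait_params <- function() {
  rbind(
    data.frame(trait = "diameter_d30",        group = c("control", "feeding"),
               mean = c(2419.40, 2650.70),    sd = c(137.26, 163.42),
               unit = "um"),
    data.frame(trait = "diameter_d60",        group = c("control", "feeding"),
               mean = c(2797.90, 3308.50),    sd = c(89.98, 331.11),
               unit = "um"),
    data.frame(trait = "polyp_number_d15",    group = c("control", "feeding"),
               mean = c(3.20, 4.00),          sd = c(0.60, 0.63),
               unit = "count"),
    data.frame(trait = "polyp_number_d60",    group = c("control", "feeding"),
               mean = c(6.10, 9.80),          sd = c(0.53, 1.93),
               unit = "count"),
    data.frame(trait = "skeleton_weight",     group = c("control", "feeding"),
               mean = c(0.00267, 0.0054),     sd = c(0.0002, 0.00036),
               unit = "g"),
    data.frame(trait = "symbiont_density",    group = c("control", "feeding"),
               mean = c(2.15e5, 2.57e5),      sd = c(0.10e5, 0.12e5),
               unit = "cells_cm2"),
    data.frame(trait = "chlorophyll_ac2",     group = c("control", "feeding"),
               mean = c(17.11, 19.05),        sd = c(1.49, 1.07),
               unit = "pg_cell"),
    data.frame(trait = "ea_host",             group = c("control", "feeding"),
               mean = c(26.92, 30.51),        sd = c(2.67, 1.52),
               unit = "J_cm2"),
    data.frame(trait = "ea_symbiont",         group = c("control", "feeding"),
               mean = c(9.31, 10.60),         sd = c(0.65, 0.76),
               unit = "J_cm2"),
    # raw caspase-substrate absorbances are not reported, only their group
    # ratio; these synthetic baselines give a suppressed (~0.7) ratio
    data.frame(trait = "a405_host",           group = c("control", "feeding"),
               mean = c(1.00, 0.70),          sd = c(0.08, 0.07),
               unit = "AU")
  )
}

#' Simulate a physiological measurement table
#'
#' Draws \code{n_per_group} normal deviates per trait and group from a
#' (trait, group, mean, sd) parameter table; deterministic under the
#' configuration seed.
#'
#' @param config a \code{sim_config} (uses \code{n_per_group} and
#'   \code{seed}).
#' @param trait_params parameter table; defaults to
#'   \code{\link{default_trait_params}}.
#' @return Wide data.frame: sample, group, then one numeric column per trait.
#' @export
simulate_physiology <- function(config, trait_params = default_trait_params()) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("trait", "group", "mean", "sd")
  if (!all(req %in% names(trait_params)))
    stop("trait_params needs columns trait, group, mean, sd")
  if (any(trait_params$sd < 0)) stop("sd must be non-negative")
  bad <- setdiff(unique(trait_params$group), c("control", "feeding"))
  if (length(bad))
    stop("unknown group label: ", paste(bad, collapse = ", "))

  set.seed(config$seed + 1L)
  m <- config$n_per_group
  samples <- c(sprintf("Control-%d", seq_len(m)),
               sprintf("Feeding-%d", seq_len(m)))
  out <- data.frame(sample = samples,
                    group = rep(c("control", "feeding"), each = m),
                    stringsAsFactors = FALSE)
  for (tr in unique(trait_params$trait)) {
    col <- rep(NA_real_, 2L * m)
    for (g in c("control", "feeding")) {
      row <- trait_params[trait_params$trait == tr & trait_params$group == g, ]
      if (nrow(row) == 0L) next
      col[out$group == g] <- stats::rnorm(m, row$mean[1], row$sd[1])
    }
    out[[tr]] <- col
  }
  out
}

#' Simulate an assay plate with a known standard curve
#'
#' Emits absorbances \code{slope * conc + intercept + noise} for the
#' standard series and for unknowns of known true concentration, as read by
#' the energetics quantification stage.
#'
#' @param slope,intercept true line parameters (AU per mg/mL, AU).
#' @param standards standard concentrations (mg/mL); default is the glucose
#'   series 0, 0.08, 0.16, 0.24, 0.32.
#' @param unknowns_conc true concentrations of unknown wells.
#' @param noise_sd absorbance noise SD (AU).
#' @param seed integer seed.
#' @return data.frame: well, role (standard/unknown), true_concentration,
#'   absorbance.
#' @export
simulate_assay_plate <- function(slope, intercept,
                                 standards = c(0, 0.08, 0.16, 0.24, 0.32),
                                 unknowns_conc = numeric(0),
                                 noise_sd = 0, seed = 1L) {
  if (length(standards) == 0L) stop("standards must be non-empty")
  if (any(standards < 0)) stop("standard concentrations must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  conc <- c(standards, unknowns_conc)
  role <- rep(c("standard", "unknown"),
              c(length(standards), length(unknowns_conc)))
  ab <- slope * conc + intercept + stats::rnorm(length(conc), 0, noise_sd)
  data.frame(well = sprintf("W%02d", seq_along(conc)),
             role = role,
             true_concentration = conc,
             absorbance = ab,
             stringsAsFactors = FALSE)
}
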