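#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run. Unknown keys are
#' rejected (the argument list is the schema) and every parameter is
#' echoed into the run manifest.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param simulate generate inputs with the synthetic-data module; when
#'   FALSE, \code{expression} and \code{metadata} paths are required.
#' @param expression,metadata,physiology,annotation optional input paths
#'   used when \code{simulate = FALSE}.
#' @param sim a \code{\link{sim_config}}; defaults to the study-scale
#'   design with the given seed.
#' @param network list of module-detection parameters (min_mean, top_n,
#'   cut_height, min_size, merge_r, edge_min_abs_r).
#' @param de list of screening parameters (lfc_threshold, q_threshold).
#' @param n_terms number of synthetic annotation terms when simulating.
#' @param alpha significance level used in reports.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = TRUE,
                            expression = NULL,
                            metadata = NULL,
                            physiology = NULL,
                            annotation = NULL,
                            sim = NULL,
                            network = list(),
                            de = list(),
                            n_terms = 25L,
                            alpha = 0.05) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  net_defaults <- list(min_mean = -Inf, top_n = 5000L, cut_height = NULL,
                       min_size = 30L, merge_r = 0.75, edge_min_abs_r = 0.6)
  de_defaults <- list(lfc_threshold = 1, q_threshold = 0.05)
  bad <- setdiff(names(network), names(net_defaults))
  if (length(bad)) stop("unknown network parameter(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(de), names(de_defaults))
  if (length(bad)) stop("unknown de parameter(s): ",
                        paste(bad, collapse = ", "))
  network <- utils::modifyList(net_defaults, network)
  de <- utils::modifyList(de_defaults, de)
  if (!simulate && (is.null(expression) || is.null(metadata)))
    stop("expression and metadata paths are required when simulate = FALSE")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 expression = expression, metadata = metadata,
                 physiology = physiology, annotation = annotation,
                 sim = sim, network = network, de = de,
                 n_terms = as.integer(n_terms), alpha = alpha),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}; a
#' \code{sim:} block is passed to \code{\link{sim_config}}. Unknown keys
#' in either block are rejected.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    bad <- setdiff(names(raw$sim), names(formals(sim_config)))
    if (length(bad)) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
    raw$sim <- do.call(sim_config, raw$sim)
  }
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

# deterministic synthetic gene-term annotation: random background terms
# plus one term concentrated in the supplied gene set
.synthetic_annotation <- function(universe, focus_genes, n_terms, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_terms), function(i) {
    size <- sample(20:120, 1)
    data.frame(gene = sample(universe, min(size, length(universe))),
               term = sprintf("TERM%03d", i), stringsAsFactors = FALSE)
  })
  if (length(focus_genes)) {
    focus <- unique(c(sample(focus_genes, ceiling(0.7 * length(focus_genes))),
                      sample(universe, 10)))
    rows <- c(rows, list(data.frame(gene = focus, term = "TERM_GROWTH",
                                    stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes the study stages in reporting order -- physiology, energetics,
#' group statistics and PCA, differential-expression screening,
#' co-expression module detection with module-trait inference, and term
#' enrichment -- writing every stage table, a JSON run manifest (package
#' version, parameters, seed, input checksums) and a plain-text summary
#' into \code{out_dir}. With \code{simulate = TRUE} in the configuration,
#' inputs are generated by the synthetic-data module and runs are
#' byte-identical for a fixed seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  manifest_path <- file.path(out_dir, "manifest.json")

  write_manifest <- function(extra = list()) {
    cfg <- unclass(config)
    cfg$sim <- unclass(cfg$sim)
    cfg$network$cut_height <- if (is.null(cfg$network$cut_height)) "auto"
                              else cfg$network$cut_height
    cfg$network$min_mean <- if (is.infinite(cfg$network$min_mean)) "none"
                            else cfg$network$min_mean
    manifest <- c(list(package = "polypnet",
                       version = as.character(utils::packageVersion("polypnet")),
                       seed = config$seed,
                       parameters = cfg,
                       stages_completed = completed),
                  extra)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  stage <- function(name, expr) {
    message(sprintf("[%s] start", name))
    res <- tryCatch(force(expr), error = function(e) {
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    completed <<- c(completed, name)
    message(sprintf("[%s] done", name))
    res
  }

  input_dir <- file.path(out_dir, "inputs")
  dir.create(input_dir, showWarnings = FALSE)

  inputs <- stage("inputs", {
    if (config$simulate) {
      sim <- simulate_expression(config$sim, counts = TRUE)
      physio <- simulate_physiology(config$sim)
      write_expression(sim$expr, file.path(input_dir, "expression.tsv"))
      write_expression(sim$counts, file.path(input_dir, "counts.tsv"))
      utils::write.table(sim$metadata, file.path(input_dir, "metadata.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
      utils::write.table(physio, file.path(input_dir, "physiology.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(gene_module = unname(sim$truth$gene_module),
             de_genes = sim$truth$de_genes),
        file.path(input_dir, "truth.json"), digits = NA)
      list(expr = sim$expr, counts = sim$counts, metadata = sim$metadata,
           physio = physio, truth = sim$truth)
    } else {
      md <- read_metadata(config$metadata)
      expr <- read_expression(config$expression, md)
      physio <- if (!is.null(config$physiology))
        utils::read.csv(config$physiology, stringsAsFactors = FALSE)
      list(expr = expr, counts = NULL, metadata = md, physio = physio,
           truth = NULL)
    }
  })

  stats_dir <- file.path(out_dir, "stats")
  dir.create(stats_dir, showWarnings = FALSE)
  caspase <- NA_real_
  group_table <- NULL
  if (!is.null(inputs$physio)) {
    group_table <- stage("group_stats", {
      tab <- compare_groups_table(inputs$physio, alpha = config$alpha)
      write_table_units(tab, file.path(stats_dir, "group_tests.tsv"),
        "routed two-group tests; means/sds in native trait units; stars: * p<0.05 ** p<0.01 *** p<0.001")
      traits <- inputs$physio[vapply(inputs$physio, is.numeric, logical(1))]
      pca <- pca_traits(traits, standardize = TRUE)
      write_table_units(
        data.frame(component = seq_along(pca$variance_explained),
                   variance_explained_pct = pca$variance_explained),
        file.path(stats_dir, "pca_variance.tsv"),
        "percent variance explained per principal component")
      write_table_units(
        data.frame(variable = rownames(pca$loadings),
                   round(pca$loadings, 6)),
        file.path(stats_dir, "pca_loadings.tsv"),
        "unit-norm loading vectors, largest entry per component positive")
      if ("a405_host" %in% names(inputs$physio)) {
        caspase <<- caspase_activation(
          inputs$physio$a405_host[inputs$physio$group == "feeding"],
          inputs$physio$a405_host[inputs$physio$group == "control"])
      }
      tab
    })
  }

  energy <- stage("energetics", {
    set.seed(config$seed + 11L)
    groups <- inputs$metadata$group
    # per-sample true concentrations (mg/mL), feeding group slightly higher
    carb_true <- stats::rnorm(length(groups), 0.16 + 0.03 * (groups == "feeding"), 0.01)
    lipid_true <- stats::rnorm(length(groups), 0.20 + 0.04 * (groups == "feeding"), 0.012)
    carb_plate <- simulate_assay_plate(2, 0.1, unknowns_conc = carb_true,
                                       noise_sd = 0.004,
                                       seed = config$seed + 12L)
    lipid_plate <- simulate_assay_plate(1.5, 0.05, unknowns_conc = lipid_true,
                                        noise_sd = 0.004,
                                        seed = config$seed + 13L)
    protein_mg <- stats::rnorm(length(groups), 0.50 + 0.05 * (groups == "feeding"), 0.03)
    ets_slope <- stats::rnorm(length(groups), 0.016, 0.0015)
    rows <- lapply(seq_along(groups), function(i) {
      cp <- carb_plate[carb_plate$role == "standard" |
                         seq_len(nrow(carb_plate)) ==
                           (sum(carb_plate$role == "standard") + i), ]
      lp <- lipid_plate[lipid_plate$role == "standard" |
                          seq_len(nrow(lipid_plate)) ==
                            (sum(lipid_plate$role == "standard") + i), ]
      eb <- energy_budget(cp, lp, protein_mg[i], assay_volume_ml = 1,
                          ets_slope = ets_slope[i], ets_volume_l = 3e-4,
                          basis = "area_cm2", basis_value = 2)
      cbind(data.frame(sample = inputs$metadata$sample[i],
                       group = groups[i], stringsAsFactors = FALSE), eb)
    })
    tab <- do.call(rbind, rows)
    en_dir <- file.path(out_dir, "energetics")
    dir.create(en_dir, showWarnings = FALSE)
    write_table_units(tab, file.path(en_dir, "energy_budget.tsv"),
      "masses mg | ea_joule J | ec_joule_per_h J/h | cea unitless | normalized J cm-2")
    tab
  })

  de_res <- NULL
  if (!is.null(inputs$counts)) {
    de_res <- stage("diffexpr", {
      norm <- normalize_counts(inputs$counts)
      tab <- de_table(norm, inputs$metadata$group,
                      lfc_threshold = config$de$lfc_threshold,
                      q_threshold = config$de$q_threshold)
      scr <- de_screen(tab)
      de_dir <- file.path(out_dir, "de")
      dir.create(de_dir, showWarnings = FALSE)
      write_table_units(tab, file.path(de_dir, "volcano.tsv"),
        "log2fc = log2(Feeding/Control) | p, q unitless | selected: |log2fc|>1 & q<0.05")
      list(table = tab, screen = scr)
    })
  }

  net <- stage("coexpression", {
    res <- detect_modules(inputs$expr,
                          min_mean = config$network$min_mean,
                          top_n = config$network$top_n,
                          cut_height = config$network$cut_height,
                          min_size = config$network$min_size,
                          merge_r = config$network$merge_r)
    traits <- data.frame(group = as.numeric(inputs$metadata$group == "feeding"))
    if (!is.null(inputs$physio)) {
      num <- inputs$physio[vapply(inputs$physio, is.numeric, logical(1))]
      traits <- cbind(traits, num)
    }
    mt <- module_trait(res$eigengenes, traits, alpha = config$alpha)
    nw <- export_network(res$R, res$labels, res$kme,
                         edge_min_abs_r = config$network$edge_min_abs_r)
    net_dir <- file.path(out_dir, "network")
    dir.create(net_dir, showWarnings = FALSE)
    own <- res$kme[cbind(seq_along(res$labels),
                         match(res$labels, colnames(res$kme)))]
    write_table_units(
      data.frame(gene = rownames(res$matrix), module = res$labels,
                 kme = ifelse(res$labels == "grey", NA, own)),
      file.path(net_dir, "module_assignment.tsv"),
      "gene | module color (grey = unassigned) | own-module kME")
    write_table_units(mt, file.path(net_dir, "module_trait.tsv"),
      "Pearson r | p from t-transform | q = BH over all pairs | significant: q<0.05")
    me_wide <- data.frame(module = rownames(res$eigengenes),
                          round(res$eigengenes, 6), check.names = FALSE)
    write_table_units(me_wide, file.path(net_dir, "eigengenes.tsv"),
      "module eigengenes, unit variance across samples")
    r_mat <- stats::reshape(mt[, c("module", "trait", "pearson_r")],
                            idvar = "module", timevar = "trait",
                            direction = "wide")
    write_table_units(r_mat, file.path(net_dir, "module_trait_r_matrix.tsv"),
      "heatmap-ready module x trait Pearson r values")
    write_network(nw, net_dir)
    list(modules = res, module_trait = mt, network = nw)
  })

  enr <- stage("enrichment", {
    universe <- rownames(inputs$expr)
    top_pair <- net$module_trait[which.min(net$module_trait$q_value), ]
    focus <- rownames(net$modules$matrix)[net$modules$labels == top_pair$module]
    pairs <- if (!is.null(config$annotation)) read_annotation(config$annotation)
             else .synthetic_annotation(universe, focus, config$n_terms,
                                        config$seed + 21L)
    ann <- annotation_map(pairs, universe = universe)
    query <- if (!is.null(de_res) && nrow(de_res$screen$selected) > 0L)
      de_res$screen$selected$gene else focus
    tab <- enrich(query, ann)
    enr_dir <- file.path(out_dir, "enrichment")
    dir.create(enr_dir, showWarnings = FALSE)
    write_table_units(tab, file.path(enr_dir, "enrichment.tsv"),
      "k query hits | K term size | n query size | N universe | hypergeometric upper-tail p | BH q")
    tab
  })

  stage("summary", {
    con <- file(file.path(out_dir, "summary.txt"), "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("Feeding-experiment pipeline summary (seed %d)", config$seed)
    w("")
    if (!is.null(group_table)) {
      w("Growth and physiology (routed two-group tests):")
      for (i in seq_len(nrow(group_table)))
        w("  %-20s %-13s p = %.4g %s", group_table$trait[i],
          group_table$route[i], group_table$p_value[i], group_table$stars[i])
      w("")
    }
    w("Energetics (simulated plate chain): mean CEA control %.3g, feeding %.3g",
      mean(energy$cea[energy$group == "control"]),
      mean(energy$cea[energy$group == "feeding"]))
    if (!is.na(caspase))
      w("Immunity: caspase-3 activation level (feeding/control) = %.3f", caspase)
    w("")
    if (!is.null(de_res))
      w("DEGs: %d selected (|log2FC| > %g & q < %g); %d up in feeding, %d up in control",
        nrow(de_res$screen$selected), config$de$lfc_threshold,
        config$de$q_threshold, de_res$screen$n_feeding_up,
        de_res$screen$n_control_up)
    sizes <- table(net$modules$labels[net$modules$labels != "grey"])
    sizes <- sort(sizes, decreasing = TRUE)
    w("Modules: %d detected (%s)", length(sizes),
      paste(sprintf("%s %d", names(sizes), sizes), collapse = ", "))
    sig <- net$module_trait[net$module_trait$significant, ]
    if (nrow(sig))
      for (i in seq_len(nrow(sig)))
        w("Module-trait: %s ~ %s r = %.3f q = %.3g", sig$module[i],
          sig$trait[i], sig$pearson_r[i], sig$q_value[i])
    else w("Module-trait: no pair significant at q < %.2f", config$alpha)
    w("Top enriched term: %s (p = %.3g)", enr$term[1], enr$p_value[1])
    invisible(NULL)
  })

  input_files <- list.files(input_dir, full.names = TRUE)
  sums <- tools::md5sum(input_files)
  names(sums) <- file.path("inputs", basename(input_files))
  write_manifest(list(input_checksums = as.list(sums)))
  invisible(out_dir)
}
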