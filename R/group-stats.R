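#' Normality- and homogeneity-routed two-group comparison
#'
#' Reproduces the routed inference procedure used for the physiological
#' variables: Shapiro-Wilk normality per group and Levene's test for
#' homogeneity of variance across groups; when every assumption p-value is
#' at or above \code{alpha_assumptions}, a two-sided pooled-variance
#' Student's t-test is run, otherwise a two-sided Mann-Whitney U test
#' (exact when both groups have at most 8 untied observations, normal
#' approximation with tie/continuity correction otherwise).
#'
#' @param a,b numeric samples for the two groups (conventionally control
#'   and feeding).
#' @param alpha significance level for the final comparison.
#' @param alpha_assumptions level for the assumption checks.
#' @param levene_center \code{"mean"} for the original Levene form
#'   (default) or \code{"median"} for the Brown-Forsythe variant.
#' @param trait optional variable name carried into the result.
#' @return object of class \code{group_test}: trait, route
#'   (\code{"student_t"} or \code{"mann_whitney"}), statistic, p_value,
#'   assumption p-values, group summaries, significance flag.
#' @export
compare_groups <- function(a, b, alpha = 0.05, alpha_assumptions = 0.05,
                           levene_center = c("mean", "median"),
                           trait = NA_character_) {
  levene_center <- match.arg(levene_center)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")

  sw_p <- function(x) {
    # a constant vector is maximally non-normal for routing purposes
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  sw_a <- sw_p(a)
  sw_b <- sw_p(b)
  lev <- tryCatch({
    values <- c(a, b)
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    tab <- car::leveneTest(values, g, center = levene_center)
    p <- tab[1, "Pr(>F)"]
    if (is.na(p)) 1 else p  # zero residual spread in both groups
  }, error = function(e) 0)

  if (sw_a >= alpha_assumptions && sw_b >= alpha_assumptions &&
      lev >= alpha_assumptions) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    route <- "student_t"
  } else {
    small <- length(a) <= 8L && length(b) <= 8L
    ties <- anyDuplicated(c(a, b)) > 0L
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = small && !ties, correct = TRUE))
    route <- "mann_whitney"
  }
  structure(list(trait = trait,
                 route = route,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 shapiro_p = c(a = sw_a, b = sw_b),
                 levene_p = lev,
                 mean = c(a = mean(a), b = mean(b)),
                 sd = c(a = stats::sd(a), b = stats::sd(b)),
                 n = c(a = length(a), b = length(b)),
                 alpha = alpha,
                 significant = ht$p.value < alpha),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: %s, statistic = %.4g, p = %.4g%s\n",
              if (is.na(x$trait)) "two-group comparison" else x$trait,
              x$route, x$statistic, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05,
#'   "" otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Routed comparisons for every trait of a physiology table
#'
#' @param physio wide data.frame with a \code{group} column (control /
#'   feeding) and numeric trait columns.
#' @param alpha,alpha_assumptions see \code{\link{compare_groups}}.
#' @return data.frame: one row per trait with route, statistic, p, group
#'   means/sds and significance stars.
#' @export
compare_groups_table <- function(physio, alpha = 0.05,
                                 alpha_assumptions = 0.05) {
  if (!"group" %in% names(physio)) stop("physio needs a 'group' column")
  traits <- names(physio)[vapply(physio, is.numeric, logical(1))]
  traits <- setdiff(traits, c("sample", "group"))
  if (length(traits) == 0L) stop("no numeric trait columns found")
  rows <- lapply(traits, function(tr) {
    r <- compare_groups(physio[[tr]][physio$group == "control"],
                        physio[[tr]][physio$group == "feeding"],
                        alpha = alpha, alpha_assumptions = alpha_assumptions,
                        trait = tr)
    data.frame(trait = tr, route = r$route,
               statistic = r$statistic, p_value = r$p_value,
               control_mean = r$mean[["a"]], control_sd = r$sd[["a"]],
               feeding_mean = r$mean[["b"]], feeding_sd = r$sd[["b"]],
               n_control = r$n[["a"]], n_feeding = r$n[["b"]],
               stars = significance_stars(r$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values): q_(i) = min_{j >= i}
#' min(p_(j) m / j, 1), returned in the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values of the same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Principal component analysis of a trait table
#'
#' Centered (and by default standardized) PCA with a reproducible sign
#' convention: each loading column is flipped so its largest-magnitude
#' entry is positive. Rows with missing values are dropped listwise.
#'
#' @param table samples x variables numeric data.frame or matrix.
#' @param standardize scale columns to unit variance before the SVD.
#' @return object of class \code{pca_result}: variance_explained (percent,
#'   summing to 100), loadings (variables x components, unit columns),
#'   scores (samples x components).
#' @export
pca_traits <- function(table, standardize = TRUE) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("table must be numeric")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 complete samples and 2 variables")
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0))
    stop("constant variable(s) cannot be standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pr <- stats::prcomp(x, center = TRUE, scale. = standardize)
  ve <- pr$sdev^2 / sum(pr$sdev^2) * 100
  rot <- pr$rotation
  sco <- pr$x
  for (k in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, k]))
    if (rot[top, k] < 0) {
      rot[, k] <- -rot[, k]
      sco[, k] <- -sco[, k]
    }
  }
  structure(list(variance_explained = ve, loadings = rot, scores = sco,
                 standardized = standardize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", paste(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                            x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}
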