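#' Library-size normalization to log2 counts per million
#'
#' value = log2(count / library_size * 1e6 + 1). This simple CPM transform
#' stands in for a model-based normalization; the downstream screening rule
#' is applied unchanged.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @return matrix of log2(CPM + 1) values with the same dimnames.
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
}

#' Per-gene differential expression table
#'
#' For each gene, log2 fold change = mean(feeding) - mean(control) on the
#' log2 scale, a two-sided Welch t-test p-value, and Benjamini-Hochberg
#' q-values over all tested genes. A gene is selected by the screening rule
#' |log2FC| > 1 and q < 0.05 (both strict). A gene with zero variance in
#' both groups gets p = 1 when the group means are equal and p = 0
#' otherwise (the noiseless limit of the t-test).
#'
#' @param norm_matrix genes x samples matrix of normalized log2 expression.
#' @param groups character vector per sample, values in
#'   \{"control", "feeding"\}.
#' @param lfc_threshold,q_threshold screening thresholds.
#' @return data.frame: gene, log2fc, p_value, q_value, selected, direction
#'   ("feeding_up" when log2fc > 0, else "control_up").
#' @export
de_table <- function(norm_matrix, groups, lfc_threshold = 1,
                     q_threshold = 0.05) {
  norm_matrix <- as.matrix(norm_matrix)
  if (length(groups) != ncol(norm_matrix))
    stop("groups must have one entry per sample")
  bad <- setdiff(unique(groups), c("control", "feeding"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  A <- norm_matrix[, groups == "feeding", drop = FALSE]
  B <- norm_matrix[, groups == "control", drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")

  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  lfc <- ma - mb

  se2 <- va / na + vb / nb
  tt <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               1)
  p <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), df),
              0)
  p[se2 == 0 & lfc == 0] <- 1
  q <- benjamini_hochberg(p)

  genes <- rownames(norm_matrix)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(norm_matrix)))
  data.frame(gene = genes,
             log2fc = lfc,
             p_value = p,
             q_value = q,
             selected = abs(lfc) > lfc_threshold & q < q_threshold,
             direction = ifelse(lfc > 0, "feeding_up", "control_up"),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Screen a differential-expression table
#'
#' @param results a \code{\link{de_table}} data.frame with q-values
#'   populated.
#' @return list: \code{selected} (the selected subset), \code{n_feeding_up}
#'   and \code{n_control_up} (directional counts partitioning the subset).
#' @export
de_screen <- function(results) {
  if (nrow(results) > 0L && anyNA(results$q_value))
    stop("q_values must be populated")
  sel <- results[isTRUE_vec(results$selected), , drop = FALSE]
  list(selected = sel,
       n_feeding_up = sum(sel$direction == "feeding_up"),
       n_control_up = sum(sel$direction == "control_up"))
}

# vectorised isTRUE guard against NA selection flags
isTRUE_vec <- function(x) !is.na(x) & x
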