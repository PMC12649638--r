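#' Module color palette
#'
#' Size-ranked module color names, assigned in order of decreasing module
#' size; "grey" is reserved for unassigned genes.
#'
#' @param k number of colors requested.
#' @return character vector of k color names (falling back to
#'   \code{moduleNN} beyond the named palette).
#' @export
module_colors <- function(k) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen",
           "darkturquoise", "darkgrey", "orange", "darkorange", "skyblue",
           "saddlebrown", "steelblue", "paleturquoise")
  if (k <= length(pal)) pal[seq_len(k)]
  else c(pal, sprintf("module%02d", seq_len(k - length(pal)) + length(pal)))
}

#' Filter genes for network construction
#'
#' Drops genes whose mean expression falls below \code{min_mean}, then
#' keeps the \code{top_n} most variable of the survivors.
#'
#' @param norm_matrix genes x samples matrix of normalized expression.
#' @param min_mean minimum mean expression to retain a gene.
#' @param top_n number of genes kept by variance rank (all, with a
#'   warning, if fewer survive the mean filter).
#' @return the reduced matrix.
#' @export
filter_genes <- function(norm_matrix, min_mean = 0, top_n = 5000L) {
  norm_matrix <- as.matrix(norm_matrix)
  keep <- rowMeans(norm_matrix) >= min_mean
  m <- norm_matrix[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no genes left after the mean filter")
  if (top_n < nrow(m)) {
    v <- apply(m, 1, stats::var)
    ord <- order(v, decreasing = TRUE)
    m <- m[sort(ord[seq_len(top_n)]), , drop = FALSE]
  } else if (top_n > nrow(m)) {
    warning("top_n exceeds the number of genes after the mean filter; keeping all")
  }
  m
}

#' Gene-gene correlation and unsigned distance matrices
#'
#' Pairwise Pearson correlations across samples and the unsigned network
#' distance D = 1 - |r|.
#'
#' @param mat genes x samples matrix; every gene must vary across samples.
#' @return list with \code{R} (correlations, unit diagonal) and \code{D}
#'   (distances in [0, 1], zero diagonal).
#' @export
correlation_and_distance <- function(mat) {
  mat <- as.matrix(mat)
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(mat)[v == 0], 5), collapse = ", "),
         " (filter before building the network)")
  R <- stats::cor(t(mat))
  D <- 1 - abs(R)
  D[D < 0] <- 0
  diag(D) <- 0
  list(R = R, D = D)
}

#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering by Ward's minimum variance criterion in its
#' Ward.D2 form: the Lance-Williams recurrence is applied to squared
#' distances and merge heights are reported unsquared. At every step the
#' minimum-distance pair is merged, ties broken by the lexicographically
#' lowest pair of cluster ids (leaves 1..n, then n+step).
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return object of class \code{ward_linkage}: \code{merge} (hclust
#'   convention: negative entries are leaves, positive entries earlier
#'   merge steps), \code{height}, \code{size} (merged cluster sizes),
#'   \code{labels}, \code{n}.
#' @export
ward_linkage <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  res <- .ward_linkage_cpp(D)
  structure(list(merge = res$merge,
                 height = as.numeric(res$height),
                 size = as.integer(res$size),
                 labels = rownames(D),
                 n = nrow(D)),
            class = "ward_linkage")
}

#' @export
print.ward_linkage <- function(x, ...) {
  cat(sprintf("Ward.D2 linkage over %d leaves (%d merges, heights %.4g .. %.4g)\n",
              x$n, x$n - 1L, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a ward_linkage to an hclust object
#'
#' @param x a \code{ward_linkage}.
#' @param ... unused.
#' @return a \code{stats::hclust} object (for plotting and
#'   cross-validation against other tooling).
#' @export
as.hclust.ward_linkage <- function(x, ...) {
  ord <- integer(0)
  collect <- function(node) {
    # iterative leaf collection in dendrogram order
    stack <- node
    out <- integer(0)
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (nd < 0) out <- c(out, -nd)
      else stack <- c(stack, x$merge[nd, 2], x$merge[nd, 1])
    }
    out
  }
  ord <- collect(nrow(x$merge))
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "ward.D2",
                 call = match.call(), dist.method = "1-|r|"),
            class = "hclust")
}

# leaves under each requested internal node; roots is a vector of merge
# steps (positive) or leaves (negative)
.collect_leaves <- function(merge, node) {
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nd < 0) out <- c(out, -nd)
    else stack <- c(stack, merge[nd, 1], merge[nd, 2])
  }
  out
}

# color labels by decreasing cluster size, ties by smallest member index;
# clusters is a list of integer leaf-index vectors
.rank_and_color <- function(clusters, n) {
  labels <- rep("grey", n)
  if (length(clusters) == 0L) return(labels)
  sizes <- lengths(clusters)
  first <- vapply(clusters, min, integer(1))
  ord <- order(-sizes, first)
  cols <- module_colors(length(clusters))
  for (i in seq_along(ord)) labels[clusters[[ord[i]]]] <- cols[i]
  labels
}

#' Cut a dendrogram into minimum-size modules
#'
#' Simplified dynamic cut: leaf sets whose internal merges all lie below
#' \code{cut_height} form candidate clusters; clusters smaller than
#' \code{min_size} are left unassigned ("grey"); each kept cluster is then
#' recursively split at its top internal merge whenever both children
#' reach \code{min_size} and that merge is clearly higher than the
#' children's own internal structure (a branch-separation gap of factor
#' \code{split_gap}), repeated until stable. The gap condition keeps
#' homogeneous clusters intact while separating distinct branches that a
#' high static cut would lump together. Modules are named by decreasing
#' size from the fixed color palette.
#'
#' @param linkage a \code{\link{ward_linkage}}.
#' @param cut_height static cut height; defaults to the 0.99 quantile of
#'   the merge heights.
#' @param min_size minimum module size (>= 2).
#' @param split_gap refinement splits a cluster only when its top merge
#'   height is at least \code{split_gap} times the higher of its
#'   children's top internal heights (and positive).
#' @return character vector of module colors per gene ("grey" =
#'   unassigned), with the cut height used stored in attribute
#'   \code{"cut_height"}.
#' @export
cut_dendrogram <- function(linkage, cut_height = NULL, min_size = 30L,
                           split_gap = 2) {
  stopifnot(inherits(linkage, "ward_linkage"))
  if (min_size < 2L) stop("min_size must be at least 2")
  h <- linkage$height
  m <- linkage$merge
  n <- linkage$n
  if (is.null(cut_height))
    cut_height <- stats::quantile(h, 0.99, names = FALSE)
  if (cut_height <= 0) stop("cut_height must be positive")

  below <- h < cut_height
  # parent merge step of each internal node (0 for the root)
  parent <- integer(n - 1L)
  for (s in seq_len(n - 1L)) {
    for (child in m[s, ]) if (child > 0) parent[child] <- s
  }
  # component tops: below-cut merges whose parent is above the cut or absent
  tops <- which(below & (parent == 0L | !below[pmax(parent, 1L)]))

  # node sizes for the split rule
  node_size <- integer(n - 1L)
  for (s in seq_len(n - 1L))
    node_size[s] <- sum(ifelse(m[s, ] < 0, 1L, node_size[pmax(m[s, ], 1L)]))

  clusters <- list()
  refine <- function(node) {
    # node: positive merge step or negative leaf
    if (node < 0) {
      clusters[[length(clusters) + 1L]] <<- -node
      return(invisible(NULL))
    }
    c1 <- m[node, 1]; c2 <- m[node, 2]
    s1 <- if (c1 < 0) 1L else node_size[c1]
    s2 <- if (c2 < 0) 1L else node_size[c2]
    h1 <- if (c1 < 0) 0 else h[c1]
    h2 <- if (c2 < 0) 0 else h[c2]
    separated <- h[node] > 0 && h[node] >= split_gap * max(h1, h2)
    if (s1 >= min_size && s2 >= min_size && separated) {
      refine(c1); refine(c2)
    } else {
      clusters[[length(clusters) + 1L]] <<- .collect_leaves(m, node)
    }
    invisible(NULL)
  }
  for (s in tops) refine(s)

  clusters <- clusters[lengths(clusters) >= min_size]
  labels <- .rank_and_color(clusters, n)
  names(labels) <- linkage$labels
  attr(labels, "cut_height") <- cut_height
  labels
}

#' Module eigengenes
#'
#' For every non-grey module, genes are z-scored across samples and the
#' module eigengene is the first principal component over samples, scaled
#' to unit variance and oriented so it correlates non-negatively with the
#' module's mean standardized expression. The fraction of module variance
#' the eigengene explains is recorded.
#'
#' @param mat genes x samples matrix.
#' @param labels per-gene module colors (same order as \code{mat} rows).
#' @return list: \code{eigengenes} (modules x samples matrix, rows named
#'   by color ordered by the palette rank), \code{var_explained} (named
#'   fraction per module).
#' @export
module_eigengenes <- function(mat, labels) {
  mat <- as.matrix(mat)
  if (length(labels) != nrow(mat))
    stop("labels must have one entry per gene")
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(match(mods, module_colors(length(mods) + 26L)))]
  if (length(mods) == 0L) stop("no assigned modules")
  ns <- ncol(mat)
  z <- t(scale(t(mat)))
  me <- matrix(NA_real_, nrow = length(mods), ncol = ns,
               dimnames = list(mods, colnames(mat)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    sub <- z[labels == mod, , drop = FALSE]
    if (nrow(sub) == 1L) {
      warning("module '", mod, "' has a single gene; eigengene is its z-profile")
      v1 <- as.numeric(sub[1, ])
      v1 <- v1 / stats::sd(v1)
      ve[mod] <- 1
    } else {
      sv <- svd(sub, nu = 0, nv = 1)
      v1 <- sv$v[, 1] * sqrt(ns - 1)  # unit variance (v1 has zero mean)
      ve[mod] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (stats::cor(v1, colMeans(sub)) < 0) v1 <- -v1
    me[mod, ] <- v1
  }
  list(eigengenes = me, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the largest eigengene Pearson
#' correlation while it exceeds \code{r_threshold}, recomputing eigengenes
#' after each merge; unassigned (grey) genes never merge. Final labels are
#' re-colored by size rank, so on exit no eigengene pair has
#' r > \code{r_threshold}.
#'
#' @param mat genes x samples matrix.
#' @param labels module colors from \code{\link{cut_dendrogram}}.
#' @param r_threshold merge when eigengene r exceeds this (default 0.75).
#' @return merged, size-ranked color labels.
#' @export
merge_modules <- function(mat, labels, r_threshold = 0.75) {
  labels <- as.character(labels)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    me <- module_eigengenes(mat, labels)$eigengenes
    C <- stats::cor(t(me))
    diag(C) <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (C[best[1], best[2]] <= r_threshold) break
    a <- rownames(C)[min(best)]
    b <- rownames(C)[max(best)]
    labels[labels == b] <- a
  }
  clusters <- lapply(setdiff(unique(labels), "grey"),
                     function(mod) which(labels == mod))
  out <- .rank_and_color(clusters, length(labels))
  names(out) <- names(labels)
  out
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene's profile with every module
#' eigengene.
#'
#' @param mat genes x samples matrix.
#' @param eigengenes modules x samples matrix (from
#'   \code{\link{module_eigengenes}}).
#' @return genes x modules kME matrix.
#' @export
kme <- function(mat, eigengenes) {
  mat <- as.matrix(mat)
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(mat)[v == 0], 5), collapse = ", "))
  stats::cor(t(mat), t(eigengenes))
}

#' Module-trait association
#'
#' Pearson correlation between every module eigengene and every numeric
#' trait, p-values from the t-transform t = r sqrt(n-2)/sqrt(1-r^2), and
#' Benjamini-Hochberg q-values over all module x trait pairs; a pair is
#' significant when q < 0.05. Shapiro-Wilk normality of each eigengene and
#' trait is recorded as a warning flag, not a gate.
#'
#' @param eigengenes modules x samples matrix.
#' @param traits data.frame of numeric traits, one row per sample in the
#'   same order (the group indicator encoded 0 = control, 1 = feeding).
#' @param alpha significance level on the adjusted values.
#' @return data.frame: module, trait, pearson_r, p_value, q_value,
#'   significant, me_nonnormal, trait_nonnormal.
#' @export
module_trait <- function(eigengenes, traits, alpha = 0.05) {
  traits <- as.data.frame(traits)
  if (!all(vapply(traits, is.numeric, logical(1))))
    stop("all traits must be numeric")
  ns <- ncol(eigengenes)
  if (nrow(traits) != ns) stop("traits must have one row per sample")
  if (ns < 4L) stop("need at least 4 samples")
  const <- vapply(traits, function(x) stats::var(x) == 0, logical(1))
  if (any(const))
    stop("constant trait(s): ", paste(names(traits)[const], collapse = ", "))

  sw_flag <- function(x) {
    p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
    p < 0.05
  }
  me_flags <- apply(eigengenes, 1, sw_flag)
  tr_flags <- vapply(traits, sw_flag, logical(1))

  grid <- expand.grid(module = rownames(eigengenes), trait = names(traits),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- mapply(function(mod, tr) stats::cor(eigengenes[mod, ], traits[[tr]]),
              grid$module, grid$trait)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(ns - 2) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(is.finite(tt), 2 * stats::pt(-abs(tt), ns - 2), 0)
  q <- benjamini_hochberg(p)
  data.frame(module = grid$module, trait = grid$trait,
             pearson_r = unname(r), p_value = unname(p), q_value = q,
             significant = q < alpha,
             me_nonnormal = unname(me_flags[grid$module]),
             trait_nonnormal = unname(tr_flags[grid$trait]),
             stringsAsFactors = FALSE)
}

#' Export node and edge tables for network visualization
#'
#' @param R gene-gene correlation matrix.
#' @param labels per-gene module colors.
#' @param kme_table genes x modules kME matrix.
#' @param edge_min_abs_r minimum |r| for a within-module edge.
#' @return list: \code{nodes} (gene, module, kme; ordered by module rank
#'   then gene index) and \code{edges} (gene_a, gene_b, module, weight =
#'   |r|; same deterministic order).
#' @export
export_network <- function(R, labels, kme_table, edge_min_abs_r = 0.6) {
  genes <- rownames(R)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(R)))
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(match(mods, module_colors(length(mods) + 26L)))]

  nodes <- list(); edges <- list()
  for (mod in mods) {
    idx <- which(labels == mod)
    nodes[[mod]] <- data.frame(gene = genes[idx], module = mod,
                               kme = kme_table[idx, mod],
                               stringsAsFactors = FALSE)
    if (length(idx) >= 2L) {
      pairs <- which(upper.tri(R[idx, idx, drop = FALSE]) &
                       abs(R[idx, idx, drop = FALSE]) >= edge_min_abs_r,
                     arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(pairs[, 1], pairs[, 2])
        pairs <- pairs[ord, , drop = FALSE]
        edges[[mod]] <- data.frame(
          gene_a = genes[idx[pairs[, 1]]],
          gene_b = genes[idx[pairs[, 2]]],
          module = mod,
          weight = abs(R[idx, idx, drop = FALSE][pairs]),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_nodes <- data.frame(gene = character(0), module = character(0),
                            kme = numeric(0), stringsAsFactors = FALSE)
  empty_edges <- data.frame(gene_a = character(0), gene_b = character(0),
                            module = character(0), weight = numeric(0),
                            stringsAsFactors = FALSE)
  list(nodes = if (length(nodes)) do.call(rbind, c(nodes, list(make.row.names = FALSE))) else empty_nodes,
       edges = if (length(edges)) do.call(rbind, c(edges, list(make.row.names = FALSE))) else empty_edges)
}

#' Full module-detection pipeline
#'
#' filter -> correlation/distance -> Ward.D2 -> minimum-size cut ->
#' eigengene merge -> kME, in one call.
#'
#' @param norm_matrix genes x samples normalized expression matrix.
#' @param min_mean,top_n see \code{\link{filter_genes}}.
#' @param cut_height,min_size see \code{\link{cut_dendrogram}}.
#' @param merge_r see \code{\link{merge_modules}}.
#' @return list: \code{matrix} (filtered), \code{R}, \code{D},
#'   \code{linkage}, \code{labels} (post-merge), \code{eigengenes},
#'   \code{var_explained}, \code{kme}.
#' @export
detect_modules <- function(norm_matrix, min_mean = -Inf, top_n = 5000L,
                           cut_height = NULL, min_size = 30L,
                           merge_r = 0.75) {
  m <- filter_genes(norm_matrix, min_mean = min_mean, top_n = top_n)
  cd <- correlation_and_distance(m)
  link <- ward_linkage(cd$D)
  raw <- cut_dendrogram(link, cut_height = cut_height, min_size = min_size)
  labels <- merge_modules(m, raw, r_threshold = merge_r)
  me <- module_eigengenes(m, labels)
  list(matrix = m, R = cd$R, D = cd$D, linkage = link,
       raw_labels = raw, labels = labels,
       eigengenes = me$eigengenes, var_explained = me$var_explained,
       kme = kme(m, me$eigengenes))
}
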