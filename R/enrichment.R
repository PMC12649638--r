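#' Build an annotation map from a gene-term table
#'
#' @param pairs data.frame with columns gene and term (one association per
#'   row); empty terms are dropped.
#' @param universe optional character vector of annotatable genes; defaults
#'   to every gene appearing in \code{pairs}.
#' @return object of class \code{annotation_map}: named list term -> gene
#'   set plus the universe.
#' @export
annotation_map <- function(pairs, universe = NULL) {
  if (!all(c("gene", "term") %in% names(pairs)))
    stop("pairs needs 'gene' and 'term' columns")
  if (is.null(universe)) universe <- unique(pairs$gene)
  bad <- setdiff(unique(pairs$gene), universe)
  if (length(bad))
    stop("annotation references genes outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  terms <- split(pairs$gene, pairs$term)
  terms <- lapply(terms, unique)
  terms <- terms[lengths(terms) > 0L]
  structure(list(terms = terms, universe = unique(universe)),
            class = "annotation_map")
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, the upper-tail hypergeometric probability
#' P(X >= k) of observing k query genes in the term, with N the universe
#' size, K the term size and n the query size; Benjamini-Hochberg q-values
#' are reported across terms.
#'
#' @param query_genes character vector of genes of interest; genes outside
#'   the universe are dropped with a warning.
#' @param annotation an \code{\link{annotation_map}}.
#' @param universe_override optional replacement universe.
#' @return data.frame sorted by p (ties by term id): term, k, K, n, N,
#'   p_value, q_value.
#' @export
enrich <- function(query_genes, annotation, universe_override = NULL) {
  stopifnot(inherits(annotation, "annotation_map"))
  universe <- if (is.null(universe_override)) annotation$universe
              else unique(universe_override)
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("empty query after universe intersection")

  N <- length(universe)
  n <- length(query)
  terms <- names(annotation$terms)
  K <- vapply(annotation$terms,
              function(g) length(intersect(g, universe)), integer(1))
  k <- vapply(annotation$terms,
              function(g) length(intersect(g, query)), integer(1))
  # P(X >= k) with X ~ Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- benjamini_hochberg(p)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    p_value = p, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$term), , drop = FALSE]
}
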