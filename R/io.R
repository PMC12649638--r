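#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file with gene ids in the first column and one
#' column per sample. When metadata is supplied, samples are checked
#' against it and reordered to the metadata order.
#'
#' @param path TSV path.
#' @param metadata optional data.frame with a \code{sample} column.
#' @return numeric genes x samples matrix.
#' @export
read_expression <- function(path, metadata = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5),
               collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric expression column(s): ",
         paste(names(df[-1])[bad], collapse = ", "))
  }
  rownames(m) <- genes
  if (!is.null(metadata)) {
    miss <- setdiff(metadata$sample, colnames(m))
    if (length(miss))
      stop("metadata sample(s) missing from expression header: ",
           paste(miss, collapse = ", "))
    m <- m[, metadata$sample, drop = FALSE]
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param mat genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path CSV with at least \code{sample} and \code{group} columns;
#'   group values must be "control" or "feeding".
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(md)))
    stop("metadata needs 'sample' and 'group' columns")
  bad <- setdiff(unique(md$group), c("control", "feeding"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  md
}

#' Read a gene-term annotation table (two-column TSV or GMT)
#'
#' @param path a two-column tab-delimited file (gene, term) or, when the
#'   extension is \code{.gmt}, a GMT file (term, description,
#'   genes...).
#' @return data.frame with columns gene and term.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    rows <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) return(NULL)
      data.frame(gene = f[-(1:2)], term = f[1], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no usable GMT records in ", path)
    return(out)
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation TSV needs two columns (gene, term)")
  names(df)[1:2] <- c("gene", "term")
  df[, c("gene", "term")]
}

# tab-delimited writer with a unit/description header comment line
write_table_units <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) writeLines(paste0("# ", units), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write node and edge tables (TSV and SIF)
#'
#' @param network list with \code{nodes} and \code{edges} from
#'   \code{\link{export_network}}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(dir, "nodes.tsv")
  ep <- file.path(dir, "edges.tsv")
  sp <- file.path(dir, "network.sif")
  write_table_units(network$nodes, np,
                    "gene | module color | kME (unitless Pearson r)")
  write_table_units(network$edges, ep,
                    "gene pair | module color | weight = |r| (unitless)")
  writeLines(sprintf("%s pp %s", network$edges$gene_a, network$edges$gene_b),
             sp)
  invisible(c(np, ep, sp))
}
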