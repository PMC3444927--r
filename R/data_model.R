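# Domain types and file I/O.  Every downstream stage consumes the validated
# containers built here; validation is strict and never coerces silently.

#' Construct a validated expression dataset
#'
#' Bundles a genes x samples expression matrix (assumed already normalized,
#' typically on a log scale -- the package performs no normalization) with a
#' per-sample design table.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers, colnames sample identifiers.
#' @param design Data frame with one row per sample and columns `sample`,
#'   `condition`, and optionally `time` (integer time-point index) and
#'   `replicate`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` and `design`.
#' @export
expression_dataset <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifier: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier")
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite expression values; impute or filter upstream")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(design)))
    stop("design must have columns `sample` and `condition`")
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample))
    stop("design maps a sample to more than one row")
  missing_design <- setdiff(colnames(values), design$sample)
  if (length(missing_design))
    stop("samples absent from design: ", paste(missing_design, collapse = ", "))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (!"time" %in% names(design)) design$time <- NA_integer_
  if (!"replicate" %in% names(design)) design$replicate <- NA_integer_
  if (!all(is.na(design$time))) design$time <- as.integer(design$time)
  if (!all(is.na(design$replicate))) design$replicate <- as.integer(design$replicate)
  structure(list(values = values, design = design), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  conds <- table(x$design$condition)
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("conditions:", paste(sprintf("%s (n=%d)", names(conds), conds), collapse = ", "), "\n")
  if (!all(is.na(x$design$time)))
    cat("time points:", length(unique(x$design$time)), "\n")
  invisible(x)
}

#' List the condition labels of a dataset
#' @param dataset An `expression_dataset`.
#' @return Character vector of unique condition labels.
#' @export
conditions <- function(dataset) unique(dataset$design$condition)

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix and design table from delimited text
#'
#' The matrix file has gene identifiers in the first column and a header row
#' of sample identifiers; TSV or CSV is chosen by file extension.  The design
#' table has columns `sample`, `condition` and optionally `time`,
#' `replicate`.  Samples present in the matrix but absent from the design are
#' an error, as are duplicate genes, non-numeric cells and missing values.
#'
#' @param matrix_path Path to the expression matrix.
#' @param design_path Path to the design table.
#' @return An [expression_dataset].
#' @export
read_expression_table <- function(matrix_path, design_path) {
  raw <- read.delim(matrix_path, sep = delim_for(matrix_path),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression matrix needs a gene column plus samples")
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric cells in expression matrix")
  rownames(mat) <- genes
  design <- read.delim(design_path, sep = delim_for(design_path),
                       check.names = FALSE, stringsAsFactors = FALSE)
  expression_dataset(mat, design)
}

#' Write a dataset back to matrix + design text files
#'
#' Inverse of [read_expression_table()]; round-trips values within text
#' precision (15 significant digits).
#'
#' @param dataset An `expression_dataset`.
#' @param matrix_path,design_path Output paths; extension picks TSV vs CSV.
#' @export
write_expression_table <- function(dataset, matrix_path, design_path) {
  df <- data.frame(gene = rownames(dataset$values),
                   format(dataset$values, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write.table(df, matrix_path, sep = delim_for(matrix_path),
              quote = FALSE, row.names = FALSE)
  keep <- c("sample", "condition",
            if (!all(is.na(dataset$design$time))) "time",
            if (!all(is.na(dataset$design$replicate))) "replicate")
  write.table(dataset$design[, keep, drop = FALSE], design_path,
              sep = delim_for(design_path), quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Construct a weighted undirected network
#'
#' @param nodes Character vector of node (gene) identifiers.
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight` and
#'   optionally `provenance` (the condition(s) an edge was called significant
#'   in, or `"differential"`).  Self-edges and duplicate edges are rejected;
#'   weights must be finite.
#' @return An object of class `rif_network`.
#' @export
rif_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifier")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), provenance = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b", "weight") %in% names(edges)))
      stop("edges need columns gene_a, gene_b, weight")
    if (!"provenance" %in% names(edges)) edges$provenance <- NA_character_
    edges <- edges[, c("gene_a", "gene_b", "weight", "provenance")]
    if (any(edges$gene_a == edges$gene_b)) stop("self-edge not allowed")
    bad <- setdiff(c(edges$gene_a, edges$gene_b), nodes)
    if (length(bad)) stop("edge endpoint not in node list: ", paste(bad, collapse = ", "))
    if (any(!is.finite(edges$weight))) stop("non-finite edge weight")
    # canonical orientation so duplicates are detectable regardless of order
    flip <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[flip]
    edges$gene_a[flip] <- edges$gene_b[flip]
    edges$gene_b[flip] <- tmp
    if (anyDuplicated(edges[, c("gene_a", "gene_b")])) stop("duplicate edge")
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "rif_network")
}

#' @export
print.rif_network <- function(x, ...) {
  cat(sprintf("rif_network: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Per-node degree of a network
#' @param network An `rif_network`.
#' @return Named integer vector over all nodes (isolated nodes included, 0).
#' @export
network_degree <- function(network) {
  deg <- structure(integer(length(network$nodes)), names = network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$gene_a, network$edges$gene_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b", "weight", "provenance")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

#' Write a network as a TSV edge list or GraphML
#'
#' @param network An `rif_network`.
#' @param path Output path.
#' @param format `"tsv"` (columns gene_a, gene_b, weight, provenance) or
#'   `"graphml"` (Cytoscape-ready, via igraph).
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (!inherits(network, "rif_network")) stop("not an rif_network")
  if (format == "tsv") {
    write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(NULL)
}

#' Read a TSV edge list written by [write_network()]
#'
#' @param path Edge-list path.
#' @param nodes Optional full node universe (isolated nodes are not
#'   recoverable from an edge list alone).
#' @return An `rif_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  rif_network(nodes, edges)
}
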