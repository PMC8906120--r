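#' Construct a clustered expression object
#'
#' A `clustered_expression` bundles a cells x genes non-negative expression
#' matrix (raw counts or pre-normalized values) with a per-cell cluster label.
#' Cells with a missing cluster label are dropped with a message. The matrix
#' may be a base matrix or a sparse [Matrix::Matrix]; it is stored as given.
#'
#' @param mat cells x genes numeric matrix; rownames are cell ids and colnames
#'   gene symbols (generated when absent).
#' @param cluster_labels character/factor vector, one label per cell.
#' @param is_normalized `TRUE` when the values are already normalized (e.g.
#'   upstream log-normalization); raw counts are validated as finite and >= 0.
#' @return object of class `clustered_expression`: a list with elements
#'   `matrix`, `gene_names`, `cell_ids`, `cluster_labels`, `is_normalized`.
#' @export
clustered_expression <- function(mat, cluster_labels, is_normalized = FALSE) {
  if (length(cluster_labels) != nrow(mat))
    stop("cluster_labels length (", length(cluster_labels),
         ") must equal the number of cells (rows, ", nrow(mat), ")")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("cell", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("gene", seq_len(ncol(mat)))
  cluster_labels <- as.character(cluster_labels)
  drop <- is.na(cluster_labels) | !nzchar(cluster_labels)
  if (any(drop)) {
    message("clustered_expression: dropping ", sum(drop),
            " cell(s) with missing cluster label")
    mat <- mat[!drop, , drop = FALSE]
    cluster_labels <- cluster_labels[!drop]
  }
  if (!is_normalized) {
    v <- if (is(mat, "sparseMatrix")) mat@x else as.numeric(as_dense(mat))
    if (length(v) && (any(!is.finite(v)) || any(v < 0)))
      stop("raw count matrix must be finite and non-negative")
  }
  structure(list(matrix = mat,
                 gene_names = colnames(mat),
                 cell_ids = rownames(mat),
                 cluster_labels = cluster_labels,
                 is_normalized = is_normalized),
            class = "clustered_expression")
}

#' @export
print.clustered_expression <- function(x, ...) {
  cat("clustered_expression:", length(x$cell_ids), "cells x",
      length(x$gene_names), "genes;",
      length(unique(x$cluster_labels)), "clusters;",
      if (x$is_normalized) "normalized" else "raw counts", "\n")
  invisible(x)
}

#' Read cluster labels from a two-column CSV
#'
#' @param path CSV with header and columns `cell_id`, `cluster` (extra columns
#'   ignored).
#' @return named character vector of cluster labels keyed by cell id.
#' @export
read_cluster_labels <- function(path) {
  if (!file.exists(path)) stop("cluster label file not found: ", path)
  tab <- data.table::fread(path, data.table = FALSE)
  miss <- setdiff(c("cell_id", "cluster"), names(tab))
  if (length(miss)) stop("cluster label file missing column(s): ",
                         paste(miss, collapse = ", "))
  stats::setNames(as.character(tab$cluster), as.character(tab$cell_id))
}

#' Read a sparse matrix-market expression matrix with sidecar files
#'
#' Reads the conventional MTX triplet layout: the matrix itself, a gene file
#' (one symbol per line, or first column of a delimited file) and a barcode
#' file, plus a cluster-label CSV (see [read_cluster_labels]).
#'
#' @param mtx_path matrix-market file.
#' @param genes_path,barcodes_path plain-text sidecars.
#' @param clusters_path two-column CSV (`cell_id`, `cluster`).
#' @param orientation `"genes_by_cells"` (the common convention; transposed on
#'   load) or `"cells_by_genes"`.
#' @return a [clustered_expression] of raw counts.
#' @export
read_mtx_expression <- function(mtx_path, genes_path, barcodes_path, clusters_path,
                                orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  for (p in c(mtx_path, genes_path, barcodes_path, clusters_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  genes <- data.table::fread(genes_path, header = FALSE, data.table = FALSE)[[1]]
  cells <- data.table::fread(barcodes_path, header = FALSE, data.table = FALSE)[[1]]
  if (orientation == "genes_by_cells") m <- Matrix::t(m)
  m <- methods::as(m, "CsparseMatrix")
  if (nrow(m) != length(cells) || ncol(m) != length(genes))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match barcodes (", length(cells), ") x genes (", length(genes), ")")
  dimnames(m) <- list(cells, genes)
  labels <- read_cluster_labels(clusters_path)
  missing_cells <- setdiff(cells, names(labels))
  lab <- unname(labels[cells])
  clustered_expression(m, lab, is_normalized = FALSE)
}

#' Write a clustered expression object as MTX + sidecars
#'
#' Emits `matrix.mtx` (genes x cells, the common convention), `genes.tsv`,
#' `barcodes.tsv` and `clusters.csv` into `dir` — the same layout
#' [read_mtx_expression] consumes.
#' @param expr a [clustered_expression].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mtx_expression <- function(expr, dir) {
  stopifnot(inherits(expr, "clustered_expression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::t(Matrix::Matrix(as_dense(expr$matrix), sparse = TRUE)),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(expr$gene_names, file.path(dir, "genes.tsv"))
  writeLines(expr$cell_ids, file.path(dir, "barcodes.tsv"))
  write_csv_atomic(data.frame(cell_id = expr$cell_ids, cluster = expr$cluster_labels),
                   file.path(dir, "clusters.csv"))
  invisible(dir)
}

#' Read a dense CSV expression matrix
#'
#' @param path CSV with a header row and the first column holding row names.
#' @param clusters_path two-column CSV (`cell_id`, `cluster`).
#' @param orientation whether rows of the CSV are cells or genes.
#' @param is_normalized pass `TRUE` when the file holds already-normalized
#'   values.
#' @return a [clustered_expression].
#' @export
read_dense_expression <- function(path, clusters_path,
                                  orientation = c("cells_by_genes", "genes_by_cells"),
                                  is_normalized = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- data.table::fread(path, data.table = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (orientation == "genes_by_cells") m <- t(m)
  labels <- read_cluster_labels(clusters_path)
  clustered_expression(m, unname(labels[rownames(m)]), is_normalized = is_normalized)
}
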