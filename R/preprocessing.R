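#' Library-size normalize and log-transform a raw count matrix
#'
#' Scales each cell so that its counts sum to `scale_factor`, then applies
#' `log(1 + x)` — the de-facto standard normalization in single-cell
#' workflows. If expression was normalized upstream by another recipe, build
#' the [clustered_expression] with `is_normalized = TRUE` and skip this step.
#'
#' @param expr a raw-count [clustered_expression].
#' @param scale_factor target per-cell total before the log transform
#'   (default 10000).
#' @return a [clustered_expression] with `is_normalized = TRUE`.
#' @export
normalize_cells <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "clustered_expression"))
  if (expr$is_normalized)
    stop("expression is already normalized; normalize_cells expects raw counts")
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be a positive number")
  totals <- Matrix::rowSums(expr$matrix)
  zero <- totals == 0
  if (any(zero))
    stop("cell(s) with zero total counts cannot be normalized: ",
         paste(utils::head(expr$cell_ids[zero], 5), collapse = ", "))
  m <- expr$matrix / totals * scale_factor
  m <- log1p(m)
  if (is(expr$matrix, "sparseMatrix")) m <- methods::as(m, "CsparseMatrix")
  out <- expr
  out$matrix <- m
  out$is_normalized <- TRUE
  out
}

#' Gene-wise z-scores across all cells
#'
#' Centers and scales each gene column across the whole system (all cells),
#' using the sample standard deviation (n - 1 denominator, matching the
#' upstream single-cell ecosystem). Zero-variance genes map to all-zero
#' columns. Optionally truncates extreme values to `[-clip, clip]`.
#'
#' @param expr a normalized [clustered_expression].
#' @param clip optional positive number; when set, z-scores are truncated.
#' @return dense cells x genes matrix of z-scores.
#' @export
zscale_genes <- function(expr, clip = NULL) {
  stopifnot(inherits(expr, "clustered_expression"))
  if (!expr$is_normalized)
    stop("zscale_genes expects normalized expression (run normalize_cells first)")
  if (!is.null(clip) && (!is.numeric(clip) || clip <= 0))
    stop("clip must be a positive number")
  m <- as_dense(expr$matrix)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)       # sample SD, n - 1
  z <- sweep(m, 2, mu, "-")
  pos <- s > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, s[pos], "/")
  z[, !pos] <- 0
  if (!is.null(clip)) z <- pmin(pmax(z, -clip), clip)
  z
}

#' Per-cluster, per-gene summary profile
#'
#' Reduces a normalized, clustered expression matrix to the node-level
#' statistics every edge is built from: the mean normalized expression, the
#' mean system-wide z-scored expression, the fraction of cells expressing
#' (value > 0), and the two-sided one-vs-rest Wilcoxon rank-sum p-value of the
#' gene in each cluster versus all other retained cells (raw, plus a
#' Benjamini-Hochberg-adjusted column computed within each cluster).
#'
#' Clusters with fewer than `min_cells_per_ident` cells are removed before any
#' statistic (including z-scaling) is computed.
#'
#' @param expr a normalized [clustered_expression].
#' @param min_cells_per_ident minimum cluster size to retain (default 0).
#' @param clip optional z-score truncation, passed to [zscale_genes].
#' @return object of class `cluster_profile`: list with ordered `clusters`,
#'   `genes`, clusters x genes matrices `mean_norm`, `mean_scaled`,
#'   `frac_expr`, `pval`, `pval_adj`, and named vector `cells_per_cluster`.
#' @export
cluster_profile <- function(expr, min_cells_per_ident = 0, clip = NULL) {
  stopifnot(inherits(expr, "clustered_expression"))
  if (!expr$is_normalized)
    stop("cluster_profile expects normalized expression (run normalize_cells first)")
  if (min_cells_per_ident < 0) stop("min_cells_per_ident must be >= 0")
  labels <- expr$cluster_labels
  sizes <- table(labels)
  keep_cl <- names(sizes)[sizes >= max(1, min_cells_per_ident)]
  if (length(keep_cl) < 2)
    stop("fewer than 2 clusters have >= ", min_cells_per_ident,
         " cells; cannot profile the system")
  keep <- labels %in% keep_cl
  sub <- expr
  sub$matrix <- expr$matrix[keep, , drop = FALSE]
  sub$cluster_labels <- labels[keep]
  sub$cell_ids <- expr$cell_ids[keep]
  labels <- factor(sub$cluster_labels, levels = sort(keep_cl))
  m <- as_dense(sub$matrix)
  z <- zscale_genes(sub, clip = clip)
  cl <- levels(labels)
  group_means <- function(x) {
    t(vapply(cl, function(ci) colMeans(x[labels == ci, , drop = FALSE]),
             numeric(ncol(x))))
  }
  mean_norm <- group_means(m)
  mean_scaled <- group_means(z)
  frac_expr <- group_means((m > 0) * 1)
  pval <- one_vs_rest_pvalues(m, labels)
  pval_adj <- t(apply(pval, 1, stats::p.adjust, method = "BH"))
  dn <- list(cl, sub$gene_names)
  dimnames(mean_norm) <- dimnames(mean_scaled) <- dimnames(frac_expr) <- dn
  dimnames(pval) <- dimnames(pval_adj) <- dn
  structure(list(clusters = cl,
                 genes = sub$gene_names,
                 mean_norm = mean_norm,
                 mean_scaled = mean_scaled,
                 frac_expr = frac_expr,
                 pval = pval,
                 pval_adj = pval_adj,
                 cells_per_cluster = stats::setNames(as.integer(table(labels)[cl]), cl)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("cluster_profile:", length(x$clusters), "clusters x",
      length(x$genes), "genes\n")
  cat("cells per cluster:", paste(x$clusters, x$cells_per_cluster,
                                  sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a cluster profile as long-format CSV
#'
#' One row per (cluster, gene) with columns cluster, gene, mean_norm,
#' mean_scaled, frac_expr, pval, pval_adj.
#' @param profile a [cluster_profile].
#' @param path output CSV path.
#' @export
write_cluster_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cluster_profile"))
  grid <- expand.grid(gene = profile$genes, cluster = profile$clusters,
                      stringsAsFactors = FALSE)
  idx <- cbind(match(grid$cluster, profile$clusters),
               match(grid$gene, profile$genes))
  out <- data.frame(cluster = grid$cluster, gene = grid$gene,
                    mean_norm = profile$mean_norm[idx],
                    mean_scaled = profile$mean_scaled[idx],
                    frac_expr = profile$frac_expr[idx],
                    pval = profile$pval[idx],
                    pval_adj = profile$pval_adj[idx])
  write_csv_atomic(out, path)
}
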