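#' Compare two connectomes edge-for-edge
#'
#' Aligns a control and a test connectome on their shared cluster vocabulary
#' and shared mechanisms and computes, for every (source, target, mechanism)
#' present in both: per-condition ligand/receptor means and expression
#' fractions, log2 fold changes
#' `log2((test + pseudocount) / (ctrl + pseudocount))` on the mean normalized
#' expression (ligand in the source cluster, receptor in the target cluster),
#' the perturbation score
#' `|ligand_log2fc| * |receptor_log2fc|`, and a four-way category from the
#' fold-change signs: `UP_UP` ("activated"), `DOWN_DOWN` ("deactivated"),
#' `UP_DOWN` ("ligand pressure"), `DOWN_UP` ("ligand starvation"), plus `NULL`
#' when either fold change is exactly zero. Minimally perturbed edges score
#' zero; the score grows with the fold change of either gene in either
#' direction.
#'
#' Clusters present in only one condition are dropped with a message; fully
#' disjoint cluster sets are an error. Cross-condition Wilcoxon p-values are
#' not computed here — attach them with [add_cross_pvalues] before p-gating in
#' [filter_differential].
#'
#' @param ctrl,test `connectome` objects built against the same
#'   ligand-receptor database.
#' @param pseudocount small positive value added to numerator and denominator
#'   of each fold-change ratio so zero means stay defined (default 0.01).
#' @return object of class `differential_connectome`: a data.frame with
#'   attributes `clusters`, `conditions`, `provenance`.
#' @export
differential_connectome <- function(ctrl, test, pseudocount = 0.01) {
  stopifnot(inherits(ctrl, "connectome"), inherits(test, "connectome"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  shared <- intersect(attr(ctrl, "clusters"), attr(test, "clusters"))
  if (length(shared) == 0L)
    stop("control and test connectomes share no cluster labels")
  dropped <- setdiff(union(attr(ctrl, "clusters"), attr(test, "clusters")), shared)
  if (length(dropped))
    message("differential_connectome: dropping cluster(s) absent from one condition: ",
            paste(dropped, collapse = ", "))
  key <- function(x) paste(x$source, x$target, x$mechanism_id, sep = "\r")
  c_df <- as.data.frame(ctrl); t_df <- as.data.frame(test)
  c_df <- c_df[c_df$source %in% shared & c_df$target %in% shared, ]
  t_df <- t_df[t_df$source %in% shared & t_df$target %in% shared, ]
  idx <- match(key(c_df), key(t_df))
  keep <- !is.na(idx)
  c_df <- c_df[keep, ]; t_df <- t_df[idx[keep], ]
  lfc <- function(ctrl_v, test_v) log2((test_v + pseudocount) / (ctrl_v + pseudocount))
  out <- data.frame(
    source = c_df$source, target = c_df$target,
    ligand = c_df$ligand, receptor = c_df$receptor,
    mechanism_id = c_df$mechanism_id, family = c_df$family,
    ligand_norm_ctrl = c_df$ligand_norm, ligand_norm_test = t_df$ligand_norm,
    ligand_log2fc = lfc(c_df$ligand_norm, t_df$ligand_norm),
    ligand_frac_ctrl = c_df$ligand_frac, ligand_frac_test = t_df$ligand_frac,
    ligand_p_cross = NA_real_,
    receptor_norm_ctrl = c_df$receptor_norm, receptor_norm_test = t_df$receptor_norm,
    receptor_log2fc = lfc(c_df$receptor_norm, t_df$receptor_norm),
    receptor_frac_ctrl = c_df$receptor_frac, receptor_frac_test = t_df$receptor_frac,
    receptor_p_cross = NA_real_,
    stringsAsFactors = FALSE
  )
  out$perturbation_score <- abs(out$ligand_log2fc) * abs(out$receptor_log2fc)
  out$category <- edge_category(out$ligand_log2fc, out$receptor_log2fc)
  ord <- order(out$mechanism_id, out$source, out$target, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            clusters = sort(shared),
            conditions = c(control = "ctrl", test = "test"),
            provenance = list(pseudocount = pseudocount),
            class = c("differential_connectome", "data.frame"))
}

edge_category <- function(lig_fc, rec_fc) {
  out <- rep("NULL", length(lig_fc))
  out[lig_fc > 0 & rec_fc > 0] <- "UP_UP"
  out[lig_fc < 0 & rec_fc < 0] <- "DOWN_DOWN"
  out[lig_fc > 0 & rec_fc < 0] <- "UP_DOWN"
  out[lig_fc < 0 & rec_fc > 0] <- "DOWN_UP"
  out
}

#' Display names of the four differential edge categories
#' @return named character vector mapping category codes to display names.
#' @export
category_display_names <- function() {
  c(UP_UP = "activated", DOWN_DOWN = "deactivated",
    UP_DOWN = "ligand pressure", DOWN_UP = "ligand starvation")
}

#' @export
print.differential_connectome <- function(x, ...) {
  cl <- attr(x, "clusters") %||% unique(c(x$source, x$target))
  cat("differential_connectome:", nrow(x), "edges;",
      length(cl), "shared clusters\n")
  print(table(x$category))
  invisible(x)
}

#' Cross-condition Wilcoxon rank-sum test per cluster and gene
#'
#' For every shared cluster and every requested gene, compares that cluster's
#' per-cell normalized expression in the test condition against the control
#' condition with a two-sided Wilcoxon rank-sum test. Clusters with fewer
#' than 2 cells in either condition get p = 1 with a warning.
#'
#' @param ctrl_expr,test_expr normalized [clustered_expression] objects.
#' @param genes character vector of genes to test; must be present in both.
#' @return data.frame with columns cluster, gene, pval.
#' @export
cross_condition_wilcoxon <- function(ctrl_expr, test_expr, genes) {
  stopifnot(inherits(ctrl_expr, "clustered_expression"),
            inherits(test_expr, "clustered_expression"))
  if (!ctrl_expr$is_normalized || !test_expr$is_normalized)
    stop("both conditions must be normalized")
  genes <- unique(genes)
  for (side in list(c("control", "ctrl_expr"), c("test", "test_expr"))) {
    e <- get(side[2])
    miss <- setdiff(genes, e$gene_names)
    if (length(miss)) stop("gene(s) absent from the ", side[1], " matrix: ",
                           paste(miss, collapse = ", "))
  }
  shared <- intersect(unique(ctrl_expr$cluster_labels),
                      unique(test_expr$cluster_labels))
  if (length(shared) == 0L) stop("conditions share no cluster labels")
  mc <- as_dense(ctrl_expr$matrix[, genes, drop = FALSE])
  mt <- as_dense(test_expr$matrix[, genes, drop = FALSE])
  res <- expand.grid(gene = genes, cluster = sort(shared),
                     stringsAsFactors = FALSE)[, c(2, 1)]
  res$pval <- NA_real_
  for (cl in sort(shared)) {
    ic <- ctrl_expr$cluster_labels == cl
    it <- test_expr$cluster_labels == cl
    rows <- res$cluster == cl
    if (sum(ic) < 2 || sum(it) < 2) {
      warning("cluster '", cl, "' has fewer than 2 cells in one condition; p = 1")
      res$pval[rows] <- 1
      next
    }
    res$pval[rows] <- vapply(genes, function(g)
      rank_sum_pvalue(mt[it, g], mc[ic, g]), numeric(1))
  }
  res
}

#' Attach cross-condition p-values to a differential connectome
#'
#' Joins [cross_condition_wilcoxon] output onto the edges: the ligand p-value
#' from the (source cluster, ligand) test and the receptor p-value from the
#' (target cluster, receptor) test.
#' @param diff a `differential_connectome`.
#' @param pvals data.frame from [cross_condition_wilcoxon].
#' @return the `differential_connectome` with `ligand_p_cross` and
#'   `receptor_p_cross` filled in (NA where no test is available).
#' @export
add_cross_pvalues <- function(diff, pvals) {
  stopifnot(inherits(diff, "differential_connectome"),
            all(c("cluster", "gene", "pval") %in% names(pvals)))
  key <- paste(pvals$cluster, pvals$gene, sep = "\r")
  diff$ligand_p_cross <- pvals$pval[match(paste(diff$source, diff$ligand, sep = "\r"), key)]
  diff$receptor_p_cross <- pvals$pval[match(paste(diff$target, diff$receptor, sep = "\r"), key)]
  diff
}

#' Filter a differential connectome
#'
#' Retains edges with both cross-condition p-values below `max_p` (strict
#' `<`), ligand and receptor each expressed in more than `min_frac_either` of
#' their cluster in *either* condition (strict `>` on the per-gene max across
#' conditions), and perturbation score at least `min_score` (inclusive `>=`,
#' a floor).
#'
#' @param diff a `differential_connectome` with cross-condition p-values
#'   attached (see [add_cross_pvalues]) whenever `max_p < 1`.
#' @param max_p p-value ceiling (default 0.05).
#' @param min_frac_either expression-fraction floor under either-condition
#'   semantics (default 0.1).
#' @param min_score minimum perturbation score (default 0).
#' @return a filtered `differential_connectome`.
#' @export
filter_differential <- function(diff, max_p = 0.05, min_frac_either = 0.1,
                                min_score = 0) {
  stopifnot(inherits(diff, "differential_connectome"))
  if (max_p <= 0 || max_p > 1) stop("max_p must be in (0, 1]")
  if (min_frac_either < 0 || min_frac_either > 1)
    stop("min_frac_either must be in [0, 1]")
  if (min_score < 0) stop("min_score must be non-negative")
  if (max_p < 1 && all(is.na(diff$ligand_p_cross)))
    stop("cross-condition p-values are not attached; run add_cross_pvalues ",
         "(or set max_p = 1 to skip the significance gate)")
  p_ok <- if (max_p >= 1 && all(is.na(diff$ligand_p_cross))) {
    rep(TRUE, nrow(diff))
  } else {
    !is.na(diff$ligand_p_cross) & diff$ligand_p_cross < max_p &
      !is.na(diff$receptor_p_cross) & diff$receptor_p_cross < max_p
  }
  keep <- p_ok &
    pmax(diff$ligand_frac_ctrl, diff$ligand_frac_test) > min_frac_either &
    pmax(diff$receptor_frac_ctrl, diff$receptor_frac_test) > min_frac_either &
    diff$perturbation_score >= min_score
  out <- as.data.frame(diff)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            clusters = attr(diff, "clusters"),
            conditions = attr(diff, "conditions"),
            provenance = utils::modifyList(attr(diff, "provenance") %||% list(),
                                           list(filter = list(max_p = max_p,
                                                              min_frac_either = min_frac_either,
                                                              min_score = min_score))),
            class = class(diff))
}

#' Partition differential edges by perturbation category
#'
#' @param diff a `differential_connectome`.
#' @return named list of data.frames, one per non-empty category among
#'   UP_UP, DOWN_DOWN, UP_DOWN, DOWN_UP (NULL-category edges are excluded);
#'   each carries a `display_name` attribute.
#' @export
categorize_edges <- function(diff) {
  stopifnot(inherits(diff, "differential_connectome"))
  cats <- names(category_display_names())
  out <- list()
  for (cat in cats) {
    block <- as.data.frame(diff)[diff$category == cat, , drop = FALSE]
    rownames(block) <- NULL
    attr(block, "display_name") <- category_display_names()[[cat]]
    out[[cat]] <- block
  }
  out
}

#' Write a differential edge list as CSV
#' @param diff a `differential_connectome`.
#' @param path output CSV path.
#' @export
write_differential <- function(diff, path) {
  stopifnot(inherits(diff, "differential_connectome"))
  write_csv_atomic(as.data.frame(diff), path)
}
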