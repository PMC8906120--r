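#' Specification for a synthetic clustered single-cell dataset
#'
#' Defines a cluster-structured negative-binomial count matrix with planted
#' cluster-specific ligand and receptor markers, decoy ligand-receptor
#' mechanisms drawn among background genes, optional dropout, and optional
#' per-condition effects for differential analyses. All randomness derives
#' from `seed`, so generation is a pure function of the spec.
#'
#' Defaults describe the reference simulation used throughout the package's
#' validation: 4 clusters of 200 cells, 1000 background genes with
#' negative-binomial mean 2 and dispersion 0.5 (roughly 2,000-count
#' libraries, so no single gene dominates the library size), 20% dropout,
#' two planted ligand-receptor edges at 4-fold enrichment, and 10 decoy
#' mechanisms.
#'
#' @param n_clusters number of clusters (nodes).
#' @param cells_per_cluster cells in each cluster.
#' @param n_background_genes background (non-planted) genes.
#' @param planted_edges data.frame with columns source, ligand, target,
#'   receptor, effect_size (> 1 fold enrichment of the ligand in its source
#'   cluster and the receptor in its target cluster; 1 = null control).
#'   Defaults to two edges at effect size 4, one per family.
#' @param baseline_mean negative-binomial mean of every gene elsewhere.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param dropout_rate independent zeroing probability in `[0, 1)`.
#' @param n_decoy_pairs decoy ligand-receptor pairs among background genes.
#' @param condition_effects optional data.frame with columns cluster, gene,
#'   fold (> 0) applied multiplicatively to the test condition's means in
#'   [generate_condition_pair].
#' @param seed integer seed.
#' @return validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 4, cells_per_cluster = 200,
                           n_background_genes = 1000,
                           planted_edges = NULL,
                           baseline_mean = 2, dispersion = 0.5,
                           dropout_rate = 0.2, n_decoy_pairs = 10,
                           condition_effects = NULL, seed = 1) {
  if (is.null(planted_edges)) {
    # two planted edges at 4-fold on disjoint cluster pairs when room allows
    planted_edges <- if (n_clusters >= 4) {
      data.frame(source = c("C1", "C3"), ligand = c("LG1", "LG2"),
                 target = c("C2", "C4"), receptor = c("RC1", "RC2"),
                 effect_size = c(4, 4), stringsAsFactors = FALSE)
    } else if (n_clusters == 3) {
      data.frame(source = c("C1", "C2"), ligand = c("LG1", "LG2"),
                 target = c("C2", "C3"), receptor = c("RC1", "RC2"),
                 effect_size = c(4, 4), stringsAsFactors = FALSE)
    } else {
      data.frame(source = "C1", ligand = "LG1", target = "C2",
                 receptor = "RC1", effect_size = 4, stringsAsFactors = FALSE)
    }
  }
  spec <- structure(list(n_clusters = n_clusters,
                         cells_per_cluster = cells_per_cluster,
                         n_background_genes = n_background_genes,
                         planted_edges = planted_edges,
                         baseline_mean = baseline_mean,
                         dispersion = dispersion,
                         dropout_rate = dropout_rate,
                         n_decoy_pairs = n_decoy_pairs,
                         condition_effects = condition_effects,
                         seed = seed),
                    class = "synthetic_spec")
  problems <- validate_synthetic_spec(spec)
  if (length(problems))
    stop("invalid synthetic_spec:\n  - ", paste(problems, collapse = "\n  - "))
  spec
}

validate_synthetic_spec <- function(spec) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(spec$n_clusters >= 2, "n_clusters must be >= 2")
  chk(spec$cells_per_cluster >= 2, "cells_per_cluster must be >= 2")
  chk(spec$n_background_genes >= 1, "n_background_genes must be >= 1")
  chk(spec$baseline_mean > 0, "baseline_mean must be positive")
  chk(spec$dispersion > 0, "dispersion must be positive")
  chk(spec$dropout_rate >= 0 && spec$dropout_rate < 1,
      "dropout_rate must be in [0, 1)")
  chk(spec$n_decoy_pairs >= 0, "n_decoy_pairs must be >= 0")
  pe <- spec$planted_edges
  chk(is.data.frame(pe) &&
        all(c("source", "ligand", "target", "receptor", "effect_size") %in% names(pe)),
      "planted_edges must have columns source, ligand, target, receptor, effect_size")
  if (is.data.frame(pe) && all(c("source", "target", "effect_size") %in% names(pe))) {
    cl <- paste0("C", seq_len(max(spec$n_clusters, 1)))
    chk(all(c(pe$source, pe$target) %in% cl),
        "planted_edges source/target must be cluster labels C1..Cn")
    chk(all(pe$effect_size >= 1), "planted effect_size must be >= 1")
    bg <- sprintf("BG%03d", seq_len(max(spec$n_background_genes, 1)))
    chk(!any(c(pe$ligand, pe$receptor) %in% bg),
        "planted ligand/receptor names must be distinct from background gene names")
  }
  if (!is.null(spec$condition_effects)) {
    ce <- spec$condition_effects
    chk(is.data.frame(ce) && all(c("cluster", "gene", "fold") %in% names(ce)),
        "condition_effects must have columns cluster, gene, fold")
    if (is.data.frame(ce) && "fold" %in% names(ce))
      chk(all(ce$fold > 0), "condition_effects fold must be positive")
  }
  p
}

# per-cell-per-gene NB mean matrix implied by the spec (no noise)
synthetic_mean_matrix <- function(spec) {
  cl <- paste0("C", seq_len(spec$n_clusters))
  labels <- rep(cl, each = spec$cells_per_cluster)
  bg <- sprintf("BG%03d", seq_len(spec$n_background_genes))
  planted <- unique(c(rbind(spec$planted_edges$ligand, spec$planted_edges$receptor)))
  genes <- c(bg, planted)
  mu <- matrix(spec$baseline_mean, length(labels), length(genes),
               dimnames = list(paste0("cell", seq_along(labels)), genes))
  for (i in seq_len(nrow(spec$planted_edges))) {
    e <- spec$planted_edges[i, ]
    mu[labels == e$source, e$ligand] <- spec$baseline_mean * e$effect_size
    mu[labels == e$target, e$receptor] <- spec$baseline_mean * e$effect_size
  }
  list(mu = mu, labels = labels, genes = genes, bg = bg, planted = planted)
}

sample_counts <- function(mu, dispersion, dropout_rate) {
  n <- length(mu)
  counts <- matrix(stats::rnbinom(n, size = 1 / dispersion, mu = as.numeric(mu)),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  if (dropout_rate > 0) {
    keep <- matrix(stats::rbinom(n, 1, 1 - dropout_rate), nrow = nrow(mu))
    counts <- counts * keep
  }
  counts
}

synthetic_lr_db <- function(spec, bg) {
  fam <- paste0("FAM", seq_len(nrow(spec$planted_edges)))
  lig <- spec$planted_edges$ligand
  rec <- spec$planted_edges$receptor
  if (spec$n_decoy_pairs > 0) {
    # decoys pair distinct background genes; deterministic under the caller's RNG
    pool <- sample(bg)
    need <- 2 * spec$n_decoy_pairs
    while (length(pool) < need) pool <- c(pool, sample(bg))
    dl <- pool[seq(1, need, by = 2)]
    dr <- pool[seq(2, need, by = 2)]
    bad <- dl == dr
    dr[bad] <- bg[(match(dl[bad], bg) %% length(bg)) + 1]
    dup <- duplicated(paste(dl, dr))
    lig <- c(lig, dl[!dup]); rec <- c(rec, dr[!dup])
    fam <- c(fam, rep("unassigned", sum(!dup)))
  }
  lr_database(lig, rec, family = fam,
              mode = rep("secreted", length(lig)))
}

#' Generate a synthetic clustered count matrix with planted signal
#'
#' Draws negative-binomial counts per the spec, multiplies the planted ligand
#' mean by its effect size in the source cluster only (receptor likewise in
#' the target cluster), applies independent dropout, and returns the
#' expression object together with a matching ligand-receptor database (the
#' planted pairs, each its own family, plus decoy pairs among background
#' genes) and the ground-truth planted edge table.
#'
#' @param spec a [synthetic_spec].
#' @return list with elements `expression` (a [clustered_expression] of raw
#'   counts), `lr_db` (an [lr_database]) and `truth` (the planted edge table).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  parts <- synthetic_mean_matrix(spec)
  counts <- sample_counts(parts$mu, spec$dispersion, spec$dropout_rate)
  db <- synthetic_lr_db(spec, parts$bg)
  list(expression = clustered_expression(counts, parts$labels),
       lr_db = db,
       truth = spec$planted_edges)
}

#' Generate a matched control/test condition pair
#'
#' The control condition is drawn exactly as in [generate_synthetic]; the test
#' condition is drawn from the same model with each `condition_effects` fold
#' multiplier applied to the named (cluster, gene) mean. Gene and cluster
#' vocabularies are shared.
#'
#' @param spec a [synthetic_spec] with non-empty `condition_effects`.
#' @return list with `control`, `test` (raw-count [clustered_expression]),
#'   `lr_db`, `truth` (planted edges) and `condition_effects`.
#' @export
generate_condition_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$condition_effects) || nrow(spec$condition_effects) == 0L)
    stop("generate_condition_pair requires non-empty condition_effects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  parts <- synthetic_mean_matrix(spec)
  ctrl_counts <- sample_counts(parts$mu, spec$dispersion, spec$dropout_rate)
  db <- synthetic_lr_db(spec, parts$bg)
  mu_test <- parts$mu
  for (i in seq_len(nrow(spec$condition_effects))) {
    e <- spec$condition_effects[i, ]
    if (!e$gene %in% colnames(mu_test))
      stop("condition effect names unknown gene: ", e$gene)
    mu_test[parts$labels == e$cluster, e$gene] <-
      mu_test[parts$labels == e$cluster, e$gene] * e$fold
  }
  test_counts <- sample_counts(mu_test, spec$dispersion, spec$dropout_rate)
  list(control = clustered_expression(ctrl_counts, parts$labels),
       test = clustered_expression(test_counts, parts$labels),
       lr_db = db,
       truth = spec$planted_edges,
       condition_effects = spec$condition_effects)
}

#' Write synthetic fixtures in the formats the readers consume
#'
#' Emits the MTX + sidecar layout ([write_mtx_expression]) and the canonical
#' ligand-receptor CSV ([write_lr_database]) into `dir`, so a full round-trip
#' through the file readers can be exercised.
#' @param sim a [generate_synthetic] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_expression(sim$expression, dir)
  write_lr_database(sim$lr_db, file.path(dir, "lr_pairs.csv"))
  write_csv_atomic(sim$truth, file.path(dir, "planted_edges.csv"))
  invisible(dir)
}
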