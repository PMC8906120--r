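# Independent oracles and fixture builders used across the suite.

# Brute-force two-sided rank-sum p-value: enumerate every assignment of the
# pooled values (midranks) to group one and count deviations of the rank sum
# from its permutation mean at least as large as observed. Written straight
# from the null definition; shares no code with the package implementation.
enum_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); n <- length(pooled)
  r <- rank(pooled)
  mu <- m * (n + 1) / 2
  obs <- abs(sum(r[seq_len(m)]) - mu)
  assignments <- utils::combn(n, m)
  devs <- abs(apply(assignments, 2, function(idx) sum(r[idx])) - mu)
  mean(devs >= obs - 1e-9)
}

# Edge content as a plain data.frame, stripped of vocabulary/provenance
# attributes, for content-equality assertions.
edges_df <- function(x) {
  x <- as.data.frame(x)
  out <- data.frame(x, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, intersect(names(x), names(out)), drop = FALSE]
}

# Minimal edge row with sensible defaults; override any field.
edge_row <- function(source = "A", target = "B", ligand = "L1", receptor = "R1",
                     family = "unassigned",
                     ligand_norm = 1, receptor_norm = 1,
                     ligand_scaled = 0.5, receptor_scaled = 0.5,
                     ligand_frac = 0.5, receptor_frac = 0.5,
                     ligand_p = 0.01, receptor_p = 0.01) {
  data.frame(source = source, target = target, ligand = ligand,
             receptor = receptor, mechanism_id = paste(ligand, receptor, sep = "|"),
             family = family,
             ligand_norm = ligand_norm, receptor_norm = receptor_norm,
             ligand_scaled = ligand_scaled, receptor_scaled = receptor_scaled,
             ligand_frac = ligand_frac, receptor_frac = receptor_frac,
             ligand_p = ligand_p, receptor_p = receptor_p,
             ligand_p_adj = ligand_p, receptor_p_adj = receptor_p,
             weight_norm = ligand_norm * receptor_norm,
             weight_scale = (ligand_scaled + receptor_scaled) / 2,
             stringsAsFactors = FALSE)
}

toy_connectome <- function(rows, ...) {
  as_connectome(do.call(rbind, rows), ...)
}

# cluster_profile built directly from given statistic matrices (clusters x
# genes), bypassing the expression pipeline, for edge-construction tests.
manual_profile <- function(mean_norm, mean_scaled = mean_norm * 0,
                           frac_expr = mean_norm * 0 + 1,
                           pval = mean_norm * 0 + 0.01) {
  structure(list(clusters = rownames(mean_norm), genes = colnames(mean_norm),
                 mean_norm = mean_norm, mean_scaled = mean_scaled,
                 frac_expr = frac_expr, pval = pval, pval_adj = pval,
                 cells_per_cluster = stats::setNames(
                   rep(10L, nrow(mean_norm)), rownames(mean_norm))),
            class = "cluster_profile")
}

# random fully-populated connectome for formula/property checks
random_connectome <- function(n_clusters = 4, n_mech = 4, seed = 1) {
  set.seed(seed)
  cl <- paste0("K", seq_len(n_clusters))
  genes <- c(paste0("L", seq_len(n_mech)), paste0("R", seq_len(n_mech)))
  mk <- function() matrix(runif(n_clusters * length(genes), 0, 3),
                          n_clusters, dimnames = list(cl, genes))
  prof <- manual_profile(mk(), mean_scaled = mk() - 1.5,
                         frac_expr = matrix(runif(n_clusters * length(genes)),
                                            n_clusters, dimnames = list(cl, genes)),
                         pval = matrix(runif(n_clusters * length(genes), 1e-6, 1),
                                       n_clusters, dimnames = list(cl, genes)))
  db <- lr_database(paste0("L", seq_len(n_mech)), paste0("R", seq_len(n_mech)),
                    family = paste0("F", rep_len(1:2, n_mech)))
  create_connectome(prof, db)
}
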