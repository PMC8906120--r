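#' Build the celltype-ligand-receptor-celltype edge list
#'
#' Maps a [cluster_profile] against an [lr_database] to produce the full
#' directed edge list: one edge per (source cluster, target cluster,
#' mechanism), self-edges (autocrine, source == target) included. Each edge
#' carries the source cluster's ligand statistics and the target cluster's
#' receptor statistics, plus two edgeweights:
#' \describe{
#'   \item{weight_norm}{`ligand_norm * receptor_norm` — the product of mean
#'     normalized expressions; raw connectivity.}
#'   \item{weight_scale}{`(ligand_scaled + receptor_scaled) / 2` — the mean of
#'     the system-wide gene z-scores; signal specificity within the system.}
#' }
#' The database is first restricted to genes present in the profile
#' ([restrict_to_genes]); an empty restricted database is an error. Edge order
#' is fixed (mechanism, then source, then target, lexicographic) so outputs
#' are byte-reproducible.
#'
#' @param profile a [cluster_profile].
#' @param db an [lr_database].
#' @param drop_self_edges drop autocrine (source == target) edges
#'   (default `FALSE`; the full matrix includes the diagonal).
#' @return object of class `connectome`: a data.frame of edges with attributes
#'   `clusters`, `mechanisms` and `provenance`.
#' @export
create_connectome <- function(profile, db, drop_self_edges = FALSE) {
  stopifnot(inherits(profile, "cluster_profile"), inherits(db, "lr_database"))
  if (length(profile$clusters) < 2) stop("need at least 2 clusters")
  db <- restrict_to_genes(db, profile$genes)
  if (nrow(db) == 0L)
    stop("no ligand-receptor mechanism has both genes in the profile")
  db <- db[order(db$mechanism_id), , drop = FALSE]
  cl <- sort(profile$clusters)
  grid <- expand.grid(target = cl, source = cl, mech = seq_len(nrow(db)),
                      stringsAsFactors = FALSE)
  si <- match(grid$source, profile$clusters)
  ti <- match(grid$target, profile$clusters)
  li <- match(db$ligand[grid$mech], profile$genes)
  ri <- match(db$receptor[grid$mech], profile$genes)
  lig_idx <- cbind(si, li)
  rec_idx <- cbind(ti, ri)
  edges <- data.frame(
    source = grid$source,
    target = grid$target,
    ligand = db$ligand[grid$mech],
    receptor = db$receptor[grid$mech],
    mechanism_id = db$mechanism_id[grid$mech],
    family = db$family[grid$mech],
    ligand_norm = profile$mean_norm[lig_idx],
    receptor_norm = profile$mean_norm[rec_idx],
    ligand_scaled = profile$mean_scaled[lig_idx],
    receptor_scaled = profile$mean_scaled[rec_idx],
    ligand_frac = profile$frac_expr[lig_idx],
    receptor_frac = profile$frac_expr[rec_idx],
    ligand_p = profile$pval[lig_idx],
    receptor_p = profile$pval[rec_idx],
    ligand_p_adj = profile$pval_adj[lig_idx],
    receptor_p_adj = profile$pval_adj[rec_idx],
    stringsAsFactors = FALSE
  )
  edges$weight_norm <- edges$ligand_norm * edges$receptor_norm
  edges$weight_scale <- (edges$ligand_scaled + edges$receptor_scaled) / 2
  ord <- order(edges$mechanism_id, edges$source, edges$target, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  if (drop_self_edges) edges <- edges[edges$source != edges$target, , drop = FALSE]
  rownames(edges) <- NULL
  as_connectome(edges, clusters = cl, mechanisms = db$mechanism_id,
                provenance = list(n_clusters = length(cl),
                                  n_mechanisms = nrow(db),
                                  drop_self_edges = drop_self_edges))
}

#' Tag an edge data.frame as a connectome
#'
#' Low-level constructor used by [create_connectome], the edge-list reader and
#' tests. Checks column presence and (source, target, mechanism) uniqueness.
#'
#' @param edges data.frame with the canonical edge columns.
#' @param clusters node vocabulary (defaults to labels seen in `edges`).
#' @param mechanisms mechanism vocabulary (defaults to those seen).
#' @param provenance named list of configuration provenance.
#' @return a `connectome`.
#' @export
as_connectome <- function(edges, clusters = NULL, mechanisms = NULL,
                          provenance = list()) {
  need <- connectome_columns()
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop("edge list is missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(edges$source, edges$target, edges$mechanism_id)
  if (anyDuplicated(key))
    stop("duplicate (source, target, mechanism) edge(s) in connectome")
  structure(as.data.frame(edges)[, need],
            clusters = clusters %||% sort(unique(c(edges$source, edges$target))),
            mechanisms = mechanisms %||% sort(unique(edges$mechanism_id)),
            provenance = provenance,
            class = c("connectome", "data.frame"))
}

connectome_columns <- function() {
  c("source", "target", "ligand", "receptor", "mechanism_id", "family",
    "ligand_norm", "receptor_norm", "ligand_scaled", "receptor_scaled",
    "ligand_frac", "receptor_frac", "ligand_p", "receptor_p",
    "ligand_p_adj", "receptor_p_adj", "weight_norm", "weight_scale")
}

#' @export
print.connectome <- function(x, ...) {
  cl <- attr(x, "clusters") %||% unique(c(x$source, x$target))
  mech <- attr(x, "mechanisms") %||% unique(x$mechanism_id)
  cat("connectome:", nrow(x), "edges;", length(cl), "clusters;",
      length(mech), "mechanisms\n")
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more edge(s)\n")
  invisible(x)
}

# rebuild a connectome around a row subset, preserving vocabulary + provenance
subset_connectome <- function(conn, keep, provenance_add = NULL) {
  out <- as.data.frame(conn)[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- attr(conn, "provenance") %||% list()
  if (!is.null(provenance_add)) prov <- utils::modifyList(prov, provenance_add)
  structure(out,
            clusters = attr(conn, "clusters"),
            mechanisms = attr(conn, "mechanisms"),
            provenance = prov,
            class = c("connectome", "data.frame"))
}

#' Filter a connectome on expression fraction, significance and identity
#'
#' Retains edges where the ligand and the receptor are each expressed in more
#' than `min_frac` of their respective clusters (strict `>`) and each have a
#' one-vs-rest Wilcoxon p-value below `max_p` (strict `<`), together with any
#' optional criteria. Filtering is monotone and idempotent; an empty result is
#' permitted (with a message).
#'
#' @param conn a `connectome`.
#' @param min_frac minimum expression fraction, in `[0, 1]` (default 0.1, the
#'   usual single-tissue recipe).
#' @param max_p p-value ceiling in `(0, 1]` (default 0.05).
#' @param min_weight_norm optional; keep edges with `weight_norm >` this.
#' @param min_z optional; keep edges with both `ligand_scaled` and
#'   `receptor_scaled` `>` this (z-score gate).
#' @param sources,targets,mechanisms,families optional identity subsets.
#' @return a filtered `connectome` with updated provenance.
#' @export
filter_connectome <- function(conn, min_frac = 0.1, max_p = 0.05,
                              min_weight_norm = NULL, min_z = NULL,
                              sources = NULL, targets = NULL,
                              mechanisms = NULL, families = NULL) {
  stopifnot(inherits(conn, "connectome"))
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  if (max_p <= 0 || max_p > 1) stop("max_p must be in (0, 1]")
  keep <- conn$ligand_frac > min_frac & conn$receptor_frac > min_frac &
    conn$ligand_p < max_p & conn$receptor_p < max_p
  if (!is.null(min_weight_norm)) keep <- keep & conn$weight_norm > min_weight_norm
  if (!is.null(min_z))
    keep <- keep & conn$ligand_scaled > min_z & conn$receptor_scaled > min_z
  if (!is.null(sources)) keep <- keep & conn$source %in% sources
  if (!is.null(targets)) keep <- keep & conn$target %in% targets
  if (!is.null(mechanisms)) keep <- keep & conn$mechanism_id %in% mechanisms
  if (!is.null(families)) keep <- keep & conn$family %in% families
  if (!any(keep)) message("filter_connectome: no edges survive the thresholds")
  subset_connectome(conn, keep, provenance_add = list(
    filter = list(min_frac = min_frac, max_p = max_p,
                  min_weight_norm = min_weight_norm, min_z = min_z,
                  sources = sources, targets = targets,
                  mechanisms = mechanisms, families = families)))
}

#' Slice a connectome into its canonical sub-networks
#'
#' \describe{
#'   \item{interactome}{all edges of one mechanism (`key` = mechanism id).}
#'   \item{outgoing}{all edges sent by one cluster (`key` = cluster).}
#'   \item{niche}{all edges received by one cluster (`key` = cluster).}
#'   \item{vector}{all edges for one (source, target) pair
#'     (`key` = c(source, target)).}
#' }
#' @param conn a `connectome`.
#' @param mode one of `"interactome"`, `"outgoing"`, `"niche"`, `"vector"`.
#' @param key mechanism id, cluster label, or length-2 (source, target).
#' @return a `connectome` subset.
#' @export
slice_connectome <- function(conn, mode = c("interactome", "outgoing", "niche", "vector"),
                             key) {
  stopifnot(inherits(conn, "connectome"))
  mode <- match.arg(mode)
  clusters <- attr(conn, "clusters")
  mechanisms <- attr(conn, "mechanisms")
  check <- function(k, valid, what) {
    bad <- setdiff(k, valid)
    if (length(bad))
      stop("unknown ", what, ": ", paste(bad, collapse = ", "),
           "; valid values: ", paste(valid, collapse = ", "))
  }
  keep <- switch(mode,
    interactome = { check(key, mechanisms, "mechanism"); conn$mechanism_id %in% key },
    outgoing = { check(key, clusters, "cluster"); conn$source %in% key },
    niche = { check(key, clusters, "cluster"); conn$target %in% key },
    vector = {
      if (length(key) != 2) stop("vector slice needs key = c(source, target)")
      check(key, clusters, "cluster")
      conn$source == key[1] & conn$target == key[2]
    })
  subset_connectome(conn, keep, provenance_add = list(slice = list(mode = mode, key = key)))
}

#' Write / read a connectome edge list
#'
#' The edge list is written as long-format CSV with the canonical column order
#' and round-trip-accurate numeric formatting; provenance (cluster and
#' mechanism vocabularies, configuration) is serialized as a JSON sidecar at
#' `<path>.provenance.json`. On read, a missing sidecar degrades to empty
#' provenance with a warning; missing columns are a schema error.
#'
#' @param conn a `connectome`.
#' @param path CSV path.
#' @return `write_edgelist`: `path`, invisibly. `read_edgelist`: a
#'   `connectome`.
#' @export
write_edgelist <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  write_csv_atomic(as.data.frame(conn), path)
  write_json_atomic(list(clusters = attr(conn, "clusters"),
                         mechanisms = attr(conn, "mechanisms"),
                         provenance = attr(conn, "provenance")),
                    paste0(path, ".provenance.json"))
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  edges <- data.table::fread(path, data.table = FALSE)
  miss <- setdiff(connectome_columns(), names(edges))
  if (length(miss)) stop("edge list is missing column(s): ",
                         paste(miss, collapse = ", "))
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    as_connectome(edges, clusters = meta$clusters, mechanisms = meta$mechanisms,
                  provenance = as.list(meta$provenance))
  } else {
    warning("provenance sidecar not found for ", path, "; provenance is empty")
    as_connectome(edges)
  }
}
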