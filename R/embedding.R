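#' Pivot a connectome into a vectortype matrix
#'
#' A "vectortype" is one celltype-to-celltype pair viewed as a feature vector
#' of mechanism edgeweights. This pivots the edge list to a
#' (source, target) x mechanism matrix over the full cluster grid; edges
#' absent from the (possibly filtered) connectome fill 0. Rows with fewer than
#' `min_nonzero` nonzero entries are dropped.
#'
#' @param conn a `connectome`.
#' @param weight `"weight_scale"` (default) or `"weight_norm"`.
#' @param min_nonzero minimum number of nonzero mechanism weights a row needs
#'   to be kept (default 0).
#' @return object of class `vectortype_matrix`: a numeric matrix with rownames
#'   `"source->target"` and attributes `source`, `target` (per-row labels).
#' @export
build_vectortype_matrix <- function(conn, weight = c("weight_scale", "weight_norm"),
                                    min_nonzero = 0) {
  stopifnot(inherits(conn, "connectome"))
  weight <- match.arg(weight)
  if (nrow(conn) == 0L) stop("connectome has no edges")
  cl <- attr(conn, "clusters")
  mech <- attr(conn, "mechanisms")
  grid <- expand.grid(target = cl, source = cl, stringsAsFactors = FALSE)[, c(2, 1)]
  vm <- matrix(0, nrow(grid), length(mech),
               dimnames = list(paste(grid$source, grid$target, sep = "->"), mech))
  ri <- match(paste(conn$source, conn$target, sep = "->"), rownames(vm))
  ci <- match(conn$mechanism_id, mech)
  vm[cbind(ri, ci)] <- conn[[weight]]
  keep <- rowSums(vm != 0) >= min_nonzero
  vm <- vm[keep, , drop = FALSE]
  structure(vm, source = grid$source[keep], target = grid$target[keep],
            class = c("vectortype_matrix", class(vm)))
}

# symmetric k-nearest-neighbour graph on L2-normalized rows (Euclidean
# distance, ties broken by row index); returns an igraph graph
knn_graph <- function(vm, n_neighbors) {
  x <- as_dense(vm)
  norms <- sqrt(rowSums(x^2))
  pos <- norms > 0
  x[pos, ] <- x[pos, , drop = FALSE] / norms[pos]
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n - 1))  # ties by index order
    nb <- setdiff(seq_len(n), i)[ord][seq_len(min(n_neighbors, n - 1))]
    edges <- rbind(edges, cbind(i, nb))
  }
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::set_vertex_attr(g, "name", value = rownames(vm))
}

#' Embed vectortypes in two dimensions
#'
#' Places each vectortype in 2D by the similarity of its mechanism-wise
#' edgeweight profile: rows are L2-normalized, a symmetric k-nearest-neighbor
#' graph (Euclidean distance) is built, vectortype clusters are assigned by
#' Louvain community detection on that graph, and coordinates come from a
#' force-directed (Fruchterman-Reingold) layout of the graph. The kNN graph
#' and communities are deterministic given the data; coordinates are
#' deterministic given `seed`.
#'
#' @param vm a [build_vectortype_matrix] result.
#' @param n_neighbors neighbors per row (default 10); needs
#'   `nrow(vm) >= n_neighbors + 1`.
#' @param seed integer seed for the layout (and any stochastic refinement).
#' @return data.frame with columns source, target, dim1, dim2,
#'   vectortype_cluster.
#' @export
embed_vectortypes <- function(vm, n_neighbors = 10, seed = 42) {
  stopifnot(inherits(vm, "vectortype_matrix"))
  if (nrow(vm) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
         " vectortype rows, have ", nrow(vm))
  g <- knn_graph(vm, n_neighbors)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  set.seed(seed)
  coords <- igraph::layout_with_fr(g)
  data.frame(source = attr(vm, "source"),
             target = attr(vm, "target"),
             dim1 = coords[, 1], dim2 = coords[, 2],
             vectortype_cluster = igraph::membership(comm),
             row.names = NULL)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
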