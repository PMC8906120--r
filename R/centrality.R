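#' Aggregate a connectome into a weighted cluster adjacency matrix
#'
#' Sums the chosen edgeweight over all mechanisms for each ordered
#' (source, target) cluster pair. Kleinberg centrality requires non-negative
#' weights, but `weight_scale` can be negative; negative values are handled
#' before summation according to `negative`:
#' \describe{
#'   \item{floor}{replace negative weights with 0 (default).}
#'   \item{shift}{add `-min(weight)` to every edge so the minimum becomes 0.}
#'   \item{drop}{remove negative-weight edges.}
#' }
#'
#' @param conn a `connectome`.
#' @param weight `"weight_scale"` (default) or `"weight_norm"`.
#' @param negative negative-weight policy, see above.
#' @return clusters x clusters non-negative matrix (row = source).
#' @export
aggregate_adjacency <- function(conn, weight = c("weight_scale", "weight_norm"),
                                negative = c("floor", "shift", "drop")) {
  stopifnot(inherits(conn, "connectome"))
  weight <- match.arg(weight)
  negative <- match.arg(negative)
  if (nrow(conn) == 0L) stop("connectome has no edges")
  w <- conn[[weight]]
  src <- conn$source; tgt <- conn$target
  if (negative == "floor") {
    w <- pmax(w, 0)
  } else if (negative == "shift") {
    if (min(w) < 0) w <- w - min(w)
  } else {
    keep <- w >= 0
    w <- w[keep]; src <- src[keep]; tgt <- tgt[keep]
  }
  cl <- attr(conn, "clusters")
  adj <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  if (length(w)) {
    agg <- stats::aggregate(w, list(source = src, target = tgt), sum)
    adj[cbind(match(agg$source, cl), match(agg$target, cl))] <- agg$x
  }
  if (all(adj == 0)) stop("no positive-weight edges in the selected network")
  adj
}

#' Kleinberg hub and authority scores by power iteration
#'
#' Runs the mutually-reinforcing HITS updates (authority <- A'h, hub <- Aa,
#' renormalized each round) from a uniform start until successive iterates
#' differ by less than `tol` in max-norm. The hub vector is the dominant
#' eigenvector direction of A A' and the authority vector of A' A; both are
#' non-negative and scaled so their maximum is 1 (for plot interpretability).
#' A warning is emitted when the graph has more than one weakly connected
#' component (the dominant component determines the scores).
#'
#' @param adj non-negative square adjacency matrix (rows = senders).
#' @param tol convergence tolerance in max-norm (default 1e-10).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return list with numeric vectors `hub` and `authority`, named by cluster.
#' @export
hits_centrality <- function(adj, tol = 1e-10, max_iter = 1000) {
  adj <- as_dense(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(adj < 0)) stop("adjacency must be non-negative")
  if (all(adj == 0)) stop("adjacency has no positive entries")
  g <- igraph::graph_from_adjacency_matrix((adj + t(adj)) > 0, mode = "undirected")
  if (igraph::components(g)$no > 1)
    warning("network has more than one weakly connected component; ",
            "HITS scores are dominated by the strongest component")
  n <- nrow(adj)
  h <- rep(1, n); a <- rep(1, n)
  norm1 <- function(v) if (max(v) > 0) v / max(v) else v
  for (it in seq_len(max_iter)) {
    a_new <- norm1(drop(crossprod(adj, h)))   # authority <- A' h
    h_new <- norm1(drop(adj %*% a_new))       # hub <- A a
    res <- max(abs(a_new - a), abs(h_new - h))
    a <- a_new; h <- h_new
    if (res < tol)
      return(list(hub = stats::setNames(h, rownames(adj)),
                  authority = stats::setNames(a, colnames(adj))))
  }
  stop("HITS power iteration did not converge in ", max_iter,
       " iterations (residual ", format(res, digits = 3), ")")
}

#' Cumulative incoming/outgoing edgeweight fractions
#'
#' Per-node sums of outgoing and incoming edgeweight, expressed as fractions
#' of the total edgeweight within the considered system, so each vector sums
#' to 1.
#' @param adj non-negative adjacency matrix.
#' @return list with vectors `out_frac` and `in_frac`.
#' @export
weight_fractions <- function(adj) {
  adj <- as_dense(adj)
  total <- sum(adj)
  if (total <= 0) stop("total edgeweight is zero")
  list(out_frac = rowSums(adj) / total, in_frac = colSums(adj) / total)
}

#' Per-family centrality table
#'
#' Iteratively subsets the connectome to each signaling family, aggregates the
#' family's edges into a weighted adjacency ([aggregate_adjacency]) and
#' computes Kleinberg hub/authority scores plus in/out edgeweight fractions
#' for every cluster. Families whose edges carry no positive weight are
#' skipped with a message.
#'
#' @param conn a `connectome`.
#' @param weight passed to [aggregate_adjacency].
#' @param families optional subset of family labels (default: all present).
#' @param negative negative-weight policy, passed to [aggregate_adjacency].
#' @return object of class `centrality_table`: data.frame with columns
#'   network_label, cluster, hub_score, authority_score, out_weight_frac,
#'   in_weight_frac, n_edges_considered.
#' @export
family_centrality <- function(conn, weight = c("weight_scale", "weight_norm"),
                              families = NULL, negative = "floor") {
  stopifnot(inherits(conn, "connectome"))
  weight <- match.arg(weight)
  families <- families %||% sort(unique(conn$family))
  blocks <- list()
  for (fam in families) {
    sub <- subset_connectome(conn, conn$family == fam)
    adj <- tryCatch(aggregate_adjacency(sub, weight = weight, negative = negative),
                    error = function(e) NULL)
    if (is.null(adj)) {
      message("family_centrality: family '", fam,
              "' has no positive-weight edges; skipped")
      next
    }
    hits <- suppressWarnings(hits_centrality(adj))
    wf <- weight_fractions(adj)
    blocks[[fam]] <- data.frame(
      network_label = fam,
      cluster = rownames(adj),
      hub_score = unname(hits$hub),
      authority_score = unname(hits$authority),
      out_weight_frac = unname(wf$out_frac),
      in_weight_frac = unname(wf$in_frac),
      n_edges_considered = nrow(sub),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(network_label = character(), cluster = character(),
               hub_score = numeric(), authority_score = numeric(),
               out_weight_frac = numeric(), in_weight_frac = numeric(),
               n_edges_considered = integer())
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Group signaling families by their dominant receiver class
#'
#' For each family (network label) in a centrality table, finds the cluster
#' with the maximal authority score — ties broken by incoming edgeweight
#' fraction, then lexicographic cluster name — and reports that cluster's
#' class.
#' @param table a `centrality_table`.
#' @param class_map named character vector, cluster -> class label; must cover
#'   every cluster in the table.
#' @return named character vector, family -> class label.
#' @export
group_by_dominant_receiver <- function(table, class_map) {
  stopifnot(inherits(table, "data.frame"))
  miss <- setdiff(unique(table$cluster), names(class_map))
  if (length(miss)) stop("class_map does not cover cluster(s): ",
                         paste(miss, collapse = ", "))
  fams <- unique(table$network_label)
  out <- vapply(fams, function(fam) {
    block <- table[table$network_label == fam, , drop = FALSE]
    ord <- order(-block$authority_score, -block$in_weight_frac, block$cluster,
                 method = "radix")
    unname(class_map[block$cluster[ord[1]]])
  }, character(1))
  stats::setNames(out, fams)
}

#' Stack centrality tables from several systems for comparison
#'
#' Produces a long-format table keyed by (system, network_label, cluster);
#' node sets need not align across systems — clusters absent from a system
#' simply have no row. Systems contributing zero rows after the optional
#' network subset trigger a warning.
#'
#' @param tables named list of `centrality_table` objects (names = system
#'   labels); at least two.
#' @param network optional network label(s) (family or mechanism) to keep.
#' @return data.frame with a leading `system` column.
#' @export
compare_centrality <- function(tables, network = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (system labels)")
  if (length(tables) < 2) stop("need at least 2 systems to compare")
  blocks <- lapply(names(tables), function(sys) {
    tab <- as.data.frame(tables[[sys]])
    if (!is.null(network)) tab <- tab[tab$network_label %in% network, , drop = FALSE]
    if (nrow(tab) == 0L)
      warning("system '", sys, "' contributes no rows to the comparison")
    if (nrow(tab)) cbind(system = sys, tab) else NULL
  })
  out <- do.call(rbind, blocks)
  if (is.null(out))
    out <- data.frame(system = character(), network_label = character(),
                      cluster = character(), hub_score = numeric(),
                      authority_score = numeric(), out_weight_frac = numeric(),
                      in_weight_frac = numeric(), n_edges_considered = integer())
  rownames(out) <- NULL
  out
}

#' Write a centrality table as CSV
#' @param table a `centrality_table` (or comparison table).
#' @param path output CSV path.
#' @export
write_centrality <- function(table, path) {
  write_csv_atomic(as.data.frame(table), path)
}
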