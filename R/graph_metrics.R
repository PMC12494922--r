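#' Hop-count shortest paths of a binary graph
#'
#' Minimum number of edges between every pair of nodes; unreachable pairs
#' are `Inf` and the diagonal is 0.
#'
#' @param adj Binary-kind [fc_matrix()] or plain 0/1 adjacency matrix with
#'   zero diagonal.
#' @return Numeric path-length matrix.
#' @export
shortest_paths <- function(adj) {
  A <- if (inherits(adj, "fc_matrix")) {
    stopifnot(adj$kind == "binary")
    adj$values
  } else adj
  stopifnot(all(A %in% c(0, 1)), all(diag(A) == 0))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

#' Global efficiency of a binary graph
#'
#' Mean over nodes of the nodal efficiency: the average inverse shortest
#' path length to the other `n - 1` nodes, with unreachable pairs
#' contributing 0. Ranges from 0 (edgeless) to 1 (complete graph).
#'
#' @param adj Binary-kind [fc_matrix()] or plain 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  d <- shortest_paths(adj)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  mean(rowSums(inv) / (n - 1))
}

#' Local efficiency of a binary graph
#'
#' Mean over nodes of the efficiency of each node's neighborhood: inverse
#' shortest-path lengths between its neighbors, computed on the subgraph
#' induced by the neighborhood, normalized by `k_i (k_i - 1)`. Nodes with
#' fewer than two neighbors contribute 0. Ranges from 0 to 1.
#'
#' @param adj Binary-kind [fc_matrix()] or plain 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  A <- if (inherits(adj, "fc_matrix")) adj$values else adj
  stopifnot(all(A %in% c(0, 1)), all(diag(A) == 0))
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes")
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    d <- shortest_paths(A[nb, nb, drop = FALSE])
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
  mean(eff)
}

#' Efficiency across a proportional-threshold range
#'
#' Binarizes a correlation matrix at every threshold in `rho_values`
#' (independently, keeping the highest connectivity values), computes
#' global and local efficiency on each binary graph, and averages across
#' thresholds. The default range 0.02 to 0.10 in steps of 0.01 avoids
#' committing to a single arbitrary density.
#'
#' @param fc Correlation-kind [fc_matrix()].
#' @param rho_values Proportional thresholds (default `seq(0.02, 0.10,
#'   0.01)`).
#' @return A list of class `graph_metrics`: `per_threshold` data frame and
#'   `mean_global_eff`, `mean_local_eff`.
#' @export
efficiency_over_thresholds <- function(fc, rho_values = seq(0.02, 0.10, 0.01)) {
  stopifnot(inherits(fc, "fc_matrix"), fc$kind == "correlation",
            length(rho_values) >= 1)
  rows <- lapply(rho_values, function(rho) {
    b <- proportional_threshold(fc, rho)
    data.frame(rho = rho,
               global_eff = global_efficiency(b),
               local_eff = local_efficiency(b))
  })
  per <- do.call(rbind, rows)
  structure(
    list(per_threshold = per,
         mean_global_eff = mean(per$global_eff),
         mean_local_eff = mean(per$local_eff)),
    class = "graph_metrics"
  )
}
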