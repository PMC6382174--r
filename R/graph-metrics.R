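# Structural graph measures and partition-counting utilities.

#' Global efficiency of a binary graph
#'
#' `E = 1/(n(n-1)) * sum_{i != j} 1/d(i, j)` with `d` the unweighted
#' shortest-path hop count; unreachable pairs contribute 0, so a complete
#' graph scores 1 and an edgeless graph 0.
#'
#' @param graph A binary `phig_graph` (threshold weighted graphs first).
#' @return A number in \[0, 1\].
#' @export
global_efficiency <- function(graph) {
  stopifnot(inherits(graph, "phig_graph"))
  if (graph$n < 2) stop_invalid("global efficiency needs at least 2 nodes")
  if (!graph$binary) stop_invalid("`graph` must be binary; threshold weights to {0,1} first")
  ig <- igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                            diag = FALSE)
  D <- igraph::distances(ig)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (graph$n * (graph$n - 1))
}

#' Newman modularity via leading-eigenvector community detection
#'
#' Detects communities with Newman's spectral (leading-eigenvector)
#' algorithm, recursively bisecting while the modularity Q increases, and
#' returns Q for the detected assignment together with the node labels.
#'
#' @param graph A connected `phig_graph`.
#' @param seed Integer seed (the spectral routine's ARPACK start is seeded
#'   for reproducibility).
#' @return A list with `Q` and integer `communities`.
#' @export
modularity_newman <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "phig_graph"))
  if (!graph_is_connected(graph)) {
    stop_domain("graph is disconnected; split components before computing modularity")
  }
  ig <- as_igraph(graph)
  comm <- withr::with_seed(as.integer(seed),
                           igraph::cluster_leading_eigen(ig, weights = igraph::E(ig)$weight))
  list(Q = igraph::modularity(ig, igraph::membership(comm),
                              weights = igraph::E(ig)$weight),
       communities = as.integer(igraph::membership(comm)))
}

# Newman's Q for an arbitrary assignment (direct evaluation of the
# degree-preserving null-model formula).
modularity_q <- function(graph, communities) {
  W <- graph$weights
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  same <- outer(communities, communities, "==")
  sum((W - outer(k, k) / m2) * same) / m2
}

#' Number of unordered bipartitions of an n-node system
#'
#' `2^(n-1) - 1`, exact (e.g. 524,287 for n = 20; 536,870,911 for n = 30).
#'
#' @param n Node count (`>= 2`).
#' @return An exact count (double; exact for `n <= 53`).
#' @export
count_bipartitions <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1 || n < 2) stop_invalid("`n` must be an integer >= 2")
  if (n > 53) stop_invalid("exact bipartition counts are supported for n <= 53")
  2^(n - 1) - 1
}

#' Number of set partitions of n elements (Bell number)
#'
#' Computed exactly with the Bell-triangle recurrence (e.g. 4,140 for n = 8;
#' 4,213,597 for n = 12).
#'
#' @param n Element count (`>= 1`, `<= 22` for exact doubles).
#' @return The Bell number `B(n)`.
#' @export
count_partitions <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1 || n < 1) stop_invalid("`n` must be an integer >= 1")
  if (n > 22) stop_invalid("exact Bell numbers are supported for n <= 22")
  row <- 1
  for (i in seq_len(n - 1)) {
    new_row <- numeric(i + 1)
    new_row[1] <- row[length(row)]
    for (j in seq_len(i)) new_row[j + 1] <- new_row[j] + row[j]
    row <- new_row
  }
  row[length(row)]
}
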