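# Weighted undirected graphs: container, Laplacians, edge-list interchange.

#' Create a weighted undirected graph
#'
#' A symmetric non-negative adjacency matrix with zero diagonal, optionally
#' carrying module labels; binary graphs have weights in \{0, 1\}.
#'
#' @param weights Symmetric non-negative numeric matrix; the diagonal is
#'   forced to zero.
#' @param modules Optional integer module label per node.
#' @return An object of class `phig_graph` with elements `n`, `weights`,
#'   `modules`, `binary`.
#' @export
weighted_graph <- function(weights, modules = NULL) {
  check_finite_matrix(weights, "weights")
  if (!is_symmetric_tol(weights)) stop_invalid("`weights` must be symmetric")
  if (any(weights < 0)) stop_invalid("`weights` must be non-negative")
  W <- symmetrize(weights)
  diag(W) <- 0
  n <- nrow(W)
  if (!is.null(modules) && length(modules) != n) {
    stop_invalid("`modules` must have one label per node")
  }
  structure(list(n = n, weights = W, modules = modules,
                 binary = all(W %in% c(0, 1))),
            class = "phig_graph")
}

#' @export
print.phig_graph <- function(x, ...) {
  cat(sprintf("<phig_graph> %d nodes, %d edges%s%s\n",
              x$n, sum(x$weights[upper.tri(x$weights)] > 0),
              if (x$binary) ", binary" else ", weighted",
              if (!is.null(x$modules)) sprintf(", %d modules", length(unique(x$modules))) else ""))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

graph_is_connected <- function(graph) {
  igraph::is_connected(as_igraph(graph))
}

#' Graph Laplacian `L = D - W`
#'
#' Rows sum to zero; the matrix is positive semidefinite and its zero
#' eigenvalue has multiplicity equal to the number of connected components.
#'
#' @param graph A `phig_graph` (or adjacency matrix).
#' @return The `n x n` Laplacian matrix.
#' @export
laplacian_matrix <- function(graph) {
  W <- if (inherits(graph, "phig_graph")) graph$weights else weighted_graph(graph)$weights
  diag(rowSums(W)) - W
}

# Symmetric-normalized Laplacian I - D^{-1/2} W D^{-1/2}; isolated nodes get
# identity rows.
normalized_laplacian <- function(W) {
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(nrow(W)) - (dinv * W) * rep(dinv, each = nrow(W))
}

#' Read / write a graph as a whitespace-delimited edge list
#'
#' One edge per line: `node_i node_j [weight]`, 0-based node ids. An optional
#' first line `# n <count>` pins the node count (otherwise the largest id
#' defines it).
#'
#' @param path File path.
#' @param graph A `phig_graph`.
#' @param n Optional node count override when reading.
#' @return `read_graph_edgelist` returns a `phig_graph`;
#'   `write_graph_edgelist` returns `path` invisibly.
#' @export
read_graph_edgelist <- function(path, n = NULL) {
  lines <- readr::read_lines(path)
  header <- grepl("^#\\s*n\\s+\\d+", lines)
  if (any(header)) {
    n <- as.integer(sub("^#\\s*n\\s+(\\d+).*", "\\1", lines[which(header)[1]]))
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  ij <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  w <- vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[3]) else 1, numeric(1))
  nn <- n %||% as.integer(max(ij) + 1)
  W <- matrix(0, nn, nn)
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1] + 1; j <- ij[k, 2] + 1
    W[i, j] <- w[k]; W[j, i] <- w[k]
  }
  weighted_graph(W)
}

#' @rdname read_graph_edgelist
#' @export
write_graph_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "phig_graph"))
  ut <- which(upper.tri(graph$weights) & graph$weights > 0, arr.ind = TRUE)
  lines <- c(sprintf("# n %d", graph$n),
             sprintf("%d %d %.10g", ut[, 1] - 1L, ut[, 2] - 1L,
                     graph$weights[ut]))
  readr::write_lines(lines, path)
  invisible(path)
}
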