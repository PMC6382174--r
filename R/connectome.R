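# Synthetic structural connectomes: modular "brain-like" graphs grown with a
# Hebbian rich-get-richer degree redistribution, structurally cut variants
# with a known ground-truth bipartition, and Watts-Strogatz graphs.

# Logistic degree-target curve 1 + (Z - 1) / (1 + exp(-(c - c0)/s)) fit by
# least squares to the (x, y) redistribution profile.
fit_degree_sigmoid <- function(x, y, Z) {
  f <- function(par) {
    s <- exp(par[2])
    pred <- 1 + (Z - 1) / (1 + exp(-(x - par[1]) / s))
    sum((pred - y)^2)
  }
  init <- c(stats::median(x), log(max(diff(range(x)) / 8, 0.5)))
  fit <- optim(init, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  c0 <- fit$par[1]; s <- exp(fit$par[2])
  function(c) 1 + (Z - 1) / (1 + exp(-(c - c0) / s))
}

# One attempt at the Hebbian generator; returns a phig_graph (possibly
# disconnected; connectivity is enforced by the caller).
brain_like_attempt <- function(n, hebbian_pct) {
  M <- ceiling(log(n))
  modules <- sample.int(M, n, replace = TRUE)
  sizes <- tabulate(modules, nbins = M)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (modules[i] == modules[j]) {
        s <- sizes[modules[i]]
        p <- if (s >= 4) 4.5 / s else 4 / s
      } else {
        s <- mean(sizes[c(modules[i], modules[j])])
        p <- if (s >= 4) 3.3 / (s * M) else 3.75 / (s * M)
      }
      if (runif(1) < min(p, 1)) {
        W[i, j] <- 1; W[j, i] <- 1
      }
    }
  }

  deg <- rowSums(W)
  q <- as.numeric(quantile(deg, hebbian_pct, type = 1))
  f <- max(deg)
  xs <- (q - 1):(f + 5)
  l <- length(xs)
  Z <- (n + log(n)) / 7
  n_head <- max(min(floor(f / 4), l - 2), 0)
  n_tail <- max(min(l - f + 1, l - n_head - 1), 0)
  n_ramp <- l - n_head - n_tail
  ys <- c(rep(1, n_head),
          if (n_ramp > 0) seq(1, Z, length.out = n_ramp) else numeric(0),
          rep(Z, n_tail))
  S <- fit_degree_sigmoid(xs, ys, Z)
  # The logistic profile sets the *shape* of the redistributed degree
  # sequence (poor nodes toward 1, rich toward Z); rescale it so the total
  # connection mass is conserved, which keeps the graph dense enough to stay
  # connected while producing the long right tail.
  shape <- S(deg)
  target <- pmin(pmax(round(shape * mean(deg) / mean(shape)), 1), n - 1)

  for (node in sample.int(n)) {
    cur <- sum(W[node, ])
    if (cur < target[node]) {
      cand <- which(W[node, ] == 0 & seq_len(n) != node)
      add <- utils::head(cand[sample.int(length(cand))], target[node] - cur)
      W[node, add] <- 1; W[add, node] <- 1
    } else if (cur > target[node]) {
      nb <- which(W[node, ] == 1)
      drop <- utils::head(nb[sample.int(length(nb))], cur - target[node])
      W[node, drop] <- 0; W[drop, node] <- 0
    }
  }
  weighted_graph(W, modules = modules)
}

#' Generate a brain-like modular connectome
#'
#' Nodes are assigned uniformly to `ceiling(log(n))` modules; binary edges
#' are cast within modules with probability `4.5/s` (module size `s >= 4`,
#' else `4/s`) and across modules with probability `3.3/(s*M)` (mean module
#' size `s >= 4`, else `3.75/(s*M)`). A Hebbian rich-get-richer step then
#' redistributes degrees: the 38th-percentile degree `q` and maximum degree
#' `f` anchor a piecewise profile ramping from 1 up to `Z = (n + log(n))/7`,
#' a logistic curve is least-squares fit to it, and each node's degree is
#' adjusted toward the rounded curve value (adding edges to random
#' non-neighbours / pruning random incident edges, in seeded random node
#' order). The output is regenerated until connected.
#'
#' @param n Number of nodes (`>= 10`).
#' @param seed Integer seed (bit-reproducible output).
#' @param hebbian_pct Percentile defining the low-degree anchor `q`
#'   (default 0.38).
#' @param max_attempts Regeneration cap for the connectivity check.
#' @return A connected binary `phig_graph` with module labels.
#' @examples
#' g <- brain_like_network(20, seed = 1)
#' @export
brain_like_network <- function(n, seed, hebbian_pct = 0.38, max_attempts = 100L) {
  n <- as.integer(n)
  if (n < 10) stop_invalid("`n` must be at least 10")
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_attempts)) {
      g <- brain_like_attempt(n, hebbian_pct)
      if (graph_is_connected(g)) return(g)
    }
    abort(sprintf("failed to generate a connected network in %d attempts (seed %d)",
                  max_attempts, as.integer(seed)),
          class = "phig_generation_failure")
  })
}

#' Generate a structurally cut brain-like network with a known MIB
#'
#' Generates a brain-like network, assigns whole modules to two halves as
#' evenly as possible (ties broken at random), deletes every edge crossing
#' the halves, and verifies that each half remains internally connected
#' (regenerating otherwise). The returned cut is, by construction, a
#' bipartition with zero crossing weight: with enough data the minimum
#' information bipartition of dynamics on this graph converges onto it.
#'
#' @inheritParams brain_like_network
#' @return A list with `graph` (the cut `phig_graph`) and `cut` (the
#'   ground-truth `phig_bipartition`).
#' @export
cut_in_half <- function(n, seed, hebbian_pct = 0.38, max_attempts = 100L) {
  n <- as.integer(n)
  if (n %% 2 != 0) stop_invalid("`n` must be even for a cut network")
  seeds <- derive_seeds(seed, max_attempts)
  for (attempt in seq_len(max_attempts)) {
    g <- tryCatch(brain_like_network(n, seeds[attempt], hebbian_pct, max_attempts),
                  phig_generation_failure = function(e) NULL)
    if (is.null(g)) next
    res <- withr::with_seed(seeds[attempt] %% 1000000L + attempt, {
      M <- max(g$modules)
      sizes <- tabulate(g$modules, nbins = M)
      ord <- sample.int(M)                      # random tie-breaking
      ord <- ord[order(sizes[ord], decreasing = TRUE)]
      half <- integer(M)
      tot <- c(0L, 0L)
      for (m in ord) {
        side <- if (tot[1] <= tot[2]) 1L else 2L
        half[m] <- side
        tot[side] <- tot[side] + sizes[m]
      }
      side1 <- which(half[g$modules] == 1L)
      if (length(side1) == 0 || length(side1) == n) NULL else side1
    })
    if (is.null(res)) next
    W <- g$weights
    side2 <- setdiff(seq_len(n), res)
    W[res, side2] <- 0
    W[side2, res] <- 0
    cut_graph <- weighted_graph(W, modules = g$modules)
    comps <- igraph::components(as_igraph(cut_graph))
    ok <- comps$no == 2 &&
      length(unique(comps$membership[res])) == 1 &&
      length(unique(comps$membership[side2])) == 1
    if (ok) {
      return(list(graph = cut_graph, cut = bipartition(res, n)))
    }
  }
  abort(sprintf("failed to generate a connected cut network in %d attempts (seed %d)",
                max_attempts, as.integer(seed)),
        class = "phig_generation_failure")
}

#' Generate a Watts-Strogatz small-world graph
#'
#' Standard ring lattice of `n` nodes each linked to its `k` nearest
#' neighbours, with every lattice edge rewired with probability `p` to a
#' uniformly random non-duplicate, non-self target (edge count conserved:
#' `n * k / 2`). Regenerated until connected.
#'
#' @param n Number of nodes.
#' @param k Even mean degree, `k < n`.
#' @param p Rewiring probability in \[0, 1\].
#' @param seed Integer seed.
#' @param max_attempts Regeneration cap for the connectivity check.
#' @return A connected binary `phig_graph`.
#' @export
watts_strogatz <- function(n, k, p, seed, max_attempts = 100L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k %% 2 != 0 || k >= n || k < 2) stop_invalid("`k` must be even with 2 <= k < n")
  if (p < 0 || p > 1) stop_invalid("`p` must lie in [0, 1]")
  withr::with_seed(as.integer(seed), {
    for (attempt in seq_len(max_attempts)) {
      ig <- igraph::sample_smallworld(1, n, k / 2, p, loops = FALSE, multiple = FALSE)
      if (igraph::is_connected(ig)) {
        W <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
        return(weighted_graph((W > 0) * 1))
      }
    }
    abort(sprintf("failed to generate a connected Watts-Strogatz graph in %d attempts (seed %d)",
                  max_attempts, as.integer(seed)),
          class = "phig_generation_failure")
  })
}
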