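# Minimum information bipartition search: exhaustive scoring for small
# systems, and the spectral-clustering candidate grid built from
# power-adjacency transforms of the correlation matrix.

#' Power adjacency transform of a correlation matrix
#'
#' Maps each correlation `r` onto a non-negative edge weight
#' `w = ((r + 1) / 2)^beta`; the diagonal is set to zero.
#'
#' @param corr Symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @param beta Power `>= 1` controlling the sharpness of the transform.
#' @return A `phig_graph` with weights in \[0, 1\].
#' @export
power_adjacency <- function(corr, beta) {
  check_finite_matrix(corr, "corr")
  if (any(abs(corr) > 1 + 1e-9)) {
    stop_invalid("correlation entries must lie in [-1, 1]")
  }
  if (beta < 1) stop_invalid("`beta` must be >= 1")
  W <- ((pmin(pmax(corr, -1), 1) + 1) / 2)^beta
  diag(W) <- 0
  weighted_graph(symmetrize(W))
}

#' Zero out edge weights below a percentile cutoff
#'
#' The cutoff is the `pct` quantile of the off-diagonal upper-triangle
#' weights; weights strictly below it are set to zero. `pct = 0` returns the
#' graph unchanged.
#'
#' @param graph A `phig_graph`.
#' @param pct Percentile in \[0, 0.99\].
#' @return A thresholded `phig_graph`.
#' @export
threshold_at_percentile <- function(graph, pct) {
  stopifnot(inherits(graph, "phig_graph"))
  if (length(pct) != 1 || pct < 0 || pct > 0.99) {
    stop_invalid("`pct` must lie in [0, 0.99]")
  }
  if (pct == 0) return(graph)
  W <- graph$weights
  cutoff <- quantile(W[upper.tri(W)], pct, names = FALSE)
  W[W < cutoff] <- 0
  weighted_graph(W, modules = graph$modules)
}

#' Normalized-cut value of a bipartition
#'
#' `Ncut(A, B) = cut(A, B) / assoc(A, V) + cut(A, B) / assoc(B, V)`: the
#' weight crossing the partition, normalized by each side's total
#' association. A side with zero association contributes 0 (isolated side),
#' so the value is 0 iff no weight crosses the partition.
#'
#' @param graph A `phig_graph`.
#' @param partition A `phig_bipartition` over the graph's nodes.
#' @return A non-negative number.
#' @export
ncut_value <- function(graph, partition) {
  stopifnot(inherits(graph, "phig_graph"), inherits(partition, "phig_bipartition"))
  if (partition$n != graph$n) stop_invalid("partition does not match graph size")
  W <- graph$weights
  g1 <- partition$group1; g2 <- partition$group2
  cut <- sum(W[g1, g2, drop = FALSE])
  a1 <- sum(W[g1, , drop = FALSE])
  a2 <- sum(W[g2, , drop = FALSE])
  t1 <- if (a1 > 0) cut / a1 else 0
  t2 <- if (a2 > 0) cut / a2 else 0
  t1 + t2
}

#' Spectral bipartition of a weighted graph
#'
#' Shi-Malik style two-way spectral clustering: takes the eigenvectors of
#' the two smallest eigenvalues of the symmetric-normalized Laplacian and
#' discretizes them into two groups. Candidate roundings are k-means on the
#' eigenvector rows (k = 2, several deterministic farthest-point
#' initializations derived from `seed`) plus the sign and median splits of
#' the Fiedler vector; the rounding with the lowest normalized cut is
#' returned, mirroring the original normalized-cut algorithm's practice of
#' choosing the discretization by the cut objective.
#'
#' @param graph A `phig_graph` with at least 2 nodes.
#' @param seed Integer seed making the clustering reproducible.
#' @return A canonical `phig_bipartition`.
#' @export
spectral_bipartition <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "phig_graph"))
  n <- graph$n
  if (n < 2) stop_invalid("graph must have at least 2 nodes")
  W <- graph$weights
  if (all(W == 0)) stop_degenerate("all edge weights are zero; nothing to cluster")
  L <- normalized_laplacian(W)
  eig <- eigen(symmetrize(L), symmetric = TRUE)
  V <- eig$vectors[, c(n, n - 1), drop = FALSE]  # two smallest eigenvalues
  fiedler <- eig$vectors[, n - 1]

  cands <- list()
  spread <- max(apply(V, 2, function(v) diff(range(v))))
  if (spread > 1e-10) {
    starts <- withr::with_seed(as.integer(seed),
                               sample.int(n, min(4L, n), replace = FALSE))
    seen <- character(0)
    for (i1 in starts) {
      d1 <- rowSums((V - matrix(V[i1, ], n, 2, byrow = TRUE))^2)
      i2 <- which.max(d1)
      pair <- paste(sort(c(i1, i2)), collapse = "-")
      if (pair %in% seen || sum((V[i1, ] - V[i2, ])^2) <= 1e-20) next
      seen <- c(seen, pair)
      km <- tryCatch(
        kmeans(V, centers = V[c(i1, i2), , drop = FALSE], iter.max = 100),
        error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == 2) {
        cands <- c(cands, list(km$cluster))
      }
    }
  }
  sign_split <- ifelse(fiedler >= 0, 1L, 2L)
  if (length(unique(sign_split)) == 2) cands <- c(cands, list(sign_split))
  med_split <- ifelse(fiedler >= stats::median(fiedler), 1L, 2L)
  if (length(unique(med_split)) == 2) cands <- c(cands, list(med_split))
  if (length(cands) == 0) {
    med_split[which.max(fiedler)] <- 2L
    cands <- list(med_split)
  }

  parts <- lapply(cands, function(lab) bipartition(which(lab == lab[1]), n))
  ncuts <- vapply(parts, function(p) ncut_value(graph, p), numeric(1))
  parts[[which.min(ncuts)]]
}

#' Generate the spectral candidate-partition grid from a correlation matrix
#'
#' Builds 10 power-adjacency transforms (beta log-spaced on \[1, 10\]) plus
#' the raw correlation matrix with negative entries floored at zero, applies
#' every percentile cutoff in `pcts` (default 0 to 0.99 in steps of 0.005,
#' i.e. 199 cutoffs) to each of the 11 matrices, and runs
#' [spectral_bipartition()] on each thresholded graph: 11 x 199 = 2189
#' candidates before deduplication under the defaults. Degenerate graphs are
#' recorded as skipped.
#'
#' @param corr Correlation matrix of at least 3 channels.
#' @param seed Integer seed controlling the (deterministic) clustering.
#' @param n_betas Number of log-spaced beta values on \[1, 10\].
#' @param pcts Vector of percentile cutoffs in \[0, 0.99\].
#' @return An object of class `phig_candidates`: a list with the per-source
#'   tibble `candidates` (columns `source`, `pct`, `partition`, `key`),
#'   `unique` (deduplicated partitions with provenance of first occurrence),
#'   `n_generated`, `n_unique`, `n_skipped`.
#' @export
candidate_partitions <- function(corr, seed = 1L, n_betas = 10L,
                                 pcts = seq(0, 0.99, by = 0.005)) {
  check_finite_matrix(corr, "corr")
  n <- nrow(corr)
  if (n < 3) stop_invalid("need at least 3 channels for the candidate grid")
  if (any(abs(corr) > 1 + 1e-9)) stop_invalid("correlation entries must lie in [-1, 1]")

  betas <- 10^seq(0, 1, length.out = n_betas)
  raw <- pmax(corr, 0)
  diag(raw) <- 0
  sources <- c(lapply(betas, function(b) power_adjacency(corr, b)),
               list(weighted_graph(symmetrize(raw))))
  source_names <- c(sprintf("beta=%.4g", betas), "raw")

  rows <- vector("list", length(sources) * length(pcts))
  idx <- 0L
  skipped <- 0L
  for (s in seq_along(sources)) {
    W <- sources[[s]]$weights
    cuts <- quantile(W[upper.tri(W)], pcts, names = FALSE)
    prev_cut <- NA_real_
    prev_part <- NULL
    for (k in seq_along(pcts)) {
      idx <- idx + 1L
      cutoff <- if (pcts[k] == 0) -Inf else cuts[k]
      if (!is.na(prev_cut) && cutoff == prev_cut && !is.null(prev_part)) {
        part <- prev_part  # identical thresholded matrix
      } else {
        Wt <- W
        if (is.finite(cutoff)) Wt[Wt < cutoff] <- 0
        part <- tryCatch(
          spectral_bipartition(weighted_graph(Wt), seed = as.integer(seed) + idx),
          phig_degenerate_data = function(e) NULL)
      }
      prev_cut <- cutoff
      prev_part <- part
      if (is.null(part)) {
        skipped <- skipped + 1L
        rows[[idx]] <- tibble::tibble(source = source_names[s], pct = pcts[k],
                                      partition = list(NULL), key = NA_character_)
      } else {
        rows[[idx]] <- tibble::tibble(source = source_names[s], pct = pcts[k],
                                      partition = list(part),
                                      key = partition_key(part))
      }
    }
  }
  cand <- dplyr::bind_rows(rows)
  uniq <- cand |>
    dplyr::filter(!is.na(.data$key)) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
  structure(
    list(candidates = cand, unique = uniq,
         n_generated = nrow(cand), n_unique = nrow(uniq), n_skipped = skipped,
         seed = as.integer(seed)),
    class = "phig_candidates"
  )
}

#' @export
print.phig_candidates <- function(x, ...) {
  cat(sprintf("<phig_candidates> %d generated, %d unique, %d skipped\n",
              x$n_generated, x$n_unique, x$n_skipped))
  invisible(x)
}

new_mib_result <- function(best, method, n_evaluated, n_skipped, candidates) {
  structure(list(best = best, method = method, n_evaluated = n_evaluated,
                 n_skipped = n_skipped, candidates = candidates),
            class = "phig_mib")
}

#' Exhaustive search for the minimum information bipartition
#'
#' Scores normalized integrated information for every canonical bipartition
#' of the model's channels and returns the minimizer (ties broken by smaller
#' raw `phi_bits`, then by enumeration order). Partitions failing the `K`
#' safeguard are skipped and counted. Practical cap at 18 channels
#' (2^17 - 1 partitions); use [spectral_mib()] beyond that.
#'
#' @param model A `phig_model`.
#' @param opts Settings from [phi_opts()].
#' @param keep_table Whether to retain the full per-partition tibble.
#' @return An object of class `phig_mib` with elements `best` (a
#'   `phig_phi`), `method`, `n_evaluated`, `n_skipped`, and `candidates`.
#' @export
brute_force_mib <- function(model, opts = phi_opts(), keep_table = FALSE) {
  stopifnot(inherits(model, "phig_model"))
  n <- model$n
  if (n > 18) {
    stop_invalid(paste0("brute force is capped at 18 channels (", n,
                        " requested); use spectral_mib() for large systems"))
  }
  parts <- enumerate_bipartitions(n)
  best <- NULL
  n_eval <- 0L
  n_skip <- 0L
  rows <- if (keep_table) vector("list", length(parts)) else NULL
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    K <- normalization_K(model$Sigma_past, p, opts$k_eps)
    if (!K$valid) {
      n_skip <- n_skip + 1L
      next
    }
    res <- phi_g(model, p, opts)
    n_eval <- n_eval + 1L
    if (keep_table) {
      rows[[i]] <- tibble::tibble(key = partition_key(p),
                                  phi_bits = res$phi_bits,
                                  normalized_phi = res$normalized_phi,
                                  partition = list(p))
    }
    if (is.null(best) ||
        res$normalized_phi < best$normalized_phi ||
        (res$normalized_phi == best$normalized_phi && res$phi_bits < best$phi_bits)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop_degenerate("every bipartition failed the K safeguard; no valid MIB")
  }
  tab <- if (keep_table) dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))]) else NULL
  new_mib_result(best, "brute", n_eval, n_skip, tab)
}

#' Spectral-clustering approximation of the minimum information bipartition
#'
#' Builds the Pearson correlation matrix of the time series, generates the
#' candidate-partition grid with [candidate_partitions()], fits the
#' transition model once at lag `tau`, evaluates normalized integrated
#' information on each unique valid candidate, and returns the minimizer
#' together with the per-candidate table.
#'
#' @param ts Time-series matrix (rows = time points, columns = channels).
#' @param tau Positive integer lag.
#' @param opts Settings from [phi_opts()].
#' @param seed Integer seed for the clustering grid.
#' @param n_betas,pcts Candidate-grid resolution passed to
#'   [candidate_partitions()]; the defaults reproduce the full 2189-candidate
#'   grid.
#' @param model Optional pre-fitted `phig_model` (must match `ts` and `tau`).
#' @param screen For systems whose feasible sets are too large for the
#'   fixed-point solver, score candidates with a faster loose-tolerance pass
#'   and re-optimize only the winner at full tolerance (the returned `best`
#'   is always fully converged). Has no effect on small systems.
#' @return An object of class `phig_mib`.
#' @export
spectral_mib <- function(ts, tau, opts = phi_opts(), seed = 1L, n_betas = 10L,
                         pcts = seq(0, 0.99, by = 0.005), model = NULL,
                         screen = TRUE) {
  ts <- as.matrix(ts)
  corr <- cor(ts)
  cands <- candidate_partitions(corr, seed = seed, n_betas = n_betas, pcts = pcts)
  if (is.null(model)) model <- fit_transition_model(ts, tau)

  use_screen <- screen && model$n > 30
  quiet_phi <- function(p, o) {
    withCallingHandlers(
      phi_g(model, p, o),
      phig_convergence_warning = function(w) invokeRestart("muffleWarning"))
  }
  screen_opts <- function(iters) {
    phi_opts(tol = 1e-5, max_iter = iters, restart = FALSE, k_eps = opts$k_eps)
  }

  uniq <- cands$unique
  results <- vector("list", nrow(uniq))
  n_eval <- 0L
  n_skip <- cands$n_skipped
  for (i in seq_len(nrow(uniq))) {
    p <- uniq$partition[[i]]
    K <- normalization_K(model$Sigma_past, p, opts$k_eps)
    if (!K$valid) {
      n_skip <- n_skip + 1L
      next
    }
    results[[i]] <- quiet_phi(p, if (use_screen) screen_opts(8L) else opts)
    n_eval <- n_eval + 1L
  }
  scored <- which(!vapply(results, is.null, logical(1)))
  if (length(scored) == 0) {
    stop_degenerate(paste0("all ", nrow(uniq),
                           " unique candidates were invalid (K safeguard or degenerate graphs)"))
  }
  if (use_screen) {
    # second screening tier: re-optimize the leading candidates more
    # carefully before committing to a winner
    ord <- scored[order(vapply(results[scored], function(r) r$normalized_phi,
                               numeric(1)))]
    for (i in utils::head(ord, 5L)) {
      results[[i]] <- quiet_phi(uniq$partition[[i]], screen_opts(60L))
    }
  }
  vals <- vapply(results[scored], function(r) r$normalized_phi, numeric(1))
  raw <- vapply(results[scored], function(r) r$phi_bits, numeric(1))
  best_i <- scored[order(vals, raw)][1]
  best <- results[[best_i]]
  if (use_screen) {
    best <- phi_g(model, best$partition, opts)
  }
  rows <- lapply(scored, function(i) {
    tibble::tibble(source = uniq$source[i], pct = uniq$pct[i],
                   key = uniq$key[i],
                   phi_bits = results[[i]]$phi_bits,
                   normalized_phi = results[[i]]$normalized_phi,
                   partition = uniq$partition[i])
  })
  tab <- dplyr::bind_rows(rows)
  new_mib_result(best, "spectral", n_eval, n_skip, tab)
}

#' @export
print.phig_mib <- function(x, ...) {
  cat(sprintf("<phig_mib> method = %s, %d partitions scored (%d skipped)\n",
              x$method, x$n_evaluated, x$n_skipped))
  print(x$best)
  invisible(x)
}

#' Tidy the per-candidate table of a MIB search
#'
#' @param x A `phig_mib` object (run with the table retained).
#' @param ... Unused.
#' @export
tidy.phig_mib <- function(x, ...) {
  if (is.null(x$candidates)) {
    stop_invalid("no per-candidate table was retained for this search")
  }
  x$candidates
}

#' One-row summary of a MIB search
#'
#' @param x A `phig_mib` object.
#' @param ... Unused.
#' @export
glance.phig_mib <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method, n_evaluated = x$n_evaluated,
                   n_skipped = x$n_skipped),
    glance(x$best)
  )
}
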