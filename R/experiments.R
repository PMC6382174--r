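# Validation experiments: small-network MIB recovery, structurally cut
# networks, and the Watts-Strogatz structure sweep. Each run returns a
# reproducible report whose aggregates recompute from its per-network
# records.

new_report <- function(experiment, records, aggregates, config, failures = 0L) {
  structure(list(experiment = experiment, records = records,
                 aggregates = aggregates, config = config,
                 n_failed = failures,
                 version = as.character(utils::packageVersion("phig"))),
            class = "phig_report")
}

#' @export
print.phig_report <- function(x, ...) {
  cat(sprintf("<phig_report> experiment = %s, %d networks (%d failed)\n",
              x$experiment, nrow(x$records), x$n_failed))
  agg <- x$aggregates
  for (nm in names(agg)) cat(sprintf("  %s = %.6g\n", nm, agg[[nm]]))
  invisible(x)
}

#' Per-network records of a validation experiment
#'
#' @param x A `phig_report`.
#' @param ... Unused.
#' @return The per-network tibble.
#' @export
tidy.phig_report <- function(x, ...) x$records

#' One-row aggregate summary of a validation experiment
#'
#' @param x A `phig_report`.
#' @param ... Unused.
#' @export
glance.phig_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(experiment = x$experiment,
                                  n_networks = nrow(x$records),
                                  n_failed = x$n_failed),
                   tibble::as_tibble(x$aggregates))
}

# Default reduced-scale candidate grid for large systems: 3 betas + raw,
# percentile step 0.1 (coarse but spanning the same cutoff range).
coarse_pcts <- function() seq(0, 0.9, by = 0.1)

resolve_sigma <- function(rule, graph) {
  if (is.numeric(rule)) return(rule)
  if (identical(rule, "msf_mid")) return(master_stability_coupling(graph)$sigma_mid)
  stop_invalid("`sigma` must be a number or \"msf_mid\"")
}

simulate_for <- function(graph, dynamics, sigma_rule, n_points, seed,
                         record_every = 100L, coupling = 0.25) {
  if (dynamics == "rossler") {
    sigma <- resolve_sigma(sigma_rule, graph)
    simulate_rossler(graph,
                     rossler_params(sigma = sigma, n_points = n_points,
                                    record_every = record_every),
                     seed)
  } else {
    simulate_var(graph, coupling = coupling, n_points = n_points, seed = seed)$ts
  }
}

#' Small-network validation: does the spectral search find the exact MIB?
#'
#' For each seeded brain-like network, simulates dynamics, runs both the
#' brute-force and the spectral MIB searches at the same lag, and records
#' the normalized-Phi difference (spectral minus exhaustive minimum; always
#' `>= 0`) and the Rand index between the two partitions. Aggregates the
#' exact-match fraction and mean difference.
#'
#' @param n_networks Number of networks.
#' @param sizes Node counts cycled over the networks (brute force caps at
#'   18).
#' @param n_points Recorded samples per simulation.
#' @param tau Time lag (in recorded samples) for the transition model.
#' @param record_every Oscillator recording interval in integration steps
#'   (see [rossler_params()]); ignored for VAR dynamics.
#' @param dynamics `"rossler"` or `"var"`.
#' @param sigma Coupling rule: a number, or `"msf_mid"` for the
#'   master-stability midpoint.
#' @param seed Master seed; per-network child seeds are derived from it.
#' @param opts Settings from [phi_opts()].
#' @param n_betas,pcts Spectral candidate-grid resolution.
#' @return A `phig_report` with per-network records and aggregates
#'   `match_fraction`, `mean_diff`, `mean_rand`.
#' @export
run_small_validation <- function(n_networks = 10L, sizes = c(12L, 14L),
                                 n_points = 25000L, tau = 1L,
                                 record_every = 400L,
                                 dynamics = c("rossler", "var"),
                                 sigma = "msf_mid", seed = 1L,
                                 opts = phi_opts(), n_betas = 10L,
                                 pcts = seq(0, 0.99, by = 0.005)) {
  dynamics <- match.arg(dynamics)
  if (any(sizes > 18)) stop_invalid("brute force validation requires sizes <= 18")
  seeds <- derive_seeds(seed, 2L * n_networks)
  size_of <- rep_len(sizes, n_networks)
  rows <- vector("list", n_networks)
  failures <- 0L
  for (i in seq_len(n_networks)) {
    rec <- tryCatch({
      g <- brain_like_network(size_of[i], seed = seeds[i])
      ts <- simulate_for(g, dynamics, sigma, n_points, seeds[n_networks + i],
                         record_every = record_every)
      model <- fit_transition_model(ts, tau)
      brute <- brute_force_mib(model, opts)
      spect <- spectral_mib(ts, tau, opts = opts, seed = seeds[i],
                           n_betas = n_betas, pcts = pcts, model = model)
      tibble::tibble(
        network = i, n_nodes = size_of[i], seed = seeds[i],
        brute_normalized = brute$best$normalized_phi,
        spectral_normalized = spect$best$normalized_phi,
        diff = spect$best$normalized_phi - brute$best$normalized_phi,
        rand = rand_index(spect$best$partition, brute$best$partition),
        brute_partition = partition_key(brute$best$partition),
        spectral_partition = partition_key(spect$best$partition)
      )
    }, error = function(e) NULL)
    if (is.null(rec)) failures <- failures + 1L else rows[[i]] <- rec
  }
  records <- dplyr::bind_rows(rows)
  if (nrow(records) == 0) stop_degenerate("every network in the experiment failed")
  agg <- list(match_fraction = mean(records$diff <= 1e-10),
              mean_diff = mean(records$diff),
              mean_rand = mean(records$rand))
  new_report("small_validation", records, agg,
             config = list(n_networks = n_networks, sizes = sizes,
                           n_points = n_points, tau = tau, dynamics = dynamics,
                           sigma = sigma, seed = seed, n_betas = n_betas,
                           pct_step = if (length(pcts) > 1) pcts[2] - pcts[1] else NA),
             failures = failures)
}

#' Cut-network validation: recovering a structurally forced MIB
#'
#' For each seeded cut network (two halves with every crossing edge
#' deleted), simulates dynamics, runs the spectral MIB search, and compares
#' normalized Phi across the spectral partition with normalized Phi across
#' the ground-truth cut, plus their Rand index. Aggregates the mean absolute
#' difference and the fraction of networks with Rand index above 0.8.
#'
#' @inheritParams run_small_validation
#' @param sizes Even node counts cycled over the networks.
#' @export
run_cut_validation <- function(n_networks = 10L, sizes = 50L,
                               n_points = 100000L, tau = 1L,
                               record_every = 100L,
                               dynamics = c("rossler", "var"),
                               sigma = "msf_mid", seed = 1L,
                               opts = phi_opts(), n_betas = 10L,
                               pcts = seq(0, 0.99, by = 0.005)) {
  dynamics <- match.arg(dynamics)
  seeds <- derive_seeds(seed, 2L * n_networks)
  size_of <- rep_len(as.integer(sizes), n_networks)
  rows <- vector("list", n_networks)
  failures <- 0L
  for (i in seq_len(n_networks)) {
    rec <- tryCatch({
      cg <- cut_in_half(size_of[i], seed = seeds[i])
      # the halves synchronize independently: take the wider of the two
      # halves' master-stability intervals via the full (cut) graph halves
      sig <- if (identical(sigma, "msf_mid")) cut_sigma(cg) else sigma
      ts <- simulate_for(cg$graph, dynamics, sig, n_points,
                         seeds[n_networks + i], record_every = record_every)
      model <- fit_transition_model(ts, tau)
      spect <- spectral_mib(ts, tau, opts = opts, seed = seeds[i],
                           n_betas = n_betas, pcts = pcts, model = model)
      truth <- normalized_phi(model, cg$cut, opts)
      tibble::tibble(
        network = i, n_nodes = size_of[i], seed = seeds[i],
        spectral_normalized = spect$best$normalized_phi,
        cut_normalized = truth$normalized_phi,
        abs_diff = abs(spect$best$normalized_phi - truth$normalized_phi),
        rand = rand_index(spect$best$partition, cg$cut),
        spectral_partition = partition_key(spect$best$partition),
        cut_partition = partition_key(cg$cut)
      )
    }, error = function(e) NULL)
    if (is.null(rec)) failures <- failures + 1L else rows[[i]] <- rec
  }
  records <- dplyr::bind_rows(rows)
  if (nrow(records) == 0) stop_degenerate("every network in the experiment failed")
  agg <- list(mean_abs_diff = mean(records$abs_diff),
              frac_rand_gt_0.8 = mean(records$rand > 0.8),
              mean_rand = mean(records$rand))
  new_report("cut_validation", records, agg,
             config = list(n_networks = n_networks, sizes = sizes,
                           n_points = n_points, tau = tau, dynamics = dynamics,
                           sigma = sigma, seed = seed, n_betas = n_betas,
                           pct_step = if (length(pcts) > 1) pcts[2] - pcts[1] else NA),
             failures = failures)
}

# Master-stability midpoint for a cut graph: the Laplacian of the cut graph
# is block-diagonal, so use the smallest positive eigenvalue across the two
# halves as the synchronization bound.
cut_sigma <- function(cg) {
  ev <- sort(eigen(laplacian_matrix(cg$graph), symmetric = TRUE,
                   only.values = TRUE)$values)
  lambda2 <- ev[ev > 1e-8][1]
  lambda_max <- ev[length(ev)]
  (0.186 / lambda2 + 4.614 / lambda_max) / 2
}

#' Structure sweep: integrated information vs efficiency and modularity
#'
#' Sweeps the Watts-Strogatz rewiring probability grid (by default 10
#' log-spaced values in \[0.001, 0.1\] plus 9 linear values in \[0.1, 1\]),
#' generating `n_per_p` seeded networks per value. Each network's binary
#' global efficiency and Newman modularity Q are computed on the structural
#' graph; oscillator dynamics are simulated at a fixed coupling (0.25) and
#' non-normalized Phi-G across the spectral MIB is recorded. Aggregates the
#' Spearman correlations of Phi with efficiency and with Q across all
#' networks.
#'
#' @inheritParams run_small_validation
#' @param n_per_p Networks per rewiring probability.
#' @param n_nodes Nodes per network.
#' @param k Even mean degree of the ring lattice.
#' @param p_grid Rewiring probabilities (default: the 19-value grid above).
#' @param sigma Fixed oscillator coupling (0.25 by default so dynamics
#'   differences are attributable to connectivity).
#' @export
run_structure_sweep <- function(n_per_p = 5L, n_nodes = 100L, k = 6L,
                                p_grid = default_p_grid(),
                                n_points = 25000L, tau = 1L,
                                record_every = 25L,
                                dynamics = c("rossler", "var"),
                                sigma = 0.25, seed = 1L, opts = phi_opts(),
                                n_betas = 3L, pcts = coarse_pcts()) {
  dynamics <- match.arg(dynamics)
  n_total <- length(p_grid) * n_per_p
  seeds <- derive_seeds(seed, 2L * n_total)
  rows <- vector("list", n_total)
  failures <- 0L
  idx <- 0L
  for (pi in seq_along(p_grid)) {
    for (r in seq_len(n_per_p)) {
      idx <- idx + 1L
      rec <- tryCatch({
        g <- watts_strogatz(n_nodes, k, p_grid[pi], seed = seeds[idx])
        eff <- global_efficiency(g)
        Q <- modularity_newman(g, seed = seeds[idx])$Q
        ts <- simulate_for(g, dynamics, sigma, n_points,
                           seeds[n_total + idx], record_every = record_every)
        spect <- spectral_mib(ts, tau, opts = opts, seed = seeds[idx],
                             n_betas = n_betas, pcts = pcts)
        tibble::tibble(p = p_grid[pi], replicate = r, seed = seeds[idx],
                       efficiency = eff, modularity = Q,
                       phi_bits = spect$best$phi_bits,
                       normalized_phi = spect$best$normalized_phi,
                       partition = partition_key(spect$best$partition))
      }, error = function(e) NULL)
      if (is.null(rec)) failures <- failures + 1L else rows[[idx]] <- rec
    }
  }
  records <- dplyr::bind_rows(rows)
  if (nrow(records) == 0) stop_degenerate("every network in the experiment failed")
  agg <- list(
    spearman_phi_efficiency = cor(records$phi_bits, records$efficiency,
                                  method = "spearman"),
    spearman_phi_modularity = cor(records$phi_bits, records$modularity,
                                  method = "spearman")
  )
  new_report("structure_sweep", records, agg,
             config = list(n_per_p = n_per_p, n_nodes = n_nodes, k = k,
                           p_grid = p_grid, n_points = n_points, tau = tau,
                           dynamics = dynamics, sigma = sigma, seed = seed,
                           n_betas = n_betas,
                           pct_step = if (length(pcts) > 1) pcts[2] - pcts[1] else NA),
             failures = failures)
}

#' Default rewiring-probability grid for the structure sweep
#'
#' Ten log-spaced values on \[0.001, 0.1\] followed by nine linearly spaced
#' values on \[0.1, 1\] (the 0.1 endpoint is not repeated).
#'
#' @return A numeric vector of 19 probabilities.
#' @export
default_p_grid <- function() {
  c(10^seq(log10(0.001), log10(0.1), length.out = 10),
    seq(0.1, 1, length.out = 10)[-1])
}

#' Plot a validation-experiment report
#'
#' Small validation: normalized-Phi differences per network. Cut validation:
#' Rand index per network. Structure sweep: Phi against efficiency or
#' modularity.
#'
#' @param object A `phig_report`.
#' @param metric For the structure sweep, `"efficiency"` or `"modularity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phig_report <- function(object, metric = c("efficiency", "modularity"), ...) {
  rec <- object$records
  if (object$experiment == "small_validation") {
    return(ggplot2::ggplot(rec, ggplot2::aes(x = factor(.data$network), y = .data$diff)) +
             ggplot2::geom_col() +
             ggplot2::labs(x = "network", y = "normalized Φ difference (spectral - MIB)") +
             ggplot2::theme_minimal())
  }
  if (object$experiment == "cut_validation") {
    return(ggplot2::ggplot(rec, ggplot2::aes(x = factor(.data$network), y = .data$rand)) +
             ggplot2::geom_col() +
             ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
             ggplot2::labs(x = "network", y = "Rand index vs ground-truth cut") +
             ggplot2::theme_minimal())
  }
  metric <- match.arg(metric)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data[[metric]], y = .data$phi_bits)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = metric, y = "integrated information (bits)") +
    ggplot2::theme_minimal()
}
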