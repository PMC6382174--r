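# Dynamics on structural networks: coupled stochastic Rossler oscillators
# (with master-stability coupling bounds) and stable VAR(1) processes.

#' Master-stability coupling bounds for Rossler x-coupling
#'
#' For networks of identical Rossler oscillators coupled through the
#' Laplacian on the x-equation, the synchronizable coupling interval is
#' bounded below by `0.186 / lambda_2` (the Fiedler eigenvalue) and above by
#' `4.614 / lambda_max`. Returns both bounds and their midpoint, with a
#' warning when the interval is empty (unsynchronizable network).
#'
#' @param graph A connected `phig_graph`.
#' @return A list with `sigma_lower`, `sigma_upper`, `sigma_mid`.
#' @examples
#' master_stability_coupling(watts_strogatz(20, 4, 0.1, seed = 1))
#' @export
master_stability_coupling <- function(graph) {
  stopifnot(inherits(graph, "phig_graph"))
  ev <- sort(eigen(laplacian_matrix(graph), symmetric = TRUE, only.values = TRUE)$values)
  lambda2 <- ev[2]
  lambda_max <- ev[length(ev)]
  if (lambda2 < 1e-10) {
    stop_domain("graph is disconnected (Fiedler eigenvalue ~ 0); no synchronization bounds")
  }
  lower <- 0.186 / lambda2
  upper <- 4.614 / lambda_max
  if (lower > upper) {
    warn("master-stability interval is empty: the network is unsynchronizable",
         class = "phig_unsynchronizable")
  }
  list(sigma_lower = lower, sigma_upper = upper, sigma_mid = (lower + upper) / 2)
}

#' Parameters of the stochastic Rossler oscillator model
#'
#' Defaults follow the standard weakly-coupled regime: `a = b = 0.2`,
#' `c = 9`, per-oscillator frequencies drawn from `N(10, 0.1)`, noise
#' amplitude `d = 750` entering the y-equation, Euler step `dt = 0.001`.
#' With the plain-Euler noise discretization (`d * eta * dt` per step) the
#' per-step y-noise standard deviation is 0.75.
#'
#' @param sigma Coupling strength (`>= 0`).
#' @param a,b,c Rossler shape parameters.
#' @param w_mean,w_sd Mean and sd of the per-oscillator frequency draw.
#' @param d Noise amplitude.
#' @param dt Integration step.
#' @param n_points Number of recorded samples (`>= 100`).
#' @param burn_in Integration steps discarded before recording.
#' @param record_every Recording interval in integration steps: one sample
#'   is kept every `record_every` steps, so the recording covers
#'   `n_points * record_every * dt` time units. The default (100, i.e. one
#'   sample per 0.1 time units) spaces samples far enough apart that
#'   consecutive observations are not dominated by single-step integration
#'   noise.
#' @param noise `"euler"` scales the noise by `dt` (plain Euler, the
#'   default); `"euler-maruyama"` scales by `sqrt(dt)`.
#' @return A list of parameters for [simulate_rossler()].
#' @export
rossler_params <- function(sigma, a = 0.2, b = 0.2, c = 9, w_mean = 10,
                           w_sd = 0.1, d = 750, dt = 0.001,
                           n_points = 25000L, burn_in = 5000L,
                           record_every = 100L,
                           noise = c("euler", "euler-maruyama")) {
  noise <- match.arg(noise)
  if (dt <= 0) stop_invalid("`dt` must be positive")
  if (sigma < 0) stop_invalid("`sigma` must be non-negative")
  if (n_points < 100) stop_invalid("`n_points` must be at least 100")
  if (record_every < 1) stop_invalid("`record_every` must be a positive integer")
  list(sigma = sigma, a = a, b = b, c = c, w_mean = w_mean, w_sd = w_sd,
       d = d, dt = dt, n_points = as.integer(n_points),
       burn_in = as.integer(burn_in), record_every = as.integer(record_every),
       noise = noise)
}

#' Simulate coupled stochastic Rossler oscillators on a graph
#'
#' Euler integration of the three-variable Rossler system per node, with
#' diffusive coupling `-sigma * sum_h g_ih x_h` (Laplacian coefficients
#' `g_ih`) on the x-equation and Gaussian noise `d * eta` on the y-equation.
#' Initial states are uniform on \[-1, 1\]^3; `burn_in` steps are discarded
#' and the y component of every oscillator is then recorded every
#' `record_every`-th step. Identical seeds give bitwise-identical output.
#'
#' @param graph A `phig_graph`; its node count sets the oscillator count.
#' @param params Parameters from [rossler_params()].
#' @param seed Integer seed.
#' @return An `n_points x n` time-series matrix of y components.
#' @export
simulate_rossler <- function(graph, params, seed) {
  stopifnot(inherits(graph, "phig_graph"))
  L <- laplacian_matrix(graph)
  noise_scale <- if (params$noise == "euler") params$dt else sqrt(params$dt)
  withr::with_seed(as.integer(seed), {
    w <- rnorm(graph$n, params$w_mean, params$w_sd)
    rossler_euler(L, w, params$a, params$b, params$c, params$d, params$sigma,
                  params$dt, params$n_points, params$burn_in, noise_scale,
                  params$record_every %||% 1L)
  })
}

#' Simulate a stable VAR(1) process on a graph
#'
#' Builds the coefficient matrix `A = self * I + coupling * W / rowdeg`
#' (row-normalized adjacency), rescales it to spectral radius 0.9 if it is
#' not already below, and iterates `x_t = A x_{t-1} + e` with standard-normal
#' innovations from a stationary start (burn-in discarded).
#'
#' @param graph A `phig_graph`.
#' @param coupling Non-negative coupling weight on the normalized adjacency.
#' @param n_points Number of recorded samples.
#' @param seed Integer seed.
#' @param self Self-coupling coefficient (default 0.2).
#' @param burn_in Samples discarded at the start.
#' @return A list with `ts` (the `n_points x n` matrix) and `A` (the
#'   coefficient matrix actually used).
#' @export
simulate_var <- function(graph, coupling, n_points, seed, self = 0.2,
                         burn_in = 500L) {
  stopifnot(inherits(graph, "phig_graph"))
  if (coupling < 0) stop_invalid("`coupling` must be non-negative")
  n <- graph$n
  W <- graph$weights
  deg <- rowSums(W)
  Wn <- W / ifelse(deg > 0, deg, 1)
  A <- diag(self, n) + coupling * Wn
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho == 0) stop_invalid("coefficient matrix is zero; nothing to simulate")
  if (rho > 0.9) A <- A * (0.9 / rho)
  total <- as.integer(n_points) + as.integer(burn_in)
  ts <- withr::with_seed(as.integer(seed), {
    E <- matrix(rnorm(total * n), total, n)
    X <- matrix(0, total, n)
    X[1, ] <- E[1, ]
    for (t in 2:total) X[t, ] <- as.vector(A %*% X[t - 1, ]) + E[t, ]
    X
  })
  list(ts = ts[(burn_in + 1):total, , drop = FALSE], A = A)
}
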