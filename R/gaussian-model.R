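# Gaussian transition model: lagged covariances, normal-equation regression,
# residual covariance, and entropy / mutual-information primitives.

#' Lagged sample covariances of a multivariate time series
#'
#' Aligns the `m - tau` pairs `(x[t - tau, ], x[t, ])` for `t = tau + 1, ..., m`,
#' demeans each channel over its own aligned window, and returns the three
#' sample covariance matrices (denominator `n_pairs - 1`) that define the
#' lagged Gaussian model: the covariance of the past window, the covariance of
#' the present window, and the cross-covariance `Cov(X_t, X_{t-tau})`.
#'
#' @param ts Numeric matrix, `m` time points (rows) by `n` channels (columns).
#' @param tau Positive integer lag in samples; must satisfy `1 <= tau <= m - 2`.
#'
#' @return A list with elements `Sigma_past`, `Sigma_present`, `Sigma_cross`
#'   (all `n x n`) and `n_pairs`.
#' @export
lagged_covariances <- function(ts, tau) {
  ts <- as.matrix(ts)
  check_finite_matrix(ts, "ts")
  m <- nrow(ts); n <- ncol(ts)
  if (m < 2 || n < 2) stop_invalid("time series needs at least 2 rows and 2 columns")
  if (length(tau) != 1 || tau != as.integer(tau) || tau < 1 || tau > m - 2) {
    stop_invalid(sprintf("`tau` must be an integer in [1, %d] for %d time points", m - 2L, m))
  }
  tau <- as.integer(tau)
  past <- ts[seq_len(m - tau), , drop = FALSE]
  present <- ts[(tau + 1):m, , drop = FALSE]
  np <- m - tau

  sds <- pmin(apply(past, 2, sd), apply(present, 2, sd))
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    labs <- colnames(ts) %||% as.character(seq_len(n))
    stop_degenerate(sprintf(
      "channel(s) %s have zero variance over the aligned window",
      paste(labs[bad], collapse = ", ")
    ))
  }

  past_c <- scale(past, center = TRUE, scale = FALSE)
  pres_c <- scale(present, center = TRUE, scale = FALSE)
  Sigma_past <- symmetrize(crossprod(past_c) / (np - 1))
  Sigma_present <- symmetrize(crossprod(pres_c) / (np - 1))
  Sigma_cross <- crossprod(pres_c, past_c) / (np - 1)
  dimnames(Sigma_past) <- dimnames(Sigma_present) <- dimnames(Sigma_cross) <-
    list(colnames(ts), colnames(ts))
  list(Sigma_past = Sigma_past, Sigma_present = Sigma_present,
       Sigma_cross = Sigma_cross, n_pairs = np)
}

#' Construct a Gaussian transition model from covariance matrices
#'
#' Builds the lagged linear-regression ("full") model of a Gaussian system:
#' the regression matrix comes from the normal equation
#' `A = Sigma_cross %*% solve(Sigma_past)` and the residual covariance is the
#' conditional covariance of the present given the past,
#' `Sigma_E = Sigma_present - A %*% t(Sigma_cross)`.
#'
#' @param Sigma_past,Sigma_present `n x n` covariance matrices of the lagged
#'   and current state.
#' @param Sigma_cross `n x n` cross-covariance `Cov(X_t, X_{t-tau})`.
#' @param tau Positive integer lag the covariances refer to.
#' @param n_pairs Number of sample pairs behind the estimates (`NA` for
#'   analytic models).
#' @param cond_cap Condition-number cap for `Sigma_past`; beyond it a
#'   conditioning error is raised rather than silently regularizing.
#'
#' @return An object of class `phig_model`.
#' @export
gaussian_model <- function(Sigma_past, Sigma_present, Sigma_cross, tau = 1L,
                           n_pairs = NA_integer_, cond_cap = 1e12) {
  check_finite_matrix(Sigma_past, "Sigma_past")
  check_finite_matrix(Sigma_present, "Sigma_present")
  check_finite_matrix(Sigma_cross, "Sigma_cross")
  n <- nrow(Sigma_past)
  if (!is_symmetric_tol(Sigma_past) || !is_symmetric_tol(Sigma_present)) {
    stop_invalid("Sigma_past and Sigma_present must be symmetric")
  }
  kp <- kappa(Sigma_past, exact = TRUE)
  if (!is.finite(kp) || kp > cond_cap) {
    stop_conditioning(sprintf(
      "Sigma_past is ill-conditioned (condition number %.3g exceeds cap %.3g)", kp, cond_cap))
  }
  A <- Sigma_cross %*% solve(Sigma_past)
  Sigma_E <- symmetrize(Sigma_present - A %*% t(Sigma_cross))
  structure(
    list(tau = as.integer(tau), n = n,
         Sigma_past = symmetrize(Sigma_past),
         Sigma_present = symmetrize(Sigma_present),
         Sigma_cross = Sigma_cross,
         A = A, Sigma_E = Sigma_E,
         n_pairs = n_pairs,
         channel_labels = colnames(Sigma_past)),
    class = "phig_model"
  )
}

#' Fit the Gaussian transition model of a time series at a given lag
#'
#' @inheritParams lagged_covariances
#' @param cond_cap Condition-number cap for the past covariance (see
#'   [gaussian_model()]).
#'
#' @return An object of class `phig_model`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(4000), ncol = 4)
#' fit_transition_model(x, tau = 1)
#' @export
fit_transition_model <- function(ts, tau, cond_cap = 1e12) {
  cc <- lagged_covariances(ts, tau)
  gaussian_model(cc$Sigma_past, cc$Sigma_present, cc$Sigma_cross,
                 tau = tau, n_pairs = cc$n_pairs, cond_cap = cond_cap)
}

#' Analytic stationary Gaussian model of a VAR(1) process
#'
#' For `x_t = A %*% x_{t-1} + e`, `e ~ N(0, Sigma_noise)`, solves the discrete
#' Lyapunov equation `S = A S A' + Sigma_noise` for the stationary covariance
#' and assembles the exact lag-`tau` transition model
#' (`Sigma_cross = A^tau %*% S`). Useful as a noise-free oracle.
#'
#' @param A Stable (`spectral radius < 1`) coefficient matrix.
#' @param Sigma_noise Innovation covariance (defaults to the identity).
#' @param tau Positive integer lag.
#' @return An object of class `phig_model`.
#' @export
var_stationary_model <- function(A, Sigma_noise = diag(nrow(A)), tau = 1L) {
  check_finite_matrix(A, "A")
  n <- nrow(A)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop_invalid("`A` must have spectral radius < 1 for a stationary model")
  }
  S <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Sigma_noise)), n, n)
  S <- symmetrize(S)
  Atau <- diag(n)
  for (i in seq_len(as.integer(tau))) Atau <- Atau %*% A
  gaussian_model(S, S, Atau %*% S, tau = tau)
}

#' Differential entropy of a multivariate Gaussian, in bits
#'
#' `H = 0.5 * log2((2 * pi * e)^n * det(Sigma))`. Block-diagonal covariances
#' give the sum of block entropies.
#'
#' @param Sigma Symmetric positive-definite covariance matrix (a scalar is
#'   treated as a 1x1 variance).
#' @return Entropy in bits.
#' @export
gaussian_entropy <- function(Sigma) {
  if (!is.matrix(Sigma)) Sigma <- matrix(Sigma, 1, 1)
  if (!is_symmetric_tol(Sigma)) stop_invalid("`Sigma` must be symmetric")
  n <- nrow(Sigma)
  0.5 * (n * log2(2 * pi * exp(1)) + logdet2(Sigma))
}

#' Total mutual information carried across the model's time lag
#'
#' `I(X_t; X_{t-tau}) = 0.5 * log2(det(Sigma_present) / det(Sigma_E))`, the
#' information the past carries about the present under the full model; an
#' upper bound for integrated information across any partition.
#'
#' @param model A `phig_model`.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information_time <- function(model) {
  stopifnot(inherits(model, "phig_model"))
  0.5 * (logdet2(model$Sigma_present, "Sigma_present") -
           logdet2(model$Sigma_E, "Sigma_E"))
}

#' @export
print.phig_model <- function(x, ...) {
  cat(sprintf("<phig_model> %d channels, lag tau = %d, %s pairs\n",
              x$n, x$tau,
              ifelse(is.na(x$n_pairs), "analytic (no)", format(x$n_pairs))))
  cat(sprintf("  max |A| = %.4f, temporal MI = %.4f bits\n",
              max(abs(x$A)), tryCatch(mutual_information_time(x),
                                      error = function(e) NA_real_)))
  invisible(x)
}

#' Tidy the regression coefficients of a Gaussian transition model
#'
#' @param x A `phig_model`.
#' @param ... Unused.
#' @return A tibble with one row per (target, source) coefficient of the
#'   regression matrix.
#' @export
tidy.phig_model <- function(x, ...) {
  labs <- x$channel_labels %||% as.character(seq_len(x$n))
  tibble::tibble(
    target = rep(labs, times = x$n),
    source = rep(labs, each = x$n),
    estimate = as.vector(x$A)
  )
}

#' One-row summary of a Gaussian transition model
#'
#' @param x A `phig_model`.
#' @param ... Unused.
#' @export
glance.phig_model <- function(x, ...) {
  tibble::tibble(
    n_channels = x$n, tau = x$tau, n_pairs = x$n_pairs,
    mutual_information = tryCatch(mutual_information_time(x),
                                  error = function(e) NA_real_),
    max_abs_coefficient = max(abs(x$A))
  )
}
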