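# Shared fixture builders and independent oracles used across test files.

# Random symmetric positive-definite matrix.
random_spd <- function(n, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (n + 2)), n + 2, n)
    crossprod(X) / (n + 2)
  })
}

# Random stable VAR(1) coefficient matrix with the given spectral radius.
random_stable_A <- function(n, seed, radius = 0.7) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n, sd = 1 / sqrt(n)), n, n)
    A * radius / max(Mod(eigen(A, only.values = TRUE)$values))
  })
}

# Stationary covariance of x_t = A x_{t-1} + e via the discrete Lyapunov
# equation, solved directly in vectorized form (independent of the package's
# own var_stationary_model()).
lyapunov_cov <- function(A, Sigma_noise = diag(nrow(A))) {
  n <- nrow(A)
  matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Sigma_noise)), n, n)
}

# Dense grid-search oracle for phi on a 2-channel model: evaluates the
# profiled objective over diagonal A' at step 1e-3, vectorized in
# memory-bounded chunks over the second coordinate.
phi_grid_2ch <- function(model, lo = -1.5, hi = 1.5, step = 1e-3) {
  A <- model$A; S <- model$Sigma_past; SE <- model$Sigma_E
  ps <- seq(lo, hi, by = step)
  det_E <- SE[1, 1] * SE[2, 2] - SE[1, 2]^2
  d12 <- A[1, 2]; d21 <- A[2, 1]
  best <- Inf
  for (qs in split(ps, ceiling(seq_along(ps) / 200))) {
    d11 <- rep(A[1, 1] - ps, times = length(qs))
    d22 <- rep(A[2, 2] - qs, each = length(ps))
    m11 <- SE[1, 1] + d11^2 * S[1, 1] + 2 * d11 * d12 * S[1, 2] + d12^2 * S[2, 2]
    m12 <- SE[1, 2] + d11 * d21 * S[1, 1] + (d11 * d22 + d12 * d21) * S[1, 2] +
      d12 * d22 * S[2, 2]
    m22 <- SE[2, 2] + d21^2 * S[1, 1] + 2 * d21 * d22 * S[1, 2] + d22^2 * S[2, 2]
    det_grid <- m11 * m22 - m12^2
    best <- min(best, min(det_grid[det_grid > 0]))
  }
  0.5 * (log2(best) - log2(det_E))
}

# Derivative-free multi-start oracle for 3-channel models (independent
# algorithm and code path from the package's solvers).
phi_nm_3ch <- function(model, partition, n_starts = 8, seed = 1) {
  A <- model$A; S <- model$Sigma_past; SE <- model$Sigma_E
  n <- 3
  g <- integer(n); g[partition$group1] <- 1L; g[partition$group2] <- 2L
  mask <- outer(g, g, "==")
  ldE <- 2 * sum(log2(diag(chol(SE))))
  f <- function(par) {
    Ap <- matrix(0, n, n); Ap[mask] <- par
    D <- A - Ap
    M <- SE + D %*% S %*% t(D)
    R <- tryCatch(chol((M + t(M)) / 2), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    0.5 * (2 * sum(log2(diag(R))) - ldE)
  }
  k <- sum(mask)
  best <- Inf
  withr::with_seed(seed, {
    starts <- c(list((A * mask)[mask]),
                lapply(seq_len(n_starts - 1), function(i) rnorm(k, sd = 0.5)))
    for (st in starts) {
      r1 <- optim(st, f, method = "Nelder-Mead",
                  control = list(maxit = 3000, reltol = 1e-13))
      r2 <- optim(r1$par, f, method = "Nelder-Mead",
                  control = list(maxit = 3000, reltol = 1e-14))
      best <- min(best, r2$value)
    }
  })
  best
}

# Direct evaluation of Newman's Q for a fixed assignment (independent of the
# package's internal helper).
q_direct <- function(W, comm) {
  m2 <- sum(W)
  k <- rowSums(W)
  tot <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) tot <- tot + W[i, j] - k[i] * k[j] / m2
    }
  }
  tot / m2
}

# Small deterministic time series with a known two-block structure.
two_block_var_ts <- function(m = 20000, seed = 42, coupling = 0.35) {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- coupling * 0.5; A[4:6, 4:6] <- coupling * 0.5
  diag(A) <- 0.5
  withr::with_seed(seed, {
    X <- matrix(0, m, 6)
    E <- matrix(rnorm(m * 6), m, 6)
    X[1, ] <- E[1, ]
    for (t in 2:m) X[t, ] <- as.vector(A %*% X[t - 1, ]) + E[t, ]
    X
  })
}
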