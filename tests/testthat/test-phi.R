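test_that("phi is zero exactly when the regression matrix is block-diagonal", {
  # feasible point attains KL = 0
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- matrix(c(0.5, 0.2, 0.1, 0.4), 2)
  A[3:4, 3:4] <- matrix(c(0.3, -0.2, 0.2, 0.5), 2)
  m <- var_stationary_model(A)
  r <- phi_g(m, bipartition(1:2, 4))
  expect_lt(r$phi_bits, 1e-6)
  expect_lt(max(abs(r$A_prime - A)), 1e-4)
  expect_equal(r$normalized_phi, 0, tolerance = 1e-6)

  # converse: off-block coupling forces phi away from zero
  A[1, 3] <- 0.3
  r2 <- phi_g(var_stationary_model(A), bipartition(1:2, 4))
  expect_gt(r2$phi_bits, 1e-3)
})

test_that("phi matches the dense grid oracle on a 2-channel system", {
  A <- matrix(c(0.8, 0.4, 0.0, 0.7), 2, 2, byrow = TRUE)
  m <- gaussian_model(lyapunov_cov(A), lyapunov_cov(A), A %*% lyapunov_cov(A))
  r <- phi_g(m, bipartition(1, 2))
  expect_equal(r$phi_bits, phi_grid_2ch(m), tolerance = 1e-4)
})

test_that("optimizer agrees with independent oracles on random 2- and 3-channel systems", {
  for (s in 1:12) {
    A <- random_stable_A(2, seed = 300 + s, radius = 0.85)
    m <- var_stationary_model(A)
    r <- phi_g(m, bipartition(1, 2))
    expect_equal(r$phi_bits, phi_grid_2ch(m), tolerance = 1e-4)
  }
  for (s in 1:8) {
    A <- random_stable_A(3, seed = 400 + s, radius = 0.85)
    m <- var_stationary_model(A)
    p <- bipartition(1, 3)
    r <- phi_g(m, p)
    expect_equal(r$phi_bits, phi_nm_3ch(m, p, seed = s), tolerance = 1e-4)
  }
})

test_that("the fixed-point and quasi-Newton solvers agree", {
  A <- random_stable_A(8, seed = 99, radius = 0.8)
  m <- var_stationary_model(A)
  p <- bipartition(c(1, 3, 5, 7), 8)
  r_fp <- phi_g(m, p)  # n_free = 32 -> fixed point
  # force the L-BFGS path by lowering the fixed-point size cutoff is not
  # exposed; instead check against the generic optimizer via optim directly
  mask <- outer(rep(1:2, 4) == 1, rep(1:2, 4) == 1, "==") |
    outer(rep(1:2, 4) == 2, rep(1:2, 4) == 2, "==")
  S <- m$Sigma_past; SE <- m$Sigma_E
  ldE <- 2 * sum(log2(diag(chol(SE))))
  f <- function(par) {
    Ap <- matrix(0, 8, 8); Ap[mask] <- par
    D <- m$A - Ap
    M <- SE + D %*% S %*% t(D)
    0.5 * (2 * sum(log2(diag(chol((M + t(M)) / 2)))) - ldE)
  }
  res <- optim((m$A * mask)[mask], f, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(r_fp$phi_bits, res$value, tolerance = 1e-5)
})

test_that("phi is bounded by the temporal mutual information", {
  for (s in 1:10) {
    A <- random_stable_A(4, seed = 500 + s, radius = 0.8)
    m <- var_stationary_model(A)
    mi <- mutual_information_time(m)
    for (p in list(bipartition(1, 4), bipartition(1:2, 4), bipartition(c(1, 3), 4))) {
      phi <- phi_g(m, p)$phi_bits
      expect_gte(phi, 0)
      expect_lte(phi, mi + 1e-6)
    }
  }
})

test_that("phi is invariant under per-channel rescaling of the data", {
  x <- two_block_var_ts(m = 5000, seed = 81)
  p <- bipartition(1:3, 6)
  base <- phi_g(fit_transition_model(x, 1), p)$phi_bits
  y <- x
  y[, 2] <- y[, 2] * 7.3
  y[, 5] <- y[, 5] * -0.04
  scaled <- phi_g(fit_transition_model(y, 1), p)$phi_bits
  expect_equal(base, scaled, tolerance = 1e-6)
})

test_that("normalization K takes the smaller marginal entropy with a safeguard", {
  # identity covariance split 2|2: both sides equal the 2-D Gaussian entropy
  r <- normalization_K(diag(4), bipartition(1:2, 4))
  expect_equal(r$K_bits, log2(2 * pi * exp(1)), tolerance = 1e-12)
  expect_true(r$valid)
  # random SPD, unbalanced split: direct formula evaluation as oracle
  S <- random_spd(6, seed = 91)
  p <- bipartition(1:2, 6)
  r2 <- normalization_K(S, p)
  h1 <- 0.5 * log2((2 * pi * exp(1))^2 * det(S[1:2, 1:2]))
  h2 <- 0.5 * log2((2 * pi * exp(1))^4 * det(S[3:6, 3:6]))
  expect_equal(r2$K_bits, min(h1, h2), tolerance = 1e-9)
  # near-constant channel trips the safeguard
  S3 <- diag(c(1e-30, 1, 1, 1))
  expect_false(normalization_K(S3, bipartition(1, 4))$valid)
})

test_that("normalized phi is the ratio of phi to K, absent when K is invalid", {
  A <- random_stable_A(4, seed = 101, radius = 0.7)
  m <- var_stationary_model(A)
  p <- bipartition(c(1, 4), 4)
  r <- normalized_phi(m, p)
  expect_equal(r$normalized_phi * r$K_bits, r$phi_bits, tolerance = 1e-9)
  # invalid K: a near-constant channel trips the entropy safeguard
  m2 <- var_stationary_model(diag(0.5, 4), Sigma_noise = diag(c(1e-10, 1, 1, 1)))
  r2 <- normalized_phi(m2, bipartition(1, 4))
  expect_false(r2$valid)
  expect_true(is.na(r2$normalized_phi))
})

test_that("the disconnected model dominates the full model's residual covariance", {
  for (s in 1:5) {
    A <- random_stable_A(5, seed = 600 + s, radius = 0.8)
    m <- var_stationary_model(A)
    r <- phi_g(m, bipartition(c(1, 2), 5))
    # A' is exactly block-constrained
    mask <- phig:::block_mask(r$partition)
    expect_true(all(r$A_prime[!mask] == 0))
    # Sigma_E' - Sigma_E is PSD
    dE <- r$Sigma_Eprime - m$Sigma_E
    expect_gt(min(eigen((dE + t(dE)) / 2, only.values = TRUE)$values), -1e-8)
  }
})

test_that("select_time_lag finds a planted interaction delay", {
  # channel 2 driven by channel 1 delayed by exactly 2 samples
  x <- withr::with_seed(111, {
    m <- 20000
    e <- matrix(rnorm(2 * m), m, 2)
    x1 <- as.vector(stats::filter(e[, 1], 0.5, method = "recursive"))
    x2 <- 0.9 * c(0, 0, x1[1:(m - 2)]) + e[, 2]
    cbind(x1, x2)
  })
  scan <- select_time_lag(x, lags = c(1, 2, 3), search = "brute")
  expect_equal(scan$tau_star, 2L)
  expect_false(scan$all_near_zero)
  expect_equal(nrow(scan$table), 3)

  # white noise: all lags near zero, flagged
  wn <- withr::with_seed(112, matrix(rnorm(30000), ncol = 3))
  expect_warning(scan2 <- select_time_lag(wn, lags = c(1, 2)),
                 class = "phig_all_near_zero")
  expect_true(scan2$all_near_zero)
  expect_true(all(scan2$table$phi_bits < 0.01))

  expect_error(select_time_lag(wn, lags = integer(0)),
               class = "phig_invalid_argument")
})
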