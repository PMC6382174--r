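test_that("lagged covariances recover independence and analytic VAR structure", {
  # i.i.d. channels: no lagged covariance, unit variances
  set.seed(11)
  x <- matrix(rnorm(30000), ncol = 3)
  cc <- lagged_covariances(x, tau = 1)
  expect_lt(max(abs(cc$Sigma_cross)), 0.05)
  expect_lt(max(abs(cc$Sigma_past - diag(3))), 0.05)
  expect_equal(cc$n_pairs, nrow(x) - 1L)

  # stable VAR(1): sample covariances match the Lyapunov-equation oracle
  A <- random_stable_A(5, seed = 21, radius = 0.7)
  S_true <- lyapunov_cov(A)
  sim <- withr::with_seed(22, {
    X <- matrix(0, 50000, 5); E <- matrix(rnorm(50000 * 5), 50000, 5)
    X[1, ] <- E[1, ]
    for (t in 2:50000) X[t, ] <- as.vector(A %*% X[t - 1, ]) + E[t, ]
    X
  })
  cc2 <- lagged_covariances(sim, tau = 1)
  expect_lt(max(abs(cc2$Sigma_past - S_true)), 0.05)
  expect_lt(max(abs(cc2$Sigma_present - S_true)), 0.05)
  expect_lt(max(abs(cc2$Sigma_cross - A %*% S_true)), 0.05)
})

test_that("lagged covariances validate their inputs", {
  x <- matrix(rnorm(40), ncol = 2)
  expect_error(lagged_covariances(x, tau = 19), class = "phig_invalid_argument")
  expect_error(lagged_covariances(x, tau = 0), class = "phig_invalid_argument")
  x[, 2] <- 1  # constant channel
  expect_error(lagged_covariances(x, tau = 1), class = "phig_degenerate_data")
})

test_that("covariance estimates are symmetric and PSD across random inputs", {
  for (s in 1:5) {
    x <- withr::with_seed(s, matrix(rnorm(2000), ncol = 4))
    cc <- lagged_covariances(x, tau = 2)
    expect_lt(max(abs(cc$Sigma_past - t(cc$Sigma_past))), 1e-12)
    expect_gt(min(eigen(cc$Sigma_past, only.values = TRUE)$values), -1e-8)
    expect_gt(min(eigen(cc$Sigma_present, only.values = TRUE)$values), -1e-8)
  }
})

test_that("fit_transition_model recovers generator coefficients", {
  A0 <- diag(0.5, 5)
  sim <- withr::with_seed(31, {
    X <- matrix(0, 50000, 5); E <- matrix(rnorm(50000 * 5), 50000, 5)
    X[1, ] <- E[1, ]
    for (t in 2:50000) X[t, ] <- 0.5 * X[t - 1, ] + E[t, ]
    X
  })
  model <- fit_transition_model(sim, tau = 1)
  expect_lt(max(abs(model$A - A0)), 0.05)
  # residual covariance is the conditional covariance identity
  expect_lt(max(abs(model$Sigma_E -
                      (model$Sigma_present - model$A %*% t(model$Sigma_cross)))), 1e-10)
  # white noise: no temporal structure
  wn <- withr::with_seed(32, matrix(rnorm(50000), ncol = 5))
  expect_lt(max(abs(fit_transition_model(wn, 1)$A)), 0.05)
})

test_that("duplicated channels trigger a conditioning error", {
  x <- withr::with_seed(33, matrix(rnorm(2000), ncol = 2))
  x <- cbind(x, x[, 2])
  expect_error(fit_transition_model(x, 1), class = "phig_conditioning_error")
})

test_that("VAR parameter recovery error shrinks as the sample grows", {
  A <- random_stable_A(4, seed = 41, radius = 0.85)
  err_at <- function(m, seed) {
    sim <- withr::with_seed(seed, {
      X <- matrix(0, m, 4); E <- matrix(rnorm(m * 4), m, 4)
      X[1, ] <- E[1, ]
      for (t in 2:m) X[t, ] <- as.vector(A %*% X[t - 1, ]) + E[t, ]
      X
    })
    max(abs(fit_transition_model(sim, 1)$A - A))
  }
  errs <- sapply(c(1e3, 1e4, 1e5), function(m) {
    mean(sapply(1:3, function(r) err_at(m, 100 * r + log10(m))))
  })
  expect_true(errs[1] > errs[2] && errs[2] > errs[3])
})

test_that("gaussian entropy matches closed forms and the log-determinant rules", {
  expect_equal(gaussian_entropy(diag(2)), log2(2 * pi * exp(1)), tolerance = 1e-12)
  # doubling one standard deviation adds exactly one bit
  S <- random_spd(3, seed = 51)
  S2 <- S
  S2[1, ] <- S2[1, ] * 2
  S2[, 1] <- S2[, 1] * 2  # sd of channel 1 doubled
  expect_equal(gaussian_entropy(S2) - gaussian_entropy(S), 1, tolerance = 1e-10)
  # block-diagonal covariance: entropies add
  B <- matrix(0, 5, 5)
  B[1:2, 1:2] <- random_spd(2, seed = 52)
  B[3:5, 3:5] <- random_spd(3, seed = 53)
  expect_equal(gaussian_entropy(B),
               gaussian_entropy(B[1:2, 1:2]) + gaussian_entropy(B[3:5, 3:5]),
               tolerance = 1e-9)
  expect_error(gaussian_entropy(matrix(1, 2, 2)), class = "phig_domain_error")
})

test_that("temporal mutual information matches the AR(1) closed form and is non-negative", {
  # univariate AR(1), coefficient 0.8: I = 0.5*log2(1/(1-a^2)) per channel
  a <- 0.8
  m <- var_stationary_model(diag(a, 2))
  expect_equal(mutual_information_time(m), 2 * 0.5 * log2(1 / (1 - a^2)),
               tolerance = 1e-10)
  # white noise carries nothing
  wn <- withr::with_seed(61, matrix(rnorm(40000), ncol = 4))
  expect_lt(abs(mutual_information_time(fit_transition_model(wn, 1))), 0.02)
  # non-negativity across random models
  for (s in 1:10) {
    A <- random_stable_A(3, seed = 200 + s, radius = runif(1, 0.2, 0.9))
    expect_gte(mutual_information_time(var_stationary_model(A)), -1e-9)
  }
  # degenerate (deterministic channel) input errors
  bad <- var_stationary_model(diag(0.5, 2))
  bad$Sigma_E <- matrix(c(1, 1, 1, 1), 2)
  expect_error(mutual_information_time(bad), class = "phig_domain_error")
})

test_that("tidy and glance summarise a fitted model", {
  x <- withr::with_seed(71, matrix(rnorm(4000), ncol = 4))
  model <- fit_transition_model(x, 1)
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 16)
  gl <- glance(model)
  expect_equal(gl$n_channels, 4)
  expect_equal(gl$tau, 1)
})
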