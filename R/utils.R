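# Internal helpers: error signalling, matrix predicates, seeding.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "phig_invalid_argument", ...)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "phig_domain_error", ...)
}

stop_degenerate <- function(msg, ...) {
  abort(msg, class = "phig_degenerate_data", ...)
}

stop_conditioning <- function(msg, ...) {
  abort(msg, class = "phig_conditioning_error", ...)
}

symmetrize <- function(M) (M + t(M)) / 2

is_symmetric_tol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

# log2 determinant of a symmetric positive-definite matrix via Cholesky;
# signals a domain error when the matrix is not PD.
logdet2 <- function(Sigma, what = "covariance matrix") {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    stop_domain(paste0(what, " is not positive definite"))
  }
  2 * sum(log2(diag(R)))
}

is_pd <- function(Sigma) {
  !is.null(tryCatch(chol(Sigma), error = function(e) NULL))
}

check_finite_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(sprintf("`%s` must be a numeric matrix", name))
  }
  if (!all(is.finite(x))) {
    stop_invalid(sprintf("`%s` contains non-finite entries", name))
  }
  invisible(x)
}

# Deterministic child seeds below 2^31 derived from a master seed.
derive_seeds <- function(master, k) {
  withr::with_seed(as.integer(master), sample.int(.Machine$integer.max - 1L, k))
}
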