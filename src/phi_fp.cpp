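#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Block fixed-point solver for the disconnected-model regression matrix.
// Inputs are permuted so group 1 occupies the first k1 rows/columns. With
// W = M^{-1} frozen, the stationarity condition [W (A - A') S]_block = 0 is
// linear in the within-block entries of A'; the linear solve is iterated
// with Aitken extrapolation and step-halving whenever the objective (in
// bits) fails to decrease. Convergence: gradient norm <= tol, or objective
// decrease per iteration below ~1e-12 bits.
// [[Rcpp::export]]
Rcpp::List phi_fixed_point(const arma::mat& A, const arma::mat& S,
                           const arma::mat& SE, int k1, double tol,
                           int maxit,
                           Rcpp::Nullable<Rcpp::NumericMatrix> init =
                               R_NilValue) {
  const int n = A.n_rows;
  const double ln2 = std::log(2.0);
  const span s1(0, k1 - 1), s2(k1, n - 1);

  mat RE;
  if (!chol(RE, symmatu(SE)))
    Rcpp::stop("residual covariance is not positive definite");
  const double ldE_ln = 2.0 * accu(log(RE.diag()));

  auto fval = [&](const mat& Ac) -> double {
    mat D = A - Ac;
    mat M = symmatu(SE + D * S * D.t());
    mat R;
    if (!chol(R, M)) return datum::inf;
    return (2.0 * accu(log(R.diag())) - ldE_ln) / (2.0 * ln2);  // bits
  };

  mat cur(n, n, fill::zeros);
  if (init.isNotNull()) {
    cur = Rcpp::as<mat>(init.get());
  } else {
    cur(s1, s1) = A(s1, s1);
    cur(s2, s2) = A(s2, s2);
  }
  double f_cur = fval(cur);
  double gn = datum::inf;
  mat prev_step;
  bool have_prev = false;
  bool converged = false;
  int iters = 0;

  for (int it = 1; it <= maxit; ++it) {
    iters = it;
    mat D = A - cur;
    mat M = symmatu(SE + D * S * D.t());
    mat W;
    if (!inv_sympd(W, M)) break;
    mat G = -(W * D * S) / ln2;  // gradient in bits (free entries only)
    gn = std::sqrt(accu(square(G(s1, s1))) + accu(square(G(s2, s2))));
    if (gn <= tol) { converged = true; break; }

    mat WAS = W * A * S;
    mat lhs = join_vert(
        join_horiz(kron(S(s1, s1).t(), W(s1, s1)),
                   kron(S(s2, s1).t(), W(s1, s2))),
        join_horiz(kron(S(s1, s2).t(), W(s2, s1)),
                   kron(S(s2, s2).t(), W(s2, s2))));
    vec rhs = join_vert(vectorise(WAS(s1, s1)), vectorise(WAS(s2, s2)));
    vec sol;
    if (!solve(sol, lhs, rhs)) break;

    mat prop(n, n, fill::zeros);
    prop(s1, s1) = reshape(sol.head(k1 * k1), k1, k1);
    prop(s2, s2) = reshape(sol.tail((n - k1) * (n - k1)), n - k1, n - k1);

    mat step = prop - cur;
    if (have_prev) {
      double denom = accu(square(prev_step));
      double rho = denom > 0 ? accu(step % prev_step) / denom : 0.0;
      if (std::isfinite(rho) && rho > 0.0 && rho < 0.95) {
        mat prop2 = cur + step / (1.0 - rho);
        if (fval(prop2) < fval(prop)) prop = prop2;
      }
    }

    double f_prop = fval(prop);
    int halvings = 0;
    while (f_prop > f_cur + 1e-14 && halvings < 30) {
      prop = (prop + cur) / 2.0;
      f_prop = fval(prop);
      ++halvings;
    }
    if (f_prop > f_cur + 1e-14) { converged = true; break; }  // stalled
    const bool stalled = (f_cur - f_prop) < 1e-12;
    prev_step = prop - cur;
    have_prev = true;
    cur = prop;
    f_cur = f_prop;
    if (stalled) { converged = true; break; }
  }

  {  // final gradient norm at the returned point
    mat D = A - cur;
    mat M = symmatu(SE + D * S * D.t());
    mat W;
    if (inv_sympd(W, M)) {
      mat G = -(W * D * S) / ln2;
      gn = std::sqrt(accu(square(G(s1, s1))) + accu(square(G(s2, s2))));
      if (gn <= tol) converged = true;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("A_prime") = cur, Rcpp::Named("value") = f_cur,
      Rcpp::Named("grad_norm") = gn, Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged);
}
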