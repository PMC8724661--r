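// Frisch-Newton primal-dual interior point solver for weighted check-loss
// (quantile) regression, formulated on the bounded dual
//
//   max  ytil' a   s.t.  Xtil' a = (1 - tau) Xtil' 1,  0 <= a <= 1,
//
// where Xtil, ytil carry the observation weights (rho_tau(w u) = w rho_tau(u),
// so a weight w scales the design row and response jointly).  The multiplier
// of the equality constraint converges to -beta_hat.
//
// The solver accepts D response columns that share one design matrix X: the
// effective problem stacks X vertically D times with entry weights
// w(i, d) = rw(i) * cw(d).  Because row (i, d) of the stacked design is
// w(i, d) * X.row(i), the Newton normal matrix collapses to X' diag(g) X
// with g_i = sum_d w(i, d)^2 q(i, d), so the stack is never materialized.
// This is what makes the SAEM M-step over a pool of simulated random
// effects affordable: the pool only contributes extra response columns.
// The hot loops are written flat (single pass, no temporaries) because the
// working set is N x D.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// solve the (symmetric positive definite) Newton system; near convergence
// the barrier terms make it ill-conditioned, so retry with a tiny ridge
// instead of accepting an approximate least-squares fallback
static bool solve_newton(vec& out, mat M, const vec& rhs) {
  if (solve(out, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx))
    return true;
  double ridge = 1e-12 * trace(M) / M.n_rows + 1e-300;
  for (int t = 0; t < 4; ++t) {
    M.diag() += ridge;
    if (solve(out, M, rhs, solve_opts::likely_sympd + solve_opts::no_approx))
      return true;
    ridge *= 1e3;
  }
  return false;
}

// [[Rcpp::export]]
Rcpp::List rqfn_multi_cpp(const arma::mat& X, const arma::mat& Y,
                          const arma::vec& rw, const arma::vec& cw,
                          double tau, double eps = 1e-10, int maxit = 100) {
  const uword n = X.n_rows, p = X.n_cols, D = Y.n_cols;
  const uword nE = n * D;
  const double step_factor = 0.99995;

  if (rw.n_elem != n || cw.n_elem != D)
    Rcpp::stop("weight vector dimensions disagree with the responses");

  // entry weights and scaled (minimization-form) responses ct = -(w % y)
  vec wts(nE), ct(nE);
  {
    const double* yp = Y.memptr();
    for (uword d = 0; d < D; ++d)
      for (uword i = 0; i < n; ++i) {
        wts(d * n + i) = rw(i) * cw(d);
        ct(d * n + i) = -wts(d * n + i) * yp[d * n + i];
      }
  }

  vec a(nE), s(nE), z(nE), w(nE), q(nE), r(nE), da(nE), dz(nE), dw(nE),
      pa(nE), qs(nE);
  a.fill(1.0 - tau);
  s.fill(tau);

  // initial multiplier: weighted least squares of ct on the stacked design
  vec g(n, fill::zeros), rag(n, fill::zeros);
  for (uword d = 0; d < D; ++d)
    for (uword i = 0; i < n; ++i) {
      const uword e = d * n + i;
      g(i) += wts(e) * wts(e);
      rag(i) += wts(e) * ct(e);
    }
  mat Mn = X.t() * (X.each_col() % g);
  vec yd;
  if (!solve_newton(yd, Mn, X.t() * rag))
    Rcpp::stop("singular design in interior point initialization");

  vec Xy = X * yd;
  double absr = 0;
  for (uword d = 0; d < D; ++d)
    for (uword i = 0; i < n; ++i) {
      const uword e = d * n + i;
      r(e) = ct(e) - wts(e) * Xy(i);
      absr += std::abs(r(e));
    }
  const double d0 = std::max(absr / nE, 1e-8);
  for (uword e = 0; e < nE; ++e) {
    z(e) = std::max(r(e), 0.0) + 0.1 * d0;
    w(e) = z(e) - r(e);
  }

  double gap = dot(a, z) + dot(s, w);
  const double scale_ref = 1.0 + accu(abs(ct)) / nE;
  const double tol = eps * nE * scale_ref;

  int it = 0;
  vec dy(p), dy2(p);
  while (gap > tol && it < maxit) {
    ++it;

    // affine predictor: build q, r and the collapsed Newton system
    g.zeros();
    rag.zeros();
    for (uword d = 0; d < D; ++d)
      for (uword i = 0; i < n; ++i) {
        const uword e = d * n + i;
        q(e) = 1.0 / (z(e) / a(e) + w(e) / s(e));
        r(e) = z(e) - w(e);
        g(i) += wts(e) * wts(e) * q(e);
        rag(i) += wts(e) * q(e) * r(e);
      }
    Mn = X.t() * (X.each_col() % g);
    if (!solve_newton(dy, Mn, X.t() * rag))
      Rcpp::stop("singular Newton system in interior point solver");
    Xy = X * dy;

    double ap = 1.0 / step_factor, ad = 1.0 / step_factor;
    for (uword d = 0; d < D; ++d)
      for (uword i = 0; i < n; ++i) {
        const uword e = d * n + i;
        da(e) = q(e) * (wts(e) * Xy(i) - r(e));
        dz(e) = -z(e) - z(e) / a(e) * da(e);
        dw(e) = -w(e) + w(e) / s(e) * da(e);
        if (da(e) < 0 && -a(e) / da(e) < ap) ap = -a(e) / da(e);
        if (da(e) > 0 && s(e) / da(e) < ap) ap = s(e) / da(e);
        if (dz(e) < 0 && -z(e) / dz(e) < ad) ad = -z(e) / dz(e);
        if (dw(e) < 0 && -w(e) / dw(e) < ad) ad = -w(e) / dw(e);
      }
    ap = std::min(1.0, step_factor * ap);
    ad = std::min(1.0, step_factor * ad);

    if (std::min(ap, ad) < 1.0) {
      // Mehrotra corrector (reuses the affine normal matrix)
      double g_aff = 0;
      for (uword e = 0; e < nE; ++e)
        g_aff += (a(e) + ap * da(e)) * (z(e) + ad * dz(e)) +
                 (s(e) - ap * da(e)) * (w(e) + ad * dw(e));
      const double mu_t = std::pow(g_aff / gap, 3) * gap / (2.0 * nE);

      rag.zeros();
      for (uword d = 0; d < D; ++d)
        for (uword i = 0; i < n; ++i) {
          const uword e = d * n + i;
          pa(e) = da(e) * dz(e) / a(e);
          qs(e) = -da(e) * dw(e) / s(e);
          const double rc = r(e) - mu_t * (1.0 / a(e) - 1.0 / s(e)) +
                            pa(e) - qs(e);
          r(e) = rc;  // r now holds the corrected residual
          rag(i) += wts(e) * q(e) * rc;
        }
      if (!solve_newton(dy2, Mn, X.t() * rag))
        Rcpp::stop("singular Newton system in interior point solver");
      dy = dy2;
      Xy = X * dy;

      ap = 1.0 / step_factor;
      ad = 1.0 / step_factor;
      for (uword d = 0; d < D; ++d)
        for (uword i = 0; i < n; ++i) {
          const uword e = d * n + i;
          da(e) = q(e) * (wts(e) * Xy(i) - r(e));
          dz(e) = mu_t / a(e) - z(e) - z(e) / a(e) * da(e) - pa(e);
          dw(e) = mu_t / s(e) - w(e) + w(e) / s(e) * da(e) - qs(e);
          if (da(e) < 0 && -a(e) / da(e) < ap) ap = -a(e) / da(e);
          if (da(e) > 0 && s(e) / da(e) < ap) ap = s(e) / da(e);
          if (dz(e) < 0 && -z(e) / dz(e) < ad) ad = -z(e) / dz(e);
          if (dw(e) < 0 && -w(e) / dw(e) < ad) ad = -w(e) / dw(e);
        }
      ap = std::min(1.0, step_factor * ap);
      ad = std::min(1.0, step_factor * ad);
    }

    gap = 0;
    for (uword e = 0; e < nE; ++e) {
      a(e) += ap * da(e);
      s(e) -= ap * da(e);
      z(e) += ad * dz(e);
      w(e) += ad * dw(e);
      gap += a(e) * z(e) + s(e) * w(e);
    }
    yd += ad * dy;
  }

  vec beta = -yd;
  // weighted check-loss objective at beta
  vec Xb = X * beta;
  double obj = 0;
  {
    const double* yp = Y.memptr();
    for (uword d = 0; d < D; ++d)
      for (uword i = 0; i < n; ++i) {
        const double res = yp[d * n + i] - Xb(i);
        obj += rw(i) * cw(d) * res * (tau - (res < 0 ? 1.0 : 0.0));
      }
  }

  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("gap") = gap,
                            Rcpp::Named("converged") = (gap <= tol));
}
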