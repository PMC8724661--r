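// Random-walk Metropolis-Hastings simulation of the subject-level random
// effects b_i from their conditional distribution
//
//   f(b | y_i, theta) propto exp{ -sum_j rho_tau((y_ij - x_ij'beta - z_ij'b)/sigma) }
//                            * N_r(b; 0, Psi),
//
// the E-step draw of the SAEM algorithm.  Proposals are N(b, scale^2 * Psi).
// Uses R's RNG so whole-fit reproducibility follows from set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double target_logpost(const vec& o, const mat& Z, const vec& b,
                             const mat& Linv, double sigma, double tau) {
  // o = y_i - X_i beta (residual without random effects)
  vec r = o - Z * b;
  double closs = accu(r % (tau - conv_to<vec>::from(r < 0)));
  vec u = Linv * b;                 // Linv = inv(chol_lower(Psi))
  return -closs / sigma - 0.5 * dot(u, u);
}

// [[Rcpp::export]]
Rcpp::List mh_estep_cpp(const arma::vec& resid_fixed, const arma::mat& Z,
                        const arma::ivec& subj_start, const arma::ivec& subj_len,
                        const arma::mat& bstart, const arma::mat& Lpsi,
                        double sigma, double tau, int m, int burn, double scale) {
  const uword nsub = subj_start.n_elem, r = Z.n_cols;
  cube draws(r, m, nsub);
  vec accept(nsub, fill::zeros);
  mat blast(nsub, r);
  mat Linv = inv(trimatl(Lpsi));

  Rcpp::RNGScope rngscope;
  for (uword i = 0; i < nsub; ++i) {
    const uword st = subj_start(i), len = subj_len(i);
    vec o = (len > 0) ? resid_fixed.subvec(st, st + len - 1) : vec();
    mat Zi = (len > 0) ? Z.rows(st, st + len - 1) : mat(0, r);
    vec b = bstart.row(i).t();
    double lp = target_logpost(o, Zi, b, Linv, sigma, tau);
    int nacc = 0, total = burn + m;
    for (int k = 0; k < total; ++k) {
      vec eta(r);
      for (uword j = 0; j < r; ++j) eta(j) = norm_rand();
      vec bp = b + scale * (Lpsi * eta);
      double lpp = target_logpost(o, Zi, bp, Linv, sigma, tau);
      if (log(unif_rand()) < lpp - lp) {
        b = bp;
        lp = lpp;
        ++nacc;
      }
      if (k >= burn) draws.slice(i).col(k - burn) = b;
    }
    accept(i) = static_cast<double>(nacc) / total;
    blast.row(i) = b.t();
  }

  return Rcpp::List::create(Rcpp::Named("draws") = draws,
                            Rcpp::Named("accept") = accept,
                            Rcpp::Named("last") = blast);
}
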