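// Coordinate-ascent E-step sweeps for the four-group (two-trait) and
// two-group (single-trait) spike-and-slab variational approximations.
//
// Group order is fixed everywhere as (00, 01, 10, 11): trait 1 is non-null
// in columns {10, 11} (0-based 2, 3), trait 2 in {01, 11} (0-based 1, 3).
//
// The sweep maintains running residuals r_k = y_k - X_k %*% (pi_k * mu_k),
// where pi_k is the posterior inclusion probability, so one full sweep is
// O(n p). The caller owns the outer VBEM loop, M-step and ELBO.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat no_copy(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

struct SlabUpdate {
  double mu, s2, u;
};

// Per-SNP slab update for one trait: s2 = se/(xtx + se/sb),
// mu = x'r_excl / (xtx + se/sb), u = log evidence gain for gamma = 1 vs 0.
static inline SlabUpdate slab_update(double xtx, double xr, double se,
                                     double sb) {
  SlabUpdate out;
  if (xtx <= 0.0) {  // constant column: prior recovered, no evidence
    out.s2 = sb;
    out.mu = 0.0;
    out.u = 0.0;
    return out;
  }
  const double denom = xtx + se / sb;
  out.s2 = se / denom;
  out.mu = xr / denom;
  out.u = 0.5 * std::log(out.s2 / sb) + out.mu * out.mu / (2.0 * out.s2);
  return out;
}

// One full coordinate sweep of the joint (four-group) E-step.
// Arguments mu (p x 2), s2 (p x 2), gpost (p x 4), r1, r2 hold the current
// state and are returned updated; X1, X2 are centered genotype matrices.
// [[Rcpp::export(name = ".sweepJoint")]]
List sweep_joint(NumericMatrix X1in, NumericMatrix X2in, NumericVector xtx1,
                 NumericVector xtx2, NumericVector r1in, NumericVector r2in,
                 NumericMatrix muin, NumericMatrix s2in, NumericMatrix gin,
                 NumericVector logAlpha, NumericVector sigma2e,
                 NumericVector sigma2b) {
  const arma::mat X1 = no_copy(X1in), X2 = no_copy(X2in);
  const int p = X1.n_cols;
  arma::vec r1 = as<arma::vec>(r1in), r2 = as<arma::vec>(r2in);
  arma::mat mu = as<arma::mat>(muin), s2 = as<arma::mat>(s2in);
  arma::mat g = as<arma::mat>(gin);
  const double la0 = logAlpha[0], la1 = logAlpha[1], la2 = logAlpha[2],
               la3 = logAlpha[3];
  const double se1 = sigma2e[0], se2 = sigma2e[1];
  const double sb1 = sigma2b[0], sb2 = sigma2b[1];

  for (int j = 0; j < p; ++j) {
    const double pi1o = g(j, 2) + g(j, 3);
    const double pi2o = g(j, 1) + g(j, 3);
    const double xr1 =
        arma::dot(X1.col(j), r1) + pi1o * mu(j, 0) * xtx1[j];
    const double xr2 =
        arma::dot(X2.col(j), r2) + pi2o * mu(j, 1) * xtx2[j];
    const SlabUpdate a = slab_update(xtx1[j], xr1, se1, sb1);
    const SlabUpdate b = slab_update(xtx2[j], xr2, se2, sb2);
    if (!std::isfinite(a.u) || !std::isfinite(b.u))
      stop("non-finite evidence term at SNP %d", j + 1);

    double l0 = la0, l1 = la1 + b.u, l2 = la2 + a.u, l3 = la3 + a.u + b.u;
    const double mx = std::max(std::max(l0, l1), std::max(l2, l3));
    l0 = std::exp(l0 - mx);
    l1 = std::exp(l1 - mx);
    l2 = std::exp(l2 - mx);
    l3 = std::exp(l3 - mx);
    const double tot = l0 + l1 + l2 + l3;
    g(j, 0) = l0 / tot;
    g(j, 1) = l1 / tot;
    g(j, 2) = l2 / tot;
    g(j, 3) = l3 / tot;

    const double pi1n = g(j, 2) + g(j, 3);
    const double pi2n = g(j, 1) + g(j, 3);
    const double d1 = pi1n * a.mu - pi1o * mu(j, 0);
    const double d2 = pi2n * b.mu - pi2o * mu(j, 1);
    if (d1 != 0.0) r1 -= d1 * X1.col(j);
    if (d2 != 0.0) r2 -= d2 * X2.col(j);
    mu(j, 0) = a.mu;
    mu(j, 1) = b.mu;
    s2(j, 0) = a.s2;
    s2(j, 1) = b.s2;
  }
  return List::create(_["mu"] = mu, _["s2"] = s2, _["gpost"] = g,
                      _["r1"] = r1, _["r2"] = r2);
}

// One full coordinate sweep of the single-trait (two-group) E-step.
// gpost is p x 2 with columns (null, non-null); logAlpha length 2.
// [[Rcpp::export(name = ".sweepSingle")]]
List sweep_single(NumericMatrix Xin, NumericVector xtx, NumericVector rin,
                  NumericMatrix muin, NumericMatrix s2in, NumericMatrix gin,
                  NumericVector logAlpha, double sigma2e, double sigma2b) {
  const arma::mat X = no_copy(Xin);
  const int p = X.n_cols;
  arma::vec r = as<arma::vec>(rin);
  arma::mat mu = as<arma::mat>(muin), s2 = as<arma::mat>(s2in);
  arma::mat g = as<arma::mat>(gin);
  const double la0 = logAlpha[0], la1 = logAlpha[1];

  for (int j = 0; j < p; ++j) {
    const double pio = g(j, 1);
    const double xr = arma::dot(X.col(j), r) + pio * mu(j, 0) * xtx[j];
    const SlabUpdate a = slab_update(xtx[j], xr, sigma2e, sigma2b);
    if (!std::isfinite(a.u))
      stop("non-finite evidence term at SNP %d", j + 1);
    double l0 = la0, l1 = la1 + a.u;
    const double mx = std::max(l0, l1);
    l0 = std::exp(l0 - mx);
    l1 = std::exp(l1 - mx);
    const double pin = l1 / (l0 + l1);
    g(j, 0) = 1.0 - pin;
    g(j, 1) = pin;
    const double d = pin * a.mu - pio * mu(j, 0);
    if (d != 0.0) r -= d * X.col(j);
    mu(j, 0) = a.mu;
    s2(j, 0) = a.s2;
  }
  return List::create(_["mu"] = mu, _["s2"] = s2, _["gpost"] = g,
                      _["r"] = r);
}
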