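// Gibbs sampler for the Gaussian animal model
//   y = X beta + Z a + Z s + e
//   a ~ N(0, sigma2_a * A),  s ~ N(0, sigma2_s * I),  e ~ N(0, sigma2_e * I)
// with an improper flat prior on beta and inverse-gamma(shape, scale)
// priors on each variance component.  Z maps records to species (one
// effect per species for both the phylogenetic and the repeat-measure
// term).  All randomness comes from R's RNG so set.seed() in R makes the
// draw stream bit-reproducible.

#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvgamma(double shape, double scale) {
  // X ~ IG(shape, scale)  <=>  1/X ~ Gamma(shape, rate = scale)
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// [[Rcpp::export(name = ".pmm_gibbs_cpp")]]
arma::mat pmm_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::ivec& sp, const arma::mat& Ainv,
                        bool use_animal, bool use_species, int q,
                        double sh_a, double sc_a,
                        double sh_s, double sc_s,
                        double sh_e, double sc_e,
                        int niter, int burnin, int thin) {
  const int n = y.n_elem;
  const int p = X.n_cols;

  arma::mat XtX = X.t() * X;
  arma::mat RX = arma::chol(XtX);        // upper triangular

  arma::vec counts(q, arma::fill::zeros);
  for (int i = 0; i < n; ++i) counts(sp(i)) += 1.0;

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::vec a(q, arma::fill::zeros);
  arma::vec s(q, arma::fill::zeros);
  double vy = arma::var(y);
  if (vy <= 0) vy = 1.0;
  double sig_a = use_animal ? vy / 3.0 : 0.0;
  double sig_s = use_species ? vy / 3.0 : 0.0;
  double sig_e = vy / 3.0;

  int nkeep = (niter - burnin) / thin;
  arma::mat out(nkeep, p + 3);
  int kept = 0;

  arma::vec Zs_eff(n, arma::fill::zeros);   // (Za a + Zs s) at record level

  for (int it = 1; it <= niter; ++it) {
    // record-level random effect sums
    for (int i = 0; i < n; ++i) Zs_eff(i) = a(sp(i)) + s(sp(i));

    // beta | rest
    arma::vec r = y - Zs_eff;
    arma::vec bhat = arma::solve(XtX, X.t() * r, arma::solve_opts::likely_sympd);
    beta = bhat + std::sqrt(sig_e) * arma::solve(arma::trimatu(RX), rnorm_vec(p));

    arma::vec xb = X * beta;

    if (use_animal) {
      // a | rest: precision = diag(counts)/sig_e + Ainv/sig_a
      arma::vec r2 = y - xb;
      for (int i = 0; i < n; ++i) r2(i) -= s(sp(i));
      arma::vec zt(q, arma::fill::zeros);
      for (int i = 0; i < n; ++i) zt(sp(i)) += r2(i);
      arma::mat P = Ainv / sig_a;
      P.diag() += counts / sig_e;
      arma::mat L = arma::chol(P, "lower");
      arma::vec mu = arma::solve(arma::trimatl(L), zt / sig_e);
      mu = arma::solve(arma::trimatu(L.t()), mu);
      a = mu + arma::solve(arma::trimatu(L.t()), rnorm_vec(q));
      sig_a = rinvgamma(sh_a + 0.5 * q,
                        sc_a + 0.5 * arma::as_scalar(a.t() * Ainv * a));
    }

    if (use_species) {
      arma::vec r3 = y - xb;
      for (int i = 0; i < n; ++i) r3(i) -= a(sp(i));
      arma::vec zt(q, arma::fill::zeros);
      for (int i = 0; i < n; ++i) zt(sp(i)) += r3(i);
      for (int j = 0; j < q; ++j) {
        double prec = counts(j) / sig_e + 1.0 / sig_s;
        double mu = (zt(j) / sig_e) / prec;
        s(j) = mu + R::norm_rand() / std::sqrt(prec);
      }
      sig_s = rinvgamma(sh_s + 0.5 * q, sc_s + 0.5 * arma::dot(s, s));
    }

    // residual
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = y(i) - xb(i) - a(sp(i)) - s(sp(i));
      rss += e * e;
    }
    sig_e = rinvgamma(sh_e + 0.5 * n, sc_e + 0.5 * rss);

    if (it > burnin && (it - burnin) % thin == 0 && kept < nkeep) {
      for (int j = 0; j < p; ++j) out(kept, j) = beta(j);
      out(kept, p) = sig_a;
      out(kept, p + 1) = sig_s;
      out(kept, p + 2) = sig_e;
      ++kept;
    }
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
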