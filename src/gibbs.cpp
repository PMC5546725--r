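// Collapsed Gibbs sampler for the Bayesian partition model.
//
// The dataset-selection indicators and the per-CEM Normal parameters are
// integrated out analytically; a fixed-K chain sweeps the membership vector
// gene by gene, sampling each label (null included) from its conditional.
// Per-(dataset, CEM) sufficient statistics (pair count, sum z, sum z^2) are
// maintained incrementally so a gene update costs O(n * D) regardless of the
// configuration. All randomness comes from R's generator (unif_rand), so
// set.seed() on the R side makes chains fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Hyper {
  double mu, kap, a, b, lpi, l1pi, vK;
};

// log NIG marginal of C z-values with sufficient statistics (C, Sz, Szz)
static inline double nig_m1(double C, double Sz, double Szz, const Hyper &h) {
  if (C == 0.0) return 0.0;
  double beta_n = h.b + 0.5 * (Szz + h.kap * h.mu * h.mu -
                               std::pow(h.kap * h.mu + Sz, 2) / (h.kap + C));
  return -C / 2.0 * std::log(2.0 * M_PI) +
         0.5 * (std::log(h.kap) - std::log(h.kap + C)) +
         h.a * std::log(h.b) - std::lgamma(h.a) + std::lgamma(h.a + C / 2.0) -
         (h.a + C / 2.0) * std::log(beta_n);
}

// background log-likelihood from sufficient statistics
static inline double bg_m0(double C, double Sz, double Szz, double t0, double s0sq) {
  if (C == 0.0) return 0.0;
  return -C / 2.0 * std::log(2.0 * M_PI * s0sq) -
         (Szz - 2.0 * t0 * Sz + C * t0 * t0) / (2.0 * s0sq);
}

// per-(dataset, CEM) collapsed factor: lse(log pi + m1, log(1-pi) + m0) - m0
static inline double cem_factor(double C, double Sz, double Szz,
                                double t0, double s0sq, const Hyper &h) {
  if (C == 0.0) return 0.0;
  double m0 = bg_m0(C, Sz, Szz, t0, s0sq);
  double x1 = h.lpi + nig_m1(C, Sz, Szz, h);
  double x0 = h.l1pi + m0;
  double mx = std::max(x1, x0);
  return mx + std::log(std::exp(x1 - mx) + std::exp(x0 - mx)) - m0;
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(const arma::cube &Z, const arma::umat &present,
                     const arma::vec &theta0, const arma::vec &s0sq,
                     int K, int M,
                     double mu_theta, double kappa_theta,
                     double alpha_sigma, double beta_sigma,
                     double pi_s, double v_k,
                     bool track_states,
                     const arma::ivec &I_init) {
  const int n = Z.n_rows;
  const int D = Z.n_slices;
  Hyper h{mu_theta, kappa_theta, alpha_sigma, beta_sigma,
          std::log(pi_s), std::log1p(-pi_s), v_k};

  // pair availability and constant background over all available pairs
  double const_bg = 0.0;
  for (int d = 0; d < D; ++d)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (present(i, d) && present(j, d) && std::isfinite(Z(i, j, d)))
          const_bg += bg_m0(1.0, Z(i, j, d), Z(i, j, d) * Z(i, j, d),
                            theta0(d), s0sq(d));

  arma::ivec I = I_init;                    // labels 0..K, 0 = null
  arma::mat Cnt(D, K, arma::fill::zeros);   // within-CEM pair counts
  arma::mat Sz(D, K, arma::fill::zeros);
  arma::mat Szz(D, K, arma::fill::zeros);
  arma::mat fval(D, K, arma::fill::zeros);  // cached cem_factor per (d, k)
  arma::ivec nk(K + 1, arma::fill::zeros);  // genes per label (incl. null)
  for (int i = 0; i < n; ++i) nk(I(i)) += 1;
  int occ = 0;                              // labels with >= 2 genes
  for (int k = 1; k <= K; ++k) if (nk(k) >= 2) occ += 1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int k = I(i);
      if (k <= 0 || I(j) != k) continue;
      for (int d = 0; d < D; ++d)
        if (present(i, d) && present(j, d) && std::isfinite(Z(i, j, d))) {
          Cnt(d, k - 1) += 1.0;
          Sz(d, k - 1) += Z(i, j, d);
          Szz(d, k - 1) += Z(i, j, d) * Z(i, j, d);
        }
    }
  double V = 0.0;                           // sum of fval
  for (int k = 0; k < K; ++k)
    for (int d = 0; d < D; ++d) {
      fval(d, k) = cem_factor(Cnt(d, k), Sz(d, k), Szz(d, k),
                              theta0(d), s0sq(d), h);
      V += fval(d, k);
    }

  arma::ivec best_I = I;
  double best_lp = const_bg + V - h.vK * occ;
  double cur_lp = best_lp;

  IntegerMatrix states(track_states ? M : 0, track_states ? n : 0);
  NumericVector lp_sweep(M);

  // scratch per gene update
  arma::mat s1(D, K), s2(D, K), cadd(D, K), fcand(D, K);
  std::vector<double> logw(K + 1), w(K + 1);

  for (int sweep = 0; sweep < M; ++sweep) {
    for (int i = 0; i < n; ++i) {
      // pair statistics between gene i and current members of each CEM
      s1.zeros(); s2.zeros(); cadd.zeros();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        int k = I(j);
        if (k <= 0) continue;
        for (int d = 0; d < D; ++d) {
          if (present(i, d) && present(j, d)) {
            double z = Z(i, j, d);
            if (!std::isfinite(z)) continue;
            s1(d, k - 1) += z;
            s2(d, k - 1) += z * z;
            cadd(d, k - 1) += 1.0;
          }
        }
      }
      // remove gene i from its current CEM
      int kold = I(i);
      if (kold > 0) {
        int c = kold - 1;
        for (int d = 0; d < D; ++d) {
          Cnt(d, c) -= cadd(d, c);
          Sz(d, c) -= s1(d, c);
          Szz(d, c) -= s2(d, c);
          double f = cem_factor(Cnt(d, c), Sz(d, c), Szz(d, c),
                                theta0(d), s0sq(d), h);
          V += f - fval(d, c);
          fval(d, c) = f;
        }
        nk(kold) -= 1;
        if (nk(kold) == 1) occ -= 1;
        nk(0) += 1;
        I(i) = 0;
      }
      // conditional log-weights over labels 0..K
      logw[0] = -h.vK * occ;
      for (int k = 1; k <= K; ++k) {
        int c = k - 1;
        double delta = 0.0;
        for (int d = 0; d < D; ++d) {
          double f = cem_factor(Cnt(d, c) + cadd(d, c), Sz(d, c) + s1(d, c),
                                Szz(d, c) + s2(d, c), theta0(d), s0sq(d), h);
          fcand(d, c) = f;
          delta += f - fval(d, c);
        }
        int occ_k = occ + (nk(k) == 1 ? 1 : 0);
        logw[k] = delta - h.vK * occ_k;
      }
      double mx = logw[0];
      for (int k = 1; k <= K; ++k) mx = std::max(mx, logw[k]);
      double tot = 0.0;
      for (int k = 0; k <= K; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
      double u = unif_rand() * tot;
      int knew = 0;
      double acc = 0.0;
      for (int k = 0; k <= K; ++k) {
        acc += w[k];
        if (u <= acc) { knew = k; break; }
      }
      // place gene i
      if (knew > 0) {
        int c = knew - 1;
        for (int d = 0; d < D; ++d) {
          Cnt(d, c) += cadd(d, c);
          Sz(d, c) += s1(d, c);
          Szz(d, c) += s2(d, c);
          V += fcand(d, c) - fval(d, c);
          fval(d, c) = fcand(d, c);
        }
        nk(0) -= 1;
        nk(knew) += 1;
        if (nk(knew) == 2) occ += 1;
        I(i) = knew;
      }
      cur_lp = const_bg + V - h.vK * occ;
      if (cur_lp > best_lp) {
        best_lp = cur_lp;
        best_I = I;
      }
    }
    // refresh the running sum once per sweep to stop floating-point drift
    V = arma::accu(fval);
    cur_lp = const_bg + V - h.vK * occ;
    lp_sweep[sweep] = cur_lp;
    if (track_states)
      for (int i = 0; i < n; ++i) states(sweep, i) = I(i);
  }

  return List::create(_["I_best"] = IntegerVector(best_I.begin(), best_I.end()),
                      _["logpost_best"] = best_lp,
                      _["lp_sweep"] = lp_sweep,
                      _["states"] = states);
}
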