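#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Newton/IRLS fit of logit P(y=1) = b0 + b1*sin(phi) + b2*cos(phi).
// Returns sqrt(b1^2 + b2^2), the phase-effect magnitude, with coefficients
// capped so that (quasi-)separation cannot blow the statistic up.
static double fit_magnitude(const double* s, const double* c,
                            const int* y, int n) {
  double b0 = 0.0, b1 = 0.0, b2 = 0.0;
  const double cap = 15.0;
  for (int it = 0; it < 25; it++) {
    // score and 3x3 information matrix
    double g0 = 0, g1 = 0, g2 = 0;
    double h00 = 0, h01 = 0, h02 = 0, h11 = 0, h12 = 0, h22 = 0;
    for (int i = 0; i < n; i++) {
      double eta = b0 + b1 * s[i] + b2 * c[i];
      if (eta > 30) eta = 30; else if (eta < -30) eta = -30;
      const double p = 1.0 / (1.0 + std::exp(-eta));
      const double r = y[i] - p;
      double wv = p * (1.0 - p);
      if (wv < 1e-10) wv = 1e-10;
      g0 += r; g1 += r * s[i]; g2 += r * c[i];
      h00 += wv; h01 += wv * s[i]; h02 += wv * c[i];
      h11 += wv * s[i] * s[i]; h12 += wv * s[i] * c[i];
      h22 += wv * c[i] * c[i];
    }
    // solve H d = g (symmetric 3x3, adjugate)
    const double A = h11 * h22 - h12 * h12;
    const double B = h02 * h12 - h01 * h22;
    const double C = h01 * h12 - h02 * h11;
    double det = h00 * A + h01 * B + h02 * C;
    if (std::fabs(det) < 1e-12) break;
    const double D = h00 * h22 - h02 * h02;
    const double E = h01 * h02 - h00 * h12;
    const double F = h00 * h11 - h01 * h01;
    const double d0 = (A * g0 + B * g1 + C * g2) / det;
    const double d1 = (B * g0 + D * g1 + E * g2) / det;
    const double d2 = (C * g0 + E * g1 + F * g2) / det;
    b0 += d0; b1 += d1; b2 += d2;
    if (b0 > cap) b0 = cap; else if (b0 < -cap) b0 = -cap;
    if (b1 > cap) b1 = cap; else if (b1 < -cap) b1 = -cap;
    if (b2 > cap) b2 = cap; else if (b2 < -cap) b2 = -cap;
    if (std::fabs(d0) + std::fabs(d1) + std::fabs(d2) < 1e-8) break;
  }
  return std::sqrt(b1 * b1 + b2 * b2);
}

// Phase-effect magnitude maps for one participant.
//
// phases: n_trials x n_points matrix (each column one time-frequency grid
// point), y: binary responses. For each grid point the observed magnitude is
// computed, together with the mean magnitude over n_perm within-participant
// permutations of the responses (the same permuted response vector is used
// for the whole grid in a given permutation, preserving the spatial
// correlation of the map). Permutations use R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_logit_maps(NumericMatrix phases, IntegerVector y, int n_perm) {
  const int n = phases.nrow(), m = phases.ncol();
  std::vector<double> sn(static_cast<size_t>(n) * m), cs(static_cast<size_t>(n) * m);
  for (int j = 0; j < m; j++)
    for (int i = 0; i < n; i++) {
      sn[static_cast<size_t>(j) * n + i] = std::sin(phases(i, j));
      cs[static_cast<size_t>(j) * n + i] = std::cos(phases(i, j));
    }

  std::vector<int> yy(n);
  for (int i = 0; i < n; i++) yy[i] = y[i];

  NumericVector obs(m), null_mean(m);
  for (int j = 0; j < m; j++)
    obs[j] = fit_magnitude(&sn[static_cast<size_t>(j) * n],
                           &cs[static_cast<size_t>(j) * n], yy.data(), n);

  if (n_perm > 0) {
    RNGScope scope;
    std::vector<int> yp(yy);
    std::vector<double> acc(m, 0.0);
    for (int b = 0; b < n_perm; b++) {
      // Fisher-Yates with R's RNG
      for (int i = n - 1; i > 0; i--) {
        int k = static_cast<int>(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(yp[i], yp[k]);
      }
      for (int j = 0; j < m; j++)
        acc[j] += fit_magnitude(&sn[static_cast<size_t>(j) * n],
                                &cs[static_cast<size_t>(j) * n], yp.data(), n);
    }
    for (int j = 0; j < m; j++) null_mean[j] = acc[j] / n_perm;
  }

  return List::create(_["observed"] = obs, _["null_mean"] = null_mean);
}
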