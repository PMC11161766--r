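#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Permutation null for the fixed-frequency sinusoid fit.
//
// p_mat: participants x conditions matrix of demeaned response proportions.
// m_proj: conditions x conditions projection matrix onto the sin/cos
//   regressors at the test frequency (X (X'X)^-1 X').
// Each permutation shuffles the condition (SOA) labels independently within
// every participant, recomputes the group curve, and returns its r^2
// (explained variance of the projection). Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_perm_r2(NumericMatrix p_mat, NumericMatrix m_proj,
                          int n_perm) {
  const int np = p_mat.nrow(), ns = p_mat.ncol();
  RNGScope scope;
  NumericVector out(n_perm);
  std::vector<int> idx(ns);
  std::vector<double> y(ns), fit(ns);

  for (int b = 0; b < n_perm; b++) {
    std::fill(y.begin(), y.end(), 0.0);
    for (int i = 0; i < np; i++) {
      for (int j = 0; j < ns; j++) idx[j] = j;
      for (int j = ns - 1; j > 0; j--) {
        int k = static_cast<int>(unif_rand() * (j + 1));
        if (k > j) k = j;
        std::swap(idx[j], idx[k]);
      }
      for (int j = 0; j < ns; j++) y[j] += p_mat(i, idx[j]);
    }
    double sstot = 0.0, ssfit = 0.0;
    for (int j = 0; j < ns; j++) y[j] /= np;
    for (int j = 0; j < ns; j++) {
      double f = 0.0;
      for (int k = 0; k < ns; k++) f += m_proj(j, k) * y[k];
      fit[j] = f;
      sstot += y[j] * y[j];
      ssfit += f * y[j];
    }
    out[b] = (sstot > 0) ? ssfit / sstot : 0.0;
  }
  return out;
}

// Connected-component labels of suprathreshold points on an nf x nt grid
// (column-major over frequency within time; 4-neighborhood adjacency).
// Returns 0 for subthreshold points, 1..K for cluster membership.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(NumericVector stat, int nf, int nt,
                                 double threshold) {
  const int m = nf * nt;
  IntegerVector lab(m, 0);
  std::vector<int> stack;
  int next = 0;
  for (int p = 0; p < m; p++) {
    if (stat[p] < threshold || lab[p] != 0) continue;
    next++;
    stack.clear();
    stack.push_back(p);
    lab[p] = next;
    while (!stack.empty()) {
      const int q = stack.back(); stack.pop_back();
      const int fi = q % nf, ti = q / nf;
      const int nb[4] = {
        (fi > 0) ? q - 1 : -1,
        (fi < nf - 1) ? q + 1 : -1,
        (ti > 0) ? q - nf : -1,
        (ti < nt - 1) ? q + nf : -1 };
      for (int k = 0; k < 4; k++) {
        const int r = nb[k];
        if (r >= 0 && lab[r] == 0 && stat[r] >= threshold) {
          lab[r] = next;
          stack.push_back(r);
        }
      }
    }
  }
  return lab;
}

// Max-cluster statistic for each permutation of a one-sample cluster test.
//
// mean_mat: n_perm x m matrix of per-permutation (sign-flipped) group means;
// sumsq: per-point sum of squares across participants (invariant under sign
// flips); n: number of participants. For each permutation the one-sample
// t-map is formed and the maximum 4-neighborhood cluster sum of t above
// threshold is recorded (0 when no point is suprathreshold).
// [[Rcpp::export]]
NumericVector cpp_max_cluster_sums(NumericMatrix mean_mat, NumericVector sumsq,
                                   int n, double t_threshold,
                                   int nf, int nt) {
  const int n_perm = mean_mat.nrow(), m = mean_mat.ncol();
  NumericVector out(n_perm);
  NumericVector tval(m);
  std::vector<int> stack;
  std::vector<char> seen(m);

  for (int b = 0; b < n_perm; b++) {
    for (int j = 0; j < m; j++) {
      const double mu = mean_mat(b, j);
      double var = (sumsq[j] - n * mu * mu) / (n - 1);
      if (var < 1e-30) var = 1e-30;
      tval[j] = mu / std::sqrt(var / n);
    }
    std::fill(seen.begin(), seen.end(), 0);
    double best = 0.0;
    for (int p = 0; p < m; p++) {
      if (tval[p] < t_threshold || seen[p]) continue;
      double sum = 0.0;
      stack.clear();
      stack.push_back(p);
      seen[p] = 1;
      while (!stack.empty()) {
        const int q = stack.back(); stack.pop_back();
        sum += tval[q];
        const int fi = q % nf, ti = q / nf;
        const int nb[4] = {
          (fi > 0) ? q - 1 : -1,
          (fi < nf - 1) ? q + 1 : -1,
          (ti > 0) ? q - nf : -1,
          (ti < nt - 1) ? q + nf : -1 };
        for (int k = 0; k < 4; k++) {
          const int r = nb[k];
          if (r >= 0 && !seen[r] && tval[r] >= t_threshold) {
            seen[r] = 1;
            stack.push_back(r);
          }
        }
      }
      if (sum > best) best = sum;
    }
    out[b] = best;
  }
  return out;
}
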