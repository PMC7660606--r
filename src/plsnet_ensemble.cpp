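#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ensemble PLS scoring of regulator -> target strengths.
//
// Xs: n x p matrix of standardised expression (samples x genes).
// For each target gene, T times, k candidate regulators are drawn without
// replacement from the remaining p - 1 genes (R RNG, so set.seed() on the
// R side controls reproducibility) and scored by an m-component NIPALS PLS
// of the target on the candidates. Importance of candidate c is
// sum_h (explained response variance of component h) * w_{ch}^2 with w the
// normalised weight vector. The returned p x p matrix holds the per-target
// accumulated scores divided by T, entry (j, i) = strength j regulates i.
//
// Break thresholds (1e-12 on the weight norm and score-vector norm) match
// the reference R implementation in pls_importance() exactly.
// [[Rcpp::export]]
NumericMatrix plsnet_ensemble_cpp(NumericMatrix Xs, int m, int k, int T) {
  const int n = Xs.nrow(), p = Xs.ncol();
  NumericMatrix W(p, p);
  std::vector<double> Xw(static_cast<size_t>(n) * k), yv(n), w(k), t(n), sc(k);
  IntegerVector others(p - 1);

  for (int target = 0; target < p; ++target) {
    int idx = 0;
    for (int j = 0; j < p; ++j)
      if (j != target) others[idx++] = j;

    for (int iter = 0; iter < T; ++iter) {
      IntegerVector pick = sample(others, k, false);
      for (int c = 0; c < k; ++c) {
        const int g = pick[c];
        for (int r = 0; r < n; ++r) Xw[c * n + r] = Xs(r, g);
      }
      for (int r = 0; r < n; ++r) yv[r] = Xs(r, target);
      std::fill(sc.begin(), sc.end(), 0.0);

      for (int h = 0; h < m; ++h) {
        double nw2 = 0.0;
        for (int c = 0; c < k; ++c) {
          double s = 0.0;
          const double* xc = &Xw[c * n];
          for (int r = 0; r < n; ++r) s += xc[r] * yv[r];
          w[c] = s;
          nw2 += s * s;
        }
        const double nw = std::sqrt(nw2);
        if (nw < 1e-12) break;
        for (int c = 0; c < k; ++c) w[c] /= nw;

        double tt = 0.0, ty = 0.0;
        for (int r = 0; r < n; ++r) {
          double s = 0.0;
          for (int c = 0; c < k; ++c) s += Xw[c * n + r] * w[c];
          t[r] = s;
          tt += s * s;
          ty += s * yv[r];
        }
        if (tt < 1e-12) break;
        const double qh = ty / tt;
        const double vexp = qh * qh * tt;
        for (int c = 0; c < k; ++c) sc[c] += vexp * w[c] * w[c];

        for (int c = 0; c < k; ++c) {
          double s = 0.0;
          double* xc = &Xw[c * n];
          for (int r = 0; r < n; ++r) s += xc[r] * t[r];
          const double ph = s / tt;
          for (int r = 0; r < n; ++r) xc[r] -= t[r] * ph;
        }
        for (int r = 0; r < n; ++r) yv[r] -= qh * t[r];
      }

      for (int c = 0; c < k; ++c) W(pick[c], target) += sc[c];
    }
  }

  const double invT = 1.0 / T;
  for (int j = 0; j < p * p; ++j) W[j] *= invT;
  return W;
}
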