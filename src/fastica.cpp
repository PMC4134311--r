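#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One deflation-FastICA component: fixed-point iteration
//   w <- E[z g(w'z)] - E[g'(w'z)] w,  g = tanh,
// with Gram-Schmidt orthogonalisation against previously extracted
// directions and renormalisation at every step.  The expectation pass is
// fused: each iteration streams the whitened matrix Z (k x V,
// column-major) exactly once.
// [[Rcpp::export(name = ".fastica_one_cpp")]]
List fastica_one_cpp(NumericMatrix Z, NumericMatrix W_prev,
                     NumericVector w0, double tol, int max_iter) {
  int k = Z.nrow();
  long V = Z.ncol();
  int p = W_prev.ncol();
  const double *z = REAL(Z);
  const double *Wp = REAL(W_prev);
  std::vector<double> w(w0.begin(), w0.end()), wn(k), proj(p);

  auto orth_norm = [&](std::vector<double> &v) {
    for (int j = 0; j < p; ++j) {
      double d = 0;
      for (int i = 0; i < k; ++i) d += Wp[i + (long)k * j] * v[i];
      proj[j] = d;
    }
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < k; ++i) v[i] -= proj[j] * Wp[i + (long)k * j];
    double nrm = 0;
    for (int i = 0; i < k; ++i) nrm += v[i] * v[i];
    nrm = std::sqrt(nrm);
    if (nrm < 1e-12) return false;
    for (int i = 0; i < k; ++i) v[i] /= nrm;
    return true;
  };

  if (!orth_norm(w)) return List::create(_["w"] = w0, _["iters"] = 0,
                                         _["converged"] = false);
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    std::fill(wn.begin(), wn.end(), 0.0);
    double sum_gp = 0.0;
    for (long v = 0; v < V; ++v) {
      const double *col = z + (long)k * v;
      double s = 0;
      for (int i = 0; i < k; ++i) s += w[i] * col[i];
      double g = std::tanh(s);
      sum_gp += 1.0 - g * g;
      for (int i = 0; i < k; ++i) wn[i] += g * col[i];
    }
    double mgp = sum_gp / (double)V;
    for (int i = 0; i < k; ++i) wn[i] = wn[i] / (double)V - mgp * w[i];
    if (!orth_norm(wn)) break;
    double dot = 0;
    for (int i = 0; i < k; ++i) dot += wn[i] * w[i];
    w = wn;
    if (std::fabs(dot) > 1.0 - tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iters"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
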