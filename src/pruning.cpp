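// Felsenstein pruning for GTR+gamma+I on site patterns, with per-node
// scaling. Transition matrices are built inside the kernel from the
// eigendecomposition of the (reversible) rate matrix, so a likelihood
// evaluation is a single call from R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector pruning_site_loglik(IntegerMatrix edge,    // postorder, cols: parent, child (1-based)
                                  NumericVector el,      // edge lengths
                                  NumericMatrix U,       // 4x4
                                  NumericMatrix Uinv,    // 4x4
                                  NumericVector lambda,  // 4 eigenvalues
                                  NumericVector rates,   // mixture rates
                                  NumericVector weights, // mixture weights
                                  NumericVector pi,      // root frequencies
                                  NumericMatrix tipPart, // 4 x (ntip*npat)
                                  int ntip, int nnode, int npat) {
  const int nedge = edge.nrow();
  const int ncat = rates.size();
  const int root = edge(nedge - 1, 0) - 1;

  std::vector<double> part((size_t)4 * npat * nnode);
  std::vector<double> scal((size_t)npat * nnode, 0.0);
  std::vector<char> seen(nnode);
  NumericMatrix catll(npat, ncat); // per-category log-likelihoods

  double P[16];

  // tip partials and tip scalers never change across categories; internal
  // nodes are (re)assigned on first touch each category, so only the
  // 'seen' flags need resetting per category
  for (int t = 0; t < ntip; ++t) {
    double *dst = &part[(size_t)4 * npat * t];
    for (int s = 0; s < npat; ++s)
      for (int i = 0; i < 4; ++i)
        dst[4 * s + i] = tipPart(i, (size_t)t * npat + s);
  }

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1;
      const int ch  = edge(e, 1) - 1;
      const double t = el[e] * rates[c];
      // P(t) = U diag(exp(lambda t)) Uinv
      double ex[4];
      for (int i = 0; i < 4; ++i) ex[i] = std::exp(lambda[i] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double v = 0.0;
          for (int k = 0; k < 4; ++k) v += U(i, k) * ex[k] * Uinv(k, j);
          P[4 * i + j] = v > 0.0 ? v : 0.0;
        }
      double *cp = &part[(size_t)4 * npat * ch];
      double *pp = &part[(size_t)4 * npat * par];
      double *cs = &scal[(size_t)npat * ch];
      double *ps = &scal[(size_t)npat * par];
      if (!seen[par]) {
        for (int s = 0; s < npat; ++s) {
          const double *x = cp + 4 * s;
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            double v = P[4 * i] * x[0] + P[4 * i + 1] * x[1] +
                       P[4 * i + 2] * x[2] + P[4 * i + 3] * x[3];
            pp[4 * s + i] = v;
            if (v > mx) mx = v;
          }
          if (mx > 0.0 && mx < 1e-80) { // rescale to avoid underflow
            for (int i = 0; i < 4; ++i) pp[4 * s + i] /= mx;
            ps[s] = cs[s] + std::log(mx);
          } else {
            ps[s] = cs[s];
          }
        }
        seen[par] = 1;
      } else {
        for (int s = 0; s < npat; ++s) {
          const double *x = cp + 4 * s;
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            double v = P[4 * i] * x[0] + P[4 * i + 1] * x[1] +
                       P[4 * i + 2] * x[2] + P[4 * i + 3] * x[3];
            double w = pp[4 * s + i] * v;
            pp[4 * s + i] = w;
            if (w > mx) mx = w;
          }
          ps[s] += cs[s];
          if (mx > 0.0 && mx < 1e-80) {
            for (int i = 0; i < 4; ++i) pp[4 * s + i] /= mx;
            ps[s] += std::log(mx);
          }
        }
      }
    }
    const double *rp = &part[(size_t)4 * npat * root];
    const double *rs = &scal[(size_t)npat * root];
    for (int s = 0; s < npat; ++s) {
      double L = 0.0;
      for (int i = 0; i < 4; ++i) L += pi[i] * rp[4 * s + i];
      catll(s, c) = (L > 0.0 ? std::log(L) : R_NegInf) + rs[s];
    }
  }

  // combine categories: log sum_c w_c exp(catll)
  NumericVector out(npat);
  for (int s = 0; s < npat; ++s) {
    double mx = R_NegInf;
    for (int c = 0; c < ncat; ++c) if (catll(s, c) > mx) mx = catll(s, c);
    if (!R_finite(mx)) { out[s] = R_NegInf; continue; }
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c) acc += weights[c] * std::exp(catll(s, c) - mx);
    out[s] = mx + std::log(acc);
  }
  return out;
}
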