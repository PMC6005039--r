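#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns for one partition.
//
// tipclv: tip conditional likelihoods, laid out as npat x 4 per tip,
//         tip-major (tip 1 block first). Ambiguous states are all-ones rows.
// po:     postorder edge matrix (parent, child), 1-based ape node ids.
// bl:     branch lengths indexed by child node id (1-based).
// U, Uinv, lambda: eigendecomposition of the scaled rate matrix.
// cat_rates: discrete-gamma category rates (equal weights).
//
// Returns the log-likelihood, or -Inf if any site likelihood underflows.
// [[Rcpp::export]]
double prune_loglik_cpp(NumericVector tipclv, NumericVector weights,
                        IntegerMatrix po, NumericVector bl,
                        NumericMatrix U, NumericMatrix Uinv,
                        NumericVector lambda, NumericVector freqs,
                        NumericVector cat_rates, int ntip, int nnode) {
  const int npat = weights.size();
  if (npat == 0) return 0.0;  // empty partition: likelihood 1
  const int ncat = cat_rates.size();
  const int nedge = po.nrow();
  std::vector<double> site_lik(npat, 0.0);
  std::vector<double> clv(static_cast<size_t>(nnode) * npat * 4);
  std::vector<bool> filled(nnode);
  double P[4][4];

  for (int k = 0; k < ncat; ++k) {
    std::fill(filled.begin(), filled.end(), false);
    // tips
    for (int i = 0; i < ntip; ++i) {
      std::copy(tipclv.begin() + static_cast<size_t>(i) * npat * 4,
                tipclv.begin() + static_cast<size_t>(i + 1) * npat * 4,
                clv.begin() + static_cast<size_t>(i) * npat * 4);
      filled[i] = true;
    }
    for (int e = 0; e < nedge; ++e) {
      const int par = po(e, 0) - 1, kid = po(e, 1) - 1;
      const double t = bl[kid] * cat_rates[k];
      // P = U diag(exp(lambda t)) Uinv
      double ex[4];
      for (int j = 0; j < 4; ++j) ex[j] = std::exp(lambda[j] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int m = 0; m < 4; ++m) s += U(i, m) * ex[m] * Uinv(m, j);
          P[i][j] = s > 0.0 ? s : 0.0;
        }
      double *ck = &clv[static_cast<size_t>(kid) * npat * 4];
      double *cp = &clv[static_cast<size_t>(par) * npat * 4];
      if (!filled[par]) {
        for (int p = 0; p < npat; ++p)
          for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j) s += P[i][j] * ck[p * 4 + j];
            cp[p * 4 + i] = s;
          }
        filled[par] = true;
      } else {
        for (int p = 0; p < npat; ++p)
          for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int j = 0; j < 4; ++j) s += P[i][j] * ck[p * 4 + j];
            cp[p * 4 + i] *= s;
          }
      }
    }
    const double *cr = &clv[static_cast<size_t>(ntip) * npat * 4];  // root
    for (int p = 0; p < npat; ++p) {
      double s = 0.0;
      for (int i = 0; i < 4; ++i) s += cr[p * 4 + i] * freqs[i];
      site_lik[p] += s / ncat;
    }
  }
  double total = 0.0;
  for (int p = 0; p < npat; ++p) {
    if (site_lik[p] <= 0.0) return R_NegInf;
    total += weights[p] * std::log(site_lik[p]);
  }
  return total;
}
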