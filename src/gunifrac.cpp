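#include <Rcpp.h>
using namespace Rcpp;

// Pairwise generalized UniFrac from per-sample branch proportions.
// P: n_samples x n_branches matrix, P(i,e) = fraction of sample i's reads
// descending from branch e; lens: branch lengths; alpha: abundance
// exponent in [0,1]. Branches with p_i + p_j == 0 are skipped.
// [[Rcpp::export]]
NumericMatrix gunifrac_pairwise(NumericMatrix P, NumericVector lens,
                                double alpha) {
  int n = P.nrow(), E = P.ncol();
  if (lens.size() != E) stop("branch length vector does not match P");
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double num = 0.0, den = 0.0;
      for (int e = 0; e < E; ++e) {
        double pi = P(i, e), pj = P(j, e);
        double s = pi + pj;
        if (s <= 0.0 || lens[e] <= 0.0) continue;
        double t = lens[e] * std::pow(s, alpha);
        den += t;
        num += t * std::fabs(pi - pj) / s;
      }
      double v = den > 0.0 ? num / den : 0.0;
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
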