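#include <Rcpp.h>
using namespace Rcpp;

// Hubbell-type local community under immigration and (optional) selection.
// One event = a uniformly chosen death, replaced with probability m by an
// immigrant drawn from the source pool q, otherwise by the offspring of a
// local individual drawn proportionally to counts * w. Uses R's RNG so the
// caller controls reproducibility with set.seed().
//
// q: source proportions (sums to 1); w: per-taxon fitness multipliers;
// n_local: community size; n_events: number of death-replacement events;
// q_init: composition the community is founded from (defaults to q;
// letting it differ models early colonization, e.g. vertically acquired
// host-adapted strains).
// [[Rcpp::export]]
IntegerVector moran_community(NumericVector q, NumericVector w, double m,
                              int n_local, int n_events,
                              Nullable<NumericVector> q_init = R_NilValue) {
  int S = q.size();
  if (w.size() != S) stop("q and w lengths differ");
  IntegerVector counts(S);
  std::vector<double> qcum(S);
  double acc = 0.0;
  for (int i = 0; i < S; ++i) { acc += q[i]; qcum[i] = acc; }

  std::vector<double> icum(S);
  double iacc = 0.0;
  if (q_init.isNotNull()) {
    NumericVector qi(q_init);
    if (qi.size() != S) stop("q_init length differs from q");
    for (int i = 0; i < S; ++i) { iacc += qi[i]; icum[i] = iacc; }
  } else {
    icum = qcum; iacc = acc;
  }

  RNGScope scope;
  // founding assembly: n_local independent draws from q_init
  for (int k = 0; k < n_local; ++k) {
    double u = unif_rand() * iacc;
    int i = std::lower_bound(icum.begin(), icum.end(), u) - icum.begin();
    if (i >= S) i = S - 1;
    counts[i] += 1;
  }
  double W = 0.0;  // total reproductive weight
  for (int i = 0; i < S; ++i) W += counts[i] * w[i];

  for (int e = 0; e < n_events; ++e) {
    // death: uniform individual
    double u = unif_rand() * n_local;
    int victim = -1;
    double c = 0.0;
    for (int i = 0; i < S; ++i) {
      c += counts[i];
      if (u < c) { victim = i; break; }
    }
    if (victim < 0) victim = S - 1;
    counts[victim] -= 1;
    W -= w[victim];

    int born;
    if (unif_rand() < m) {
      double v = unif_rand() * acc;
      born = std::lower_bound(qcum.begin(), qcum.end(), v) - qcum.begin();
      if (born >= S) born = S - 1;
    } else {
      double v = unif_rand() * W;
      born = -1;
      double cw = 0.0;
      for (int i = 0; i < S; ++i) {
        if (counts[i] == 0) continue;
        cw += counts[i] * w[i];
        if (v < cw) { born = i; break; }
      }
      if (born < 0) {  // numerical slack at the upper edge
        for (int i = S - 1; i >= 0; --i) if (counts[i] > 0) { born = i; break; }
      }
    }
    counts[born] += 1;
    W += w[born];
  }
  return counts;
}
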