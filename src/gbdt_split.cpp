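#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive best-split search for one tree node under squared loss.
//
// X:        full n x p feature matrix (training rows of the current tree)
// ord:      n x p matrix of 0-based row indices sorting each column of X
//           ascending (precomputed once per tree fit)
// member:   length-n logical marker of the rows sitting in this node
// resid:    length-n residuals (negative gradients)
// feats:    0-based candidate column indices (column subsample)
// min_cnt:  minimum number of rows required in each child
//
// Gain of a split is the reduction in sum of squared errors when the
// node mean is replaced by the two child means:
//   gain = sl^2/nl + sr^2/nr - st^2/nt
// Thresholds are midpoints of consecutive distinct sorted values. Ties in
// gain are broken toward the lowest feature index, then lowest threshold
// (both guaranteed by scan order with strict improvement tests).
// [[Rcpp::export]]
List gbdt_best_split(NumericMatrix X, IntegerMatrix ord, LogicalVector member,
                     NumericVector resid, IntegerVector feats, int min_cnt) {
  const int n_total = X.nrow();
  int n_node = 0;
  double st = 0.0;
  for (int i = 0; i < n_total; ++i) {
    if (member[i]) { ++n_node; st += resid[i]; }
  }
  double best_gain = R_NegInf, best_thr = NA_REAL;
  int best_feat = NA_INTEGER;
  if (n_node < 2 * min_cnt) {
    return List::create(_["gain"] = best_gain, _["feature"] = best_feat,
                        _["threshold"] = best_thr);
  }
  std::vector<double> xs(n_node), rs(n_node);
  const double parent = st * st / n_node;
  for (int fi = 0; fi < feats.size(); ++fi) {
    const int j = feats[fi];
    int k = 0;
    for (int i = 0; i < n_total; ++i) {
      const int row = ord(i, j);
      if (member[row]) { xs[k] = X(row, j); rs[k] = resid[row]; ++k; }
    }
    double sl = 0.0;
    for (int i = 0; i < n_node - 1; ++i) {
      sl += rs[i];
      const int nl = i + 1, nr_ = n_node - nl;
      if (nl < min_cnt) continue;
      if (nr_ < min_cnt) break;
      if (xs[i + 1] <= xs[i]) continue;  // not a boundary between values
      const double sr = st - sl;
      const double gain = sl * sl / nl + sr * sr / nr_ - parent;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = (xs[i] + xs[i + 1]) / 2.0;
      }
    }
  }
  return List::create(_["gain"] = best_gain, _["feature"] = best_feat,
                      _["threshold"] = best_thr);
}
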