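#include <Rcpp.h>
using namespace Rcpp;

// Cheap all-vs-all overlap screen: score-only DP with lookback 1 (adjacent
// labels must chain) in both orientations. True overlaps chain runs of
// consecutive matched labels and clear `min_score`; random pairs rarely do.
// Survivors are re-aligned with the full kernel in R.

static double screen_score(const std::vector<double>& q,
                           const std::vector<double>& t, double match_bonus,
                           double sd02, double sdscale) {
  const int m = q.size(), n = t.size();
  std::vector<double> prev(n, 0.0), curr(n, 0.0);
  double best = 0.0;
  for (int i = 1; i < m; ++i) {
    const double dq = q[i] - q[i - 1];
    curr[0] = match_bonus;
    for (int j = 1; j < n; ++j) {
      const double dt = t[j] - t[j - 1];
      double var = sd02 + sdscale * dt;
      if (var < 1.0) var = 1.0;
      const double res = dq - dt;
      double cand = prev[j - 1] + match_bonus - res * res / (2.0 * var);
      if (cand < match_bonus) cand = match_bonus;
      curr[j] = cand;
      if (cand > best) best = cand;
    }
    std::swap(prev, curr);
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix pair_screen_cpp(List queries, double match_bonus, double sd0,
                              double sdscale, double min_score) {
  const int n = queries.size();
  std::vector<std::vector<double> > labs(n), labs_rev(n);
  for (int i = 0; i < n; ++i) {
    NumericVector v = queries[i];
    labs[i] = std::vector<double>(v.begin(), v.end());
    std::vector<double> r(labs[i].size());
    const double mx = labs[i].empty() ? 0.0 : labs[i].back();
    for (size_t k = 0; k < labs[i].size(); ++k)
      r[k] = mx - labs[i][labs[i].size() - 1 - k];
    labs_rev[i] = r;
  }
  const double sd02 = sd0 * sd0;
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i) {
    if (labs[i].size() < 2) continue;
    for (int j = i + 1; j < n; ++j) {
      if (labs[j].size() < 2) continue;
      double s = screen_score(labs[i], labs[j], match_bonus, sd02, sdscale);
      if (s < min_score)
        s = screen_score(labs_rev[i], labs[j], match_bonus, sd02, sdscale);
      if (s >= min_score) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k]; out(k, 1) = jj[k];
  }
  return out;
}
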