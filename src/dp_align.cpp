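#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming alignment of two ordered label maps (positions in bp).
//
// Local on both ends: an alignment may start and end at any label pair, so
// unaligned molecule/map ends are free.  State (i,j) = best score of an
// alignment whose last matched pair is (q[i], t[j]).  Transitions look back
// up to max_skip labels on each side; skipped labels are penalised per label
// (false_pen on the query side, miss_pen on the target side) and the interval
// length discrepancy is penalised by a Gaussian sizing term with variance
// sd0^2 + sdscale * (target interval).
//
// Tie-breaking (deterministic): higher score; then more matched pairs; then
// the smallest-lookback predecessor encountered first in the fixed scan
// order.

// [[Rcpp::export]]
List dp_align_cpp(NumericVector q, NumericVector t, double match_bonus,
                  double miss_pen, double false_pen, double sd0,
                  double sdscale, int max_skip, bool traceback = true) {
  const int m = q.size(), n = t.size();
  const double eps = 1e-9;
  if (m < 2 || n < 2) {
    return List::create(_["score"] = R_NegInf, _["qidx"] = IntegerVector(0),
                        _["tidx"] = IntegerVector(0),
                        _["residuals"] = NumericVector(0));
  }
  std::vector<double> S((size_t)m * n);
  std::vector<int> NP((size_t)m * n), PRED((size_t)m * n, -1);
  const double sd02 = sd0 * sd0;
  const double* qp = REAL(q);
  const double* tp = REAL(t);

  double gbest = R_NegInf;
  int gnp = -1, gcell = -1;

  for (int i = 0; i < m; ++i) {
    const double qi = qp[i];
    const int amax = std::min(max_skip, i);
    double* Si = &S[(size_t)i * n];
    int* NPi = &NP[(size_t)i * n];
    int* PRi = &PRED[(size_t)i * n];
    for (int j = 0; j < n; ++j) {
      double best = match_bonus;
      int bnp = 1, bpred = -1;
      const double tj = tp[j];
      const int bmax = std::min(max_skip, j);
      for (int a = 1; a <= amax; ++a) {
        const double dq = qi - qp[i - a];
        const double base = match_bonus - (a - 1) * false_pen;
        const double* Sp = &S[(size_t)(i - a) * n + j];
        const int* NPp = &NP[(size_t)(i - a) * n + j];
        for (int b = 1; b <= bmax; ++b) {
          const double dt = tj - tp[j - b];
          const double res = dq - dt;
          double var = sd02 + sdscale * dt;
          if (var < 1.0) var = 1.0;
          const double cand = Sp[-b] + base - res * res / (2.0 * var) -
                              (b - 1) * miss_pen;
          if (cand > best + eps ||
              (cand > best - eps && NPp[-b] + 1 > bnp)) {
            best = cand; bnp = NPp[-b] + 1;
            bpred = (i - a) * n + (j - b);
          }
        }
      }
      Si[j] = best; NPi[j] = bnp; PRi[j] = bpred;
      if (best > gbest + eps || (best > gbest - eps && bnp > gnp)) {
        gbest = best; gnp = bnp; gcell = i * n + j;
      }
    }
  }

  if (!traceback) {
    return List::create(_["score"] = gbest, _["npairs"] = gnp);
  }
  std::vector<int> qi_v, ti_v;
  for (int c = gcell; c >= 0; c = PRED[c]) {
    qi_v.push_back(c / n + 1);  // 1-based for R
    ti_v.push_back(c % n + 1);
  }
  std::reverse(qi_v.begin(), qi_v.end());
  std::reverse(ti_v.begin(), ti_v.end());
  const int k = qi_v.size();
  NumericVector resid(std::max(k - 1, 0));
  for (int p = 1; p < k; ++p) {
    resid[p - 1] = (qp[qi_v[p] - 1] - qp[qi_v[p - 1] - 1]) -
                   (tp[ti_v[p] - 1] - tp[ti_v[p - 1] - 1]);
  }
  return List::create(_["score"] = gbest,
                      _["qidx"] = IntegerVector(qi_v.begin(), qi_v.end()),
                      _["tidx"] = IntegerVector(ti_v.begin(), ti_v.end()),
                      _["residuals"] = resid);
}

// Lookback-2 chaining screen: per-target-cell best chain score with skips
// of at most one label per side; reports the best chain end and the best
// chain end at least `min_sep` bp away (two candidate windows for the full
// DP). Used to pick orientation and target windows before the full DP.
// [[Rcpp::export]]
List dp_screen1_cpp(NumericVector q, NumericVector t, double match_bonus,
                    double sd0, double sdscale, double min_sep = 0.0) {
  const int m = q.size(), n = t.size();
  if (m < 2 || n < 2)
    return List::create(_["score"] = R_NegInf, _["tend"] = NA_INTEGER,
                        _["score2"] = R_NegInf, _["tend2"] = NA_INTEGER);
  const double sd02 = sd0 * sd0;
  const double* qp = REAL(q);
  const double* tp = REAL(t);
  std::vector<double> S((size_t)m * n, 0.0);
  std::vector<double> colbest(n, R_NegInf);
  for (int i = 1; i < m; ++i) {
    double* Si = &S[(size_t)i * n];
    const int amax = std::min(2, i);
    Si[0] = match_bonus;
    for (int j = 1; j < n; ++j) {
      double best = match_bonus;
      const double tj = tp[j];
      const int bmax = std::min(2, j);
      for (int a = 1; a <= amax; ++a) {
        const double dq = qp[i] - qp[i - a];
        const double* Sp = &S[(size_t)(i - a) * n + j];
        for (int b = 1; b <= bmax; ++b) {
          const double dt = tj - tp[j - b];
          double var = sd02 + sdscale * dt;
          if (var < 1.0) var = 1.0;
          const double res = dq - dt;
          const double cand = Sp[-b] + match_bonus -
                              res * res / (2.0 * var) - (a - 1) - (b - 1);
          if (cand > best) best = cand;
        }
      }
      Si[j] = best;
      if (best > colbest[j]) colbest[j] = best;
    }
  }
  double b1 = R_NegInf; int e1 = 0;
  for (int j = 0; j < n; ++j)
    if (colbest[j] > b1) { b1 = colbest[j]; e1 = j; }
  double b2 = R_NegInf; int e2 = 0;
  for (int j = 0; j < n; ++j) {
    if (std::fabs(tp[j] - tp[e1]) <= min_sep) continue;
    if (colbest[j] > b2) { b2 = colbest[j]; e2 = j; }
  }
  return List::create(_["score"] = b1, _["tend"] = e1 + 1,
                      _["score2"] = b2, _["tend2"] = e2 + 1);
}

// Best score only, for a batch of queries against one target (null fitting).
// [[Rcpp::export]]
NumericVector dp_batch_scores_cpp(List queries, NumericVector t,
                                  double match_bonus, double miss_pen,
                                  double false_pen, double sd0,
                                  double sdscale, int max_skip) {
  const int nq = queries.size();
  NumericVector out(nq);
  for (int k = 0; k < nq; ++k) {
    NumericVector q = queries[k];
    List r = dp_align_cpp(q, t, match_bonus, miss_pen, false_pen, sd0,
                          sdscale, max_skip, false);
    out[k] = as<double>(r["score"]);
  }
  return out;
}
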