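#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact minimization of J(w) = w^2/2 + C * sum_i u_i * max(0, 1 - w g_i)
// over w >= 0 for one candidate boundary t (g_i = y_i (x_i - t)).
// J is convex piecewise quadratic with kinks at w = 1/g_i for g_i > 0;
// within the interval where the k largest-g points are inactive the
// stationary point is w = C * S_k, S_k the weighted g-sum of the active
// set. Checking every kink and every clamped stationary point covers the
// optimum exactly.
static void solve_w_for_t(const std::vector<double> &gs,
                          const std::vector<double> &us,
                          double C, double &w_out, double &j_out) {
  const int n = (int)gs.size();
  double tot_u = 0.0, tot_s = 0.0;
  for (int i = 0; i < n; ++i) {
    tot_u += us[i];
    tot_s += us[i] * gs[i];
  }
  int npos = 0;
  while (npos < n && gs[npos] > 0.0) ++npos;

  double best_w = 0.0, best_j = R_PosInf;
  double cum_u = 0.0, cum_s = 0.0;
  for (int k = 0; k <= npos; ++k) {
    if (k > 0) {
      cum_u += us[k - 1];
      cum_s += us[k - 1] * gs[k - 1];
    }
    const double act_u = tot_u - cum_u;
    const double act_s = tot_s - cum_s;
    const double w_lo = (k == 0) ? 0.0 : 1.0 / gs[k - 1];
    const double w_hi = (k < npos) ? 1.0 / gs[k] : R_PosInf;
    double w = C * act_s;
    if (w < w_lo) w = w_lo;
    if (w > w_hi) w = w_hi;
    if (!R_FINITE(w)) w = std::max(C * act_s, 0.0);
    if (w < 0.0) w = 0.0;
    const double j = 0.5 * w * w + C * (act_u - w * act_s);
    if (j < best_j) {
      best_j = j;
      best_w = w;
    }
  }
  w_out = best_w;
  j_out = best_j;
}

// Scan candidate boundaries, solving w exactly for each; returns the best
// (t, w, objective). Candidates come from R (data points, midpoints,
// extremes).
// [[Rcpp::export]]
List cpp_scan_fit(NumericVector x, NumericVector y, NumericVector u,
                  double C, NumericVector cand) {
  const int n = x.size(), m = cand.size();
  std::vector<std::pair<double, double> > gu(n);
  std::vector<double> gs(n), us(n);
  double best_obj = R_PosInf, best_t = NA_REAL, best_w = 0.0;

  for (int j = 0; j < m; ++j) {
    const double t = cand[j];
    for (int i = 0; i < n; ++i) {
      gu[i] = std::make_pair(y[i] * (x[i] - t), u[i]);
    }
    std::sort(gu.begin(), gu.end(),
              [](const std::pair<double, double> &a,
                 const std::pair<double, double> &b) {
                return a.first > b.first;
              });
    for (int i = 0; i < n; ++i) {
      gs[i] = gu[i].first;
      us[i] = gu[i].second;
    }
    double w, obj;
    solve_w_for_t(gs, us, C, w, obj);
    if (obj < best_obj) {
      best_obj = obj;
      best_t = t;
      best_w = w;
    }
  }
  return List::create(_["t"] = best_t, _["w"] = best_w,
                      _["objective"] = best_obj);
}
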