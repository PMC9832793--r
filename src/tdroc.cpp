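// Time-dependent ROC kernel: for each score cutoff, Kaplan-Meier survival at
// the horizon within the high- and low-marker strata, combined into
// sensitivity (cumulative cases) and specificity (dynamic controls).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// KM survival at `horizon` for the subset flagged in `grp`, given indices
// sorted by time. Ties: events and censorings at the same time share the
// risk set of everyone still under observation at that time.
static double km_at(const NumericVector& t, const IntegerVector& ev,
                    const std::vector<int>& idx, const double horizon) {
  const int n = idx.size();
  double surv = 1.0;
  int at_risk = n;
  int i = 0;
  while (i < n) {
    const double ti = t[idx[i]];
    if (ti > horizon) break;
    int d = 0, c = 0;
    int j = i;
    while (j < n && t[idx[j]] == ti) {
      if (ev[idx[j]] == 1) ++d; else ++c;
      ++j;
    }
    if (d > 0) surv *= 1.0 - (double)d / at_risk;
    at_risk -= (j - i);
    i = j;
  }
  return surv;
}

// [[Rcpp::export]]
NumericMatrix td_roc_kernel(const NumericVector& times,
                            const IntegerVector& events,
                            const NumericVector& scores,
                            const double horizon,
                            const NumericVector& cutoffs) {
  const int n = times.size(), K = cutoffs.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return times[a] < times[b];
  });
  const double s_all = km_at(times, events, ord, horizon);
  NumericMatrix out(K, 2);
  std::vector<int> hi, lo;
  hi.reserve(n); lo.reserve(n);
  for (int k = 0; k < K; ++k) {
    hi.clear(); lo.clear();
    for (int i = 0; i < n; ++i) {
      if (scores[ord[i]] > cutoffs[k]) hi.push_back(ord[i]);
      else lo.push_back(ord[i]);
    }
    const double p_hi = (double)hi.size() / n;
    double se = 0.0, sp = 0.0;
    if (!hi.empty())
      se = (1.0 - km_at(times, events, hi, horizon)) * p_hi / (1.0 - s_all);
    if (!lo.empty())
      sp = km_at(times, events, lo, horizon) * (1.0 - p_hi) / s_all;
    out(k, 0) = se;
    out(k, 1) = sp;
  }
  return out;
}
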