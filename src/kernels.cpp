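#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// ES of a hit set given sorted 0-based hit positions over a ranked list.
// w: |metric|^weight per position. Signed maximum deviation of the
// running sum (hit adds w/sum_hit_w, miss subtracts 1/(N - h)); on equal
// absolute deviation the earliest extremum wins, matching a left-to-right
// walk that updates only on strict improvement.
static double es_from_positions(const NumericVector& w,
                                const std::vector<int>& pos) {
  const int N = w.size();
  const int h = pos.size();
  const double miss_dec = 1.0 / (double)(N - h);
  double wsum = 0.0;
  for (int j = 0; j < h; ++j) wsum += w[pos[j]];
  double best = 0.0, best_abs = 0.0, cum = 0.0;
  for (int j = 0; j < h; ++j) {
    // running value just before the j-th hit
    double before = cum - (double)(pos[j] - j) * miss_dec;
    if (std::fabs(before) > best_abs) { best_abs = std::fabs(before); best = before; }
    cum += w[pos[j]] / wsum;
    double after = cum - (double)(pos[j] - j) * miss_dec;
    if (std::fabs(after) > best_abs) { best_abs = std::fabs(after); best = after; }
  }
  return best;
}

// Null ES for size-matched random member sets. For each requested set
// size, draws n_perm subsets of {1..N} without replacement and returns
// their ES values (n_perm x length(sizes)). Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_null_es(NumericVector w, IntegerVector sizes, int n_perm) {
  const int N = w.size();
  NumericMatrix out(n_perm, sizes.size());
  std::vector<int> idx(N);
  for (int s = 0; s < sizes.size(); ++s) {
    const int h = sizes[s];
    if (h <= 0 || h >= N) stop("set size must be in (0, N)");
    for (int p = 0; p < n_perm; ++p) {
      for (int i = 0; i < N; ++i) idx[i] = i;
      // partial Fisher-Yates: first h entries are the sampled positions
      for (int i = 0; i < h; ++i) {
        int j = i + (int)(unif_rand() * (N - i));
        if (j >= N) j = N - 1;
        std::swap(idx[i], idx[j]);
      }
      std::vector<int> pos(idx.begin(), idx.begin() + h);
      std::sort(pos.begin(), pos.end());
      out(p, s) = es_from_positions(w, pos);
    }
  }
  return out;
}

// Two-group log-rank chi-square statistic. Inputs must be sorted by
// time ascending; deaths precede censorings at tied times by
// construction of the at-risk bookkeeping (all patients with time >= t
// are at risk at event time t).
static double logrank_stat(const NumericVector& time,
                           const IntegerVector& event,
                           const std::vector<int>& grp) {
  const int n = time.size();
  int risk1 = 0, risk_tot = n;
  for (int i = 0; i < n; ++i) risk1 += grp[i];
  double oe = 0.0, v = 0.0;
  int i = 0;
  while (i < n) {
    int j = i;
    int d_tot = 0, d1 = 0;
    while (j < n && time[j] == time[i]) {
      if (event[j] == 1) { d_tot++; d1 += grp[j]; }
      ++j;
    }
    if (d_tot > 0 && risk_tot > 1) {
      double e1 = (double)d_tot * risk1 / risk_tot;
      oe += (double)d1 - e1;
      v += (double)d_tot * ((double)risk1 / risk_tot) *
           (1.0 - (double)risk1 / risk_tot) *
           ((double)(risk_tot - d_tot) / (double)(risk_tot - 1));
    }
    for (int k = i; k < j; ++k) { risk_tot--; risk1 -= grp[k]; }
    i = j;
  }
  if (v <= 0.0) return NA_REAL;
  return oe * oe / v;
}

// [[Rcpp::export]]
double cpp_logrank(NumericVector time, IntegerVector event,
                   IntegerVector group) {
  std::vector<int> grp(group.begin(), group.end());
  return logrank_stat(time, event, grp);
}

// Log-rank statistic for every candidate cutpoint (group = score > cut).
// time/event/score are parallel vectors sorted by time ascending.
// [[Rcpp::export]]
NumericVector cpp_cut_scan(NumericVector time, IntegerVector event,
                           NumericVector score, NumericVector cuts) {
  const int n = time.size();
  NumericVector out(cuts.size());
  std::vector<int> grp(n);
  for (int c = 0; c < cuts.size(); ++c) {
    int n1 = 0;
    for (int i = 0; i < n; ++i) {
      grp[i] = score[i] > cuts[c] ? 1 : 0;
      n1 += grp[i];
    }
    if (n1 == 0 || n1 == n) { out[c] = NA_REAL; continue; }
    out[c] = logrank_stat(time, event, grp);
  }
  return out;
}

// plain double-precision sequential cumulative sum (R's cumsum uses long
// double accumulation; the running-sum walk is defined in double so that
// an elementwise reimplementation reproduces it bit for bit)
// [[Rcpp::export]]
NumericVector cpp_cumsum_d(NumericVector x) {
  NumericVector out(x.size());
  double s = 0.0;
  for (int i = 0; i < x.size(); ++i) { s += x[i]; out[i] = s; }
  return out;
}
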