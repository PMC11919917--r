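#include <Rcpp.h>
using namespace Rcpp;

// Max circular-arc mean-shift statistic for a numeric series.
//
// Arcs are (i, j] in 0-based boundary coordinates, arc length
// k = j - i constrained to [min_width, n - min_width] so that both the
// arc and its (circular) complement hold at least min_width points.
// The statistic is the two-sample t-like quantity
//   |mean(arc) - mean(rest)| / (s * sqrt(1/k + 1/(n-k)))
// with s the sample sd of the whole series (assumed common variance).
// Ties resolve to the smallest arc length, then the smallest i, which
// the exhaustive reference search must mirror.
static void max_arc_stat(const double* x, int n, int min_width,
                         double& best, int& bi, int& bj) {
  best = 0.0; bi = 0; bj = n;
  if (n < 2 * min_width) return;
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  double mean = S[n] / n;
  double ss = 0.0;
  for (int t = 0; t < n; ++t) { double d = x[t] - mean; ss += d * d; }
  double s = std::sqrt(ss / (n - 1));
  if (!(s > 0.0)) return;
  double found = -1.0;
  for (int k = min_width; k <= n - min_width; ++k) {
    // |mean(arc) - mean(rest)| = n * |A - k*mean| / (k * (n-k))
    double denom = s * std::sqrt(1.0 / k + 1.0 / (n - k));
    double scale = (double)n / ((double)k * (double)(n - k)) / denom;
    for (int i = 0; i + k <= n; ++i) {
      double st = std::fabs(S[i + k] - S[i] - k * mean) * scale;
      if (st > found) { found = st; bi = i; bj = i + k; }
    }
  }
  if (found > 0.0) best = found;
}

// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width = 2) {
  double stat; int i, j;
  max_arc_stat(x.begin(), x.size(), min_width, stat, i, j);
  return List::create(_["stat"] = stat, _["i"] = i, _["j"] = j);
}

// Permutation reference distribution for the max arc statistic.
// Shuffles x with R's RNG (so results follow set.seed()) and counts
// permutations whose max statistic reaches stat_obs.  Stops early once
// exceed >= max_exceed because the split can then no longer reach
// significance at the caller's alpha.
// [[Rcpp::export]]
List cbs_perm_test(NumericVector x, double stat_obs, int n_perm,
                   int max_exceed, int min_width = 2) {
  RNGScope scope;
  int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  int exceed = 0, done = 0;
  double stat; int i, j;
  for (int p = 0; p < n_perm; ++p) {
    for (int t = n - 1; t > 0; --t) {
      int u = (int)std::floor(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(y[t], y[u]);
    }
    max_arc_stat(y.data(), n, min_width, stat, i, j);
    ++done;
    if (stat >= stat_obs) {
      ++exceed;
      if (exceed >= max_exceed) break;
    }
  }
  return List::create(_["exceed"] = exceed, _["n_done"] = done);
}
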