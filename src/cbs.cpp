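#include <Rcpp.h>
using namespace Rcpp;

// Arc-based circular binary segmentation kernels.
//
// A segment x[1..n] is treated as a circle; every arc x[(i+1)..j]
// (0 <= i < j <= n, arc length k in [2, n-2]) is compared against its
// complement with a pooled-variance two-sample t statistic. The scan is
// O(n^2) with cumulative sums; the permutation reference shuffles x in
// place and early-exits a scan as soon as any arc beats the observed
// statistic.

static double max_arc_t(const std::vector<double>& x, int* bi, int* bj) {
  const int n = (int)x.size();
  if (bi) *bi = -1;
  if (bj) *bj = -1;
  if (n < 4) return 0.0;
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    Q[t + 1] = Q[t] + x[t] * x[t];
  }
  const double Sn = S[n], Qn = Q[n];
  double best = 0.0;
  for (int i = 0; i <= n - 2; ++i) {
    for (int j = i + 2; j <= n; ++j) {
      const int k = j - i;
      if (k > n - 2) break;
      const double sa = S[j] - S[i];
      const double qa = Q[j] - Q[i];
      const double ma = sa / k;
      const double mb = (Sn - sa) / (n - k);
      const double ss = (qa - k * ma * ma) + ((Qn - qa) - (n - k) * mb * mb);
      double s2 = ss / (n - 2);
      if (s2 <= 0) continue;
      const double t = std::fabs(ma - mb) /
        std::sqrt(s2 * (1.0 / k + 1.0 / (n - k)));
      if (t > best) {
        best = t;
        if (bi) *bi = i;
        if (bj) *bj = j;
      }
    }
  }
  return best;
}

// Does any arc of x reach t >= thr? (early-exit scan for permutations)
static bool any_arc_ge(const std::vector<double>& x, double thr) {
  const int n = (int)x.size();
  if (n < 4) return false;
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    S[t + 1] = S[t] + x[t];
    Q[t + 1] = Q[t] + x[t] * x[t];
  }
  const double Sn = S[n], Qn = Q[n];
  for (int i = 0; i <= n - 2; ++i) {
    for (int j = i + 2; j <= n; ++j) {
      const int k = j - i;
      if (k > n - 2) break;
      const double sa = S[j] - S[i];
      const double qa = Q[j] - Q[i];
      const double ma = sa / k;
      const double mb = (Sn - sa) / (n - k);
      const double ss = (qa - k * ma * ma) + ((Qn - qa) - (n - k) * mb * mb);
      double s2 = ss / (n - 2);
      if (s2 <= 0) continue;
      const double t = std::fabs(ma - mb) /
        std::sqrt(s2 * (1.0 / k + 1.0 / (n - k)));
      if (t >= thr) return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  int i, j;
  double t = max_arc_t(v, &i, &j);
  return List::create(_["i"] = i, _["j"] = j, _["t"] = t);
}

// Count permutations whose max arc t reaches obs_t; stop once the count
// reaches early_stop (the accept decision is then already negative).
// [[Rcpp::export(name = ".cbs_perm_count")]]
int cbs_perm_count(NumericVector x, double obs_t, int nperm,
                   int early_stop) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  int count = 0;
  RNGScope scope;  // use R's RNG so set.seed() governs the permutations
  for (int p = 0; p < nperm; ++p) {
    for (int t = n - 1; t > 0; --t) {  // Fisher-Yates with R uniforms
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(v[t], v[u]);
    }
    if (any_arc_ge(v, obs_t)) {
      if (++count >= early_stop) return count;
    }
  }
  return count;
}
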