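#include <Rcpp.h>
using namespace Rcpp;

// Newton-Raphson fit of the Cox partial likelihood (Breslow ties) for a
// single binary covariate.  Data must be sorted by time ascending; tie
// groups and per-group event counts are precomputed by the caller.
//
// For a binary covariate the Breslow log partial likelihood reduces to
//   l(b) = b * D1 - sum_k d_k * log(n0_k + n1_k * exp(b))
// over tie groups k with d_k events, where n0_k/n1_k are the at-risk counts
// by group and D1 is the total number of events in group 1.  Score and
// information have closed forms, so a scalar Newton iteration suffices.

struct BinFit {
  double beta;
  double se;
  bool ok;
};

static BinFit fit_binary_breslow(const std::vector<int> &grp_start,
                                 const std::vector<int> &grp_d,
                                 const IntegerVector &status,
                                 const std::vector<int> &g,
                                 int n) {
  // suffix counts of group-1 membership: n1 at risk for group starting at s
  // computed on the fly via a reverse pass stored in suf1.
  static thread_local std::vector<int> suf1;
  suf1.resize(n + 1);
  suf1[n] = 0;
  for (int i = n - 1; i >= 0; --i) suf1[i] = suf1[i + 1] + g[i];

  int K = (int)grp_start.size();
  double D1 = 0.0, D = 0.0;
  static thread_local std::vector<double> n1k, n0k, dk, d1k;
  n1k.clear(); n0k.clear(); dk.clear(); d1k.clear();
  for (int k = 0; k < K; ++k) {
    int s = grp_start[k];
    int e = (k + 1 < K) ? grp_start[k + 1] : n;
    if (grp_d[k] == 0) continue;
    int d1 = 0;
    for (int i = s; i < e; ++i)
      if (status[i] == 1 && g[i] == 1) ++d1;
    double atrisk = n - s;
    double n1 = suf1[s];
    n1k.push_back(n1);
    n0k.push_back(atrisk - n1);
    dk.push_back((double)grp_d[k]);
    d1k.push_back((double)d1);
    D1 += d1;
    D += grp_d[k];
  }
  BinFit out;
  out.beta = NA_REAL; out.se = NA_REAL; out.ok = false;
  if (D < 1) return out;

  double b = 0.0;
  double info = 0.0;
  bool converged = false;
  for (int iter = 0; iter < 40; ++iter) {
    double U = D1, I = 0.0;
    const double eb = std::exp(b);
    for (size_t k = 0; k < dk.size(); ++k) {
      double r = n1k[k] * eb;
      double tot = n0k[k] + r;
      double frac = r / tot;
      U -= dk[k] * frac;
      I += dk[k] * frac * (1.0 - frac);
    }
    info = I;
    if (I < 1e-12) return out;  // covariate constant within risk sets
    double step = U / I;
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    b += step;
    if (b > 15.0) b = 15.0;
    if (b < -15.0) b = -15.0;
    if (std::fabs(step) < 1e-10) { converged = true; break; }
  }
  if (!converged && std::fabs(b) < 15.0) return out;
  out.beta = b;
  out.se = 1.0 / std::sqrt(info);
  out.ok = true;
  return out;
}

static void tie_groups(const NumericVector &time, const IntegerVector &status,
                       std::vector<int> &grp_start, std::vector<int> &grp_d) {
  int n = time.size();
  grp_start.clear();
  grp_d.clear();
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0;
    while (j < n && time[j] == time[i]) {
      if (status[j] == 1) ++d;
      ++j;
    }
    grp_start.push_back(i);
    grp_d.push_back(d);
    i = j;
  }
}

// [[Rcpp::export(name = ".cpp_cox_binary")]]
NumericVector cpp_cox_binary(NumericVector time, IntegerVector status,
                             IntegerVector group) {
  int n = time.size();
  IntegerVector ord(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  NumericVector t2(n);
  IntegerVector s2(n);
  std::vector<int> g(n);
  for (int i = 0; i < n; ++i) {
    t2[i] = time[idx[i]];
    s2[i] = status[idx[i]];
    g[i] = group[idx[i]];
  }
  std::vector<int> gs, gd;
  tie_groups(t2, s2, gs, gd);
  BinFit f = fit_binary_breslow(gs, gd, s2, g, n);
  return NumericVector::create(_["beta"] = f.beta, _["se"] = f.se,
                               _["ok"] = f.ok ? 1.0 : 0.0);
}

// Exhaustive scan over cutoff pairs and quadrant designs at one rotation
// angle.  x, y are the (already rotated) coordinates; c1grid/c2grid the
// candidate cutoffs; masks the 2-bit-per-quadrant HR-set encodings
// (bit q-1 set <=> quadrant q in the HR sector, quadrant = 1 + 2*(x>c1) +
// (y>c2)).  Data sorted by time ascending by the caller.  Returns one row
// per (design, i1, i2) in that loop order: beta, se (NA when the partition
// is inadmissible: a side smaller than min_group, no events, or a constant
// covariate within risk sets).
// [[Rcpp::export(name = ".cpp_scan_partitions")]]
NumericMatrix cpp_scan_partitions(NumericVector time, IntegerVector status,
                                  NumericVector x, NumericVector y,
                                  NumericVector c1grid, NumericVector c2grid,
                                  IntegerVector masks, int min_group) {
  int n = time.size();
  int nc1 = c1grid.size(), nc2 = c2grid.size(), nm = masks.size();
  std::vector<int> gs, gd;
  tie_groups(time, status, gs, gd);

  NumericMatrix out((R_xlen_t)nm * nc1 * nc2, 2);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> quad(n), g(n);

  for (int i1 = 0; i1 < nc1; ++i1) {
    double c1 = c1grid[i1];
    for (int i2 = 0; i2 < nc2; ++i2) {
      double c2 = c2grid[i2];
      for (int i = 0; i < n; ++i)
        quad[i] = (x[i] > c1 ? 2 : 0) + (y[i] > c2 ? 1 : 0);  // 0..3 = Q1..Q4
      for (int m = 0; m < nm; ++m) {
        int mask = masks[m];
        int n1 = 0;
        for (int i = 0; i < n; ++i) {
          g[i] = (mask >> quad[i]) & 1;
          n1 += g[i];
        }
        R_xlen_t row = ((R_xlen_t)m * nc1 + i1) * nc2 + i2;
        if (n1 < min_group || (n - n1) < min_group) continue;
        BinFit f = fit_binary_breslow(gs, gd, status, g, n);
        if (!f.ok) continue;
        out(row, 0) = f.beta;
        out(row, 1) = f.se;
      }
    }
  }
  return out;
}
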