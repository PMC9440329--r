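#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <functional>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Small dense Cholesky solve for SPD systems up to 6x6 (intercept + trend +
// at most 4 weather features).  Returns false on (near) rank deficiency so
// callers can skip degenerate designs.
static bool chol_solve(const double* A, const double* b, double* x, int m) {
  double L[36];
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * m + j];
      for (int k = 0; k < j; ++k) s -= L[i * m + k] * L[j * m + k];
      if (i == j) {
        if (s <= 1e-10 * (std::fabs(A[i * m + i]) + 1e-300)) return false;
        L[i * m + i] = std::sqrt(s);
      } else {
        L[i * m + j] = s / L[j * m + j];
      }
    }
  }
  double z[6];
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * m + k] * z[k];
    z[i] = s / L[i * m + i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < m; ++k) s -= L[k * m + i] * x[k];
    x[i] = s / L[i * m + i];
  }
  return true;
}

struct TopEntry {
  double r2;
  std::array<int, 4> idx;   // 0-based feature indices, ascending; -1 padded
  std::array<int, 4> rank;  // sorted name ranks; INT_MAX padded
};

// ranking order: higher R2 first; ties broken towards the combination whose
// sorted feature-name ranks are lexicographically smaller (deterministic)
static bool entry_better(const TopEntry& a, const TopEntry& b) {
  if (a.r2 != b.r2) return a.r2 > b.r2;
  return a.rank < b.rank;
}

// Exhaustive top-k best-subset search for one district and target year.
//
// W: n x p feature values (complete; the target year's row is already
//    censored on the R side); t: years; y: yields (complete)
// conflict: p x p, true where two features may not co-occur
// name_rank: 1-based lexicographic rank of each feature's name
// first_lo/first_hi: 1-based inclusive chunk bounds on the smallest feature
//   index of a combination (parallel-map contract; full range by default)
// [[Rcpp::export]]
List cpp_top_k(NumericMatrix W, NumericVector t, NumericVector y,
               int d, int k, LogicalMatrix conflict, IntegerVector name_rank,
               int first_lo, int first_hi) {
  const int n = W.nrow(), p = W.ncol();
  if (d < 1 || d > 4) stop("d must be in 1..4");
  const int m = d + 2, q = p + 2;
  const int IMAX = std::numeric_limits<int>::max();
  // centred trend keeps the Gram well conditioned for calendar years
  double tbar = 0, ybar = 0;
  for (int i = 0; i < n; ++i) { tbar += t[i]; ybar += y[i]; }
  tbar /= n; ybar /= n;
  std::vector<double> G((size_t)q * q, 0.0), gy(q, 0.0);
  {
    std::vector<double> z(q);
    for (int i = 0; i < n; ++i) {
      z[0] = 1.0; z[1] = t[i] - tbar;
      for (int j = 0; j < p; ++j) z[2 + j] = W(i, j);
      for (int a = 0; a < q; ++a) {
        gy[a] += z[a] * y[i];
        for (int b = 0; b <= a; ++b) G[(size_t)a * q + b] += z[a] * z[b];
      }
    }
    for (int a = 0; a < q; ++a)
      for (int b = a + 1; b < q; ++b) G[(size_t)a * q + b] = G[(size_t)b * q + a];
  }
  double yty = 0, sst = 0;
  for (int i = 0; i < n; ++i) {
    yty += y[i] * y[i];
    sst += (y[i] - ybar) * (y[i] - ybar);
  }
  if (sst <= 0) stop("zero yield variance");

  std::vector<TopEntry> top;  // kept sorted, best first
  top.reserve(k + 1);
  int sel[4];
  double A[36], rhs[6], beta[6];

  auto consider = [&]() {
    int cols[6] = {0, 1, 0, 0, 0, 0};
    for (int a = 0; a < d; ++a) cols[a + 2] = sel[a] + 2;
    for (int a = 0; a < m; ++a) {
      rhs[a] = gy[cols[a]];
      for (int b = 0; b < m; ++b)
        A[a * m + b] = G[(size_t)cols[a] * q + cols[b]];
    }
    if (!chol_solve(A, rhs, beta, m)) return;  // degenerate: excluded
    double rss = yty;
    for (int a = 0; a < m; ++a) rss -= beta[a] * rhs[a];
    double r2 = 1.0 - rss / sst;
    if ((int)top.size() >= k && r2 < top.back().r2) return;
    TopEntry e;
    e.r2 = r2;
    e.idx = {-1, -1, -1, -1};
    e.rank = {IMAX, IMAX, IMAX, IMAX};
    for (int a = 0; a < d; ++a) { e.idx[a] = sel[a]; e.rank[a] = name_rank[sel[a]]; }
    std::sort(e.rank.begin(), e.rank.begin() + d);
    if ((int)top.size() >= k) {
      if (!entry_better(e, top.back())) return;
      top.pop_back();
    }
    top.insert(std::upper_bound(top.begin(), top.end(), e, entry_better), e);
  };

  const int lo = std::max(0, first_lo - 1);
  const int hi = std::min(p - d, first_hi - 1);
  std::function<void(int, int)> rec = [&](int depth, int start) {
    const int jmax = p - d + depth;
    for (int j = start; j <= jmax; ++j) {
      bool ok = true;
      for (int a = 0; a < depth; ++a)
        if (conflict(sel[a], j)) { ok = false; break; }
      if (!ok) continue;
      sel[depth] = j;
      if (depth + 1 == d) consider();
      else rec(depth + 1, j + 1);
    }
  };
  for (int j0 = lo; j0 <= hi; ++j0) {
    sel[0] = j0;
    if (d == 1) consider();
    else rec(1, j0 + 1);
  }

  const int nt = (int)top.size();
  IntegerMatrix combos(nt, d);
  NumericVector r2s(nt);
  for (int i = 0; i < nt; ++i) {
    r2s[i] = top[i].r2;
    for (int a = 0; a < d; ++a) combos(i, a) = top[i].idx[a] + 1;
  }
  return List::create(_["combos"] = combos, _["r2"] = r2s);
}

// Leave-one-out Pearson skill of many feature combinations for one district.
//
// W: n x q screened feature values (rows = years with observed yield,
//    complete features); t: years; y: yields (no NA)
// combos: ncombo x d_max feature indices (1-based, 0-padded); sizes gives
//    each combination's number of features (0 = trend-only)
// target_idx: 1-based row of the target year among the n rows (0 if the
//    target year carries no observed yield)
// strict: censor the target year from every fit and from the correlation
// min_pairs: minimum prediction/observation pairs for a valid r
// [[Rcpp::export]]
NumericVector cpp_eval_combos(NumericMatrix W, NumericVector t,
                              NumericVector y, IntegerMatrix combos,
                              IntegerVector sizes, int target_idx,
                              bool strict, int min_pairs) {
  const int n = W.nrow();
  const int nc = combos.nrow();
  NumericVector out(nc, NA_REAL);
  const int tgt = target_idx - 1;  // -1 if absent
  double tbar = 0;
  for (int i = 0; i < n; ++i) tbar += t[i];
  tbar /= n;

  std::vector<double> Zs((size_t)n * 6);
  double Gf[36], gyf[6], A[36], rhs[6], beta[6];

  for (int c = 0; c < nc; ++c) {
    const int s = sizes[c], m = s + 2;
    for (int i = 0; i < n; ++i) {
      Zs[(size_t)i * m + 0] = 1.0;
      Zs[(size_t)i * m + 1] = t[i] - tbar;
      for (int a = 0; a < s; ++a)
        Zs[(size_t)i * m + 2 + a] = W(i, combos(c, a) - 1);
    }
    // Gram over the fitting base: all rows, minus the target when strict
    for (int a = 0; a < m; ++a) { gyf[a] = 0; for (int b = 0; b < m; ++b) Gf[a * m + b] = 0; }
    for (int i = 0; i < n; ++i) {
      if (strict && i == tgt) continue;
      const double* zi = &Zs[(size_t)i * m];
      for (int a = 0; a < m; ++a) {
        gyf[a] += zi[a] * y[i];
        for (int b = 0; b <= a; ++b) Gf[a * m + b] += zi[a] * zi[b];
      }
    }
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b) Gf[a * m + b] = Gf[b * m + a];

    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    int np = 0;
    for (int j = 0; j < n; ++j) {
      if (strict && j == tgt) continue;  // pair excluded from r as well
      const double* zj = &Zs[(size_t)j * m];
      for (int a = 0; a < m; ++a) {
        rhs[a] = gyf[a] - zj[a] * y[j];
        for (int b = 0; b < m; ++b)
          A[a * m + b] = Gf[a * m + b] - zj[a] * zj[b];
      }
      if (!chol_solve(A, rhs, beta, m)) continue;  // degenerate LOO fit
      double pred = 0;
      for (int a = 0; a < m; ++a) pred += zj[a] * beta[a];
      sx += pred; sy += y[j]; sxx += pred * pred; syy += y[j] * y[j];
      sxy += pred * y[j]; ++np;
    }
    if (np < min_pairs) continue;
    double vx = sxx - sx * sx / np, vy = syy - sy * sy / np;
    if (vx <= 0 || vy <= 0) continue;
    out[c] = (sxy - sx * sy / np) / std::sqrt(vx * vy);
  }
  return out;
}
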