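#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Knight (1966) O(n log n) Kendall tau-b.
// Returns NA_REAL when either vector is constant (tau undefined).
//
// Counts, with n0 = n(n-1)/2:
//   n1 = pairs tied in x, n2 = pairs tied in y, n3 = pairs tied in both,
//   S  = discordant pairs (merge-sort exchange count on y after sorting by x).
//   concordant - discordant = n0 - n1 - n2 + n3 - 2S
//   tau_b = (n0 - n1 - n2 + n3 - 2S) / sqrt((n0 - n1) * (n0 - n2))

static double merge_count(std::vector<double> &y, std::vector<double> &buf,
                          size_t lo, size_t hi) {
  // counts inversions in y[lo, hi) (strict), sorting in place
  if (hi - lo < 2) return 0.0;
  size_t mid = lo + (hi - lo) / 2;
  double cnt = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {            // strict: ties are not inversions
      cnt += (double)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi)  buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return cnt;
}

static double tau_b_core(const double *x, const double *y, int n) {
  if (n < 2) return NA_REAL;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  double n0 = (double)n * (n - 1) / 2.0;
  double n1 = 0.0, n3 = 0.0;

  // ties in x, and joint ties, along the x-sorted order
  {
    double run = 1.0, runxy = 1.0;
    for (int i = 1; i < n; ++i) {
      if (x[idx[i]] == x[idx[i - 1]]) {
        run += 1.0;
        if (y[idx[i]] == y[idx[i - 1]]) runxy += 1.0;
        else { n3 += runxy * (runxy - 1) / 2; runxy = 1.0; }
      } else {
        n1 += run * (run - 1) / 2;  run = 1.0;
        n3 += runxy * (runxy - 1) / 2; runxy = 1.0;
      }
    }
    n1 += run * (run - 1) / 2;
    n3 += runxy * (runxy - 1) / 2;
  }

  std::vector<double> ys(n), buf(n);
  for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
  double S = merge_count(ys, buf, 0, (size_t)n);  // ys now sorted

  double n2 = 0.0;
  {
    double run = 1.0;
    for (int i = 1; i < n; ++i) {
      if (ys[i] == ys[i - 1]) run += 1.0;
      else { n2 += run * (run - 1) / 2; run = 1.0; }
    }
    n2 += run * (run - 1) / 2;
  }

  double denom = std::sqrt((n0 - n1) * (n0 - n2));
  if (denom == 0.0) return NA_REAL;  // constant vector(s)
  return (n0 - n1 - n2 + n3 - 2.0 * S) / denom;
}

// [[Rcpp::export(name = ".kendall_tau_cpp")]]
double kendall_tau_cpp(NumericVector x, NumericVector y) {
  if (x.size() != y.size()) stop("x and y must have equal length");
  return tau_b_core(REAL(x), REAL(y), x.size());
}

// Pairwise tau-b between the ROWS of m (cells x genes); diagonal set to 1.
// Undefined pairs (constant rows) yield NA and are handled by the caller.
// [[Rcpp::export(name = ".kendall_tau_rows_cpp")]]
NumericMatrix kendall_tau_rows_cpp(NumericMatrix m) {
  int n = m.nrow(), g = m.ncol();
  NumericMatrix out(n, n);
  std::vector<double> xi(g), xj(g);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int k = 0; k < g; ++k) xi[k] = m(i, k);
    for (int j = i + 1; j < n; ++j) {
      for (int k = 0; k < g; ++k) xj[k] = m(j, k);
      double t = tau_b_core(xi.data(), xj.data(), g);
      out(i, j) = t;
      out(j, i) = t;
    }
  }
  return out;
}
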