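// Kendall's tau-b by Knight's O(n log n) algorithm: sort by (x, y),
// count discordant pairs as merge-sort inversions of y, correct for ties.
#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static double count_inversions(std::vector<double>& v, std::vector<double>& buf,
                               size_t lo, size_t hi) {
  if (hi - lo < 2) return 0.0;
  size_t mid = lo + (hi - lo) / 2;
  double inv = count_inversions(v, buf, lo, mid) + count_inversions(v, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (v[j] < v[i]) { inv += (double)(mid - i); buf[k++] = v[j++]; }
    else buf[k++] = v[i++];
  }
  while (i < mid) buf[k++] = v[i++];
  while (j < hi) buf[k++] = v[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, v.begin() + lo);
  return inv;
}

static double tie_pairs(const std::vector<double>& v) {
  double t = 0.0;
  size_t i = 0;
  while (i < v.size()) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    double m = (double)(j - i);
    t += m * (m - 1.0) / 2.0;
    i = j;
  }
  return t;
}

// [[Rcpp::export]]
double cpp_kendall_tau(NumericVector x, NumericVector y) {
  const size_t n = x.size();
  if (n < 2) return NA_REAL;
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> ys(n);
  for (size_t i = 0; i < n; ++i) ys[i] = y[ord[i]];

  // ties in x and joint ties, on the sorted order
  double n1 = 0.0, n3 = 0.0;
  size_t i = 0;
  while (i < n) {
    size_t j = i;
    while (j < n && x[ord[j]] == x[ord[i]]) ++j;
    double m = (double)(j - i);
    n1 += m * (m - 1.0) / 2.0;
    std::vector<double> grp(ys.begin() + i, ys.begin() + j);
    n3 += tie_pairs(grp); // grp already sorted within equal x
    i = j;
  }
  std::vector<double> buf(n);
  double disc = count_inversions(ys, buf, 0, n); // ys now sorted
  double n2 = tie_pairs(ys);
  double n0 = (double)n * ((double)n - 1.0) / 2.0;
  double num = n0 - n1 - n2 + n3 - 2.0 * disc;
  double den = std::sqrt((n0 - n1) * (n0 - n2));
  if (den <= 0.0) return NA_REAL;
  return num / den;
}
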