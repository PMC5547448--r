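#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Large sentinel standing in for +infinity; INT_MAX/4 leaves headroom for +1.
static const int ED_INF = INT_MAX / 4;

// Wagner-Fischer unit-cost edit distance, two rolling rows.
// [[Rcpp::export(name = ".cpp_edit_distance")]]
int cpp_edit_distance(std::string x, std::string y) {
  const std::string &a = (x.size() <= y.size()) ? x : y;
  const std::string &b = (x.size() <= y.size()) ? y : x;
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int i = 0; i <= n; ++i) prev[i] = i;
  for (int j = 1; j <= m; ++j) {
    cur[0] = j;
    const char bj = b[j - 1];
    for (int i = 1; i <= n; ++i) {
      int sub = prev[i - 1] + (a[i - 1] == bj ? 0 : 1);
      int del = prev[i] + 1;
      int ins = cur[i - 1] + 1;
      int v = sub < del ? sub : del;
      cur[i] = v < ins ? v : ins;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Banded edit distance: DP restricted to cells with |i - j| <= beff,
// out-of-band neighbours treated as +infinity. beff must already include
// any widening for unequal lengths (done on the R side).
// [[Rcpp::export(name = ".cpp_banded_edit_distance")]]
int cpp_banded_edit_distance(std::string x, std::string y, int beff) {
  const int n = (int)x.size(), m = (int)y.size();
  if (beff < 0) stop("band must be non-negative");
  std::vector<int> prev(m + 1, ED_INF), cur(m + 1, ED_INF);
  int hi0 = std::min(m, beff);
  for (int j = 0; j <= hi0; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - beff), hi = std::min(m, i + beff);
    for (int j = lo; j <= hi; ++j) cur[j] = ED_INF;
    if (lo == 0) cur[0] = i;
    const char xi = x[i - 1];
    for (int j = std::max(1, lo); j <= hi; ++j) {
      int diag = prev[j - 1];
      int up   = (j <= i - 1 + beff) ? prev[j] : ED_INF;   // (i-1, j) in band?
      int left = (j - 1 >= lo) ? cur[j - 1] : ED_INF;      // (i, j-1) in band?
      int sub = (diag >= ED_INF) ? ED_INF : diag + (xi == y[j - 1] ? 0 : 1);
      int del = (up   >= ED_INF) ? ED_INF : up + 1;
      int ins = (left >= ED_INF) ? ED_INF : left + 1;
      int v = sub < del ? sub : del;
      cur[j] = v < ins ? v : ins;
    }
    std::swap(prev, cur);
  }
  if (prev[m] >= ED_INF) stop("band infeasible: no path within band");
  return prev[m];
}
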