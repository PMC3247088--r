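#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bounded Levenshtein on code-point vectors: returns d(a,b) if <= t, else t+1.
// Banded DP (band half-width t) with per-row early exit.
static int lev_bounded_core(const int* a, int la, const int* b, int lb, int t) {
  if (la > lb) { std::swap(a, b); std::swap(la, lb); }
  if (lb - la > t) return t + 1;
  const int INF = t + 1;
  if (la == 0) return lb <= t ? lb : INF;
  std::vector<int> prev(lb + 1), cur(lb + 1, INF);
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= t) ? j : INF;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - t), jhi = std::min(lb, i + t);
    std::fill(cur.begin(), cur.end(), INF);
    if (jlo == 1 && i <= t) cur[0] = i;
    int rowmin = cur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int v = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      if (prev[j] + 1 < v) v = prev[j] + 1;
      if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > t) return INF;
    std::swap(prev, cur);
  }
  return prev[lb] > t ? INF : prev[lb];
}

// [[Rcpp::export]]
IntegerVector lev_pairs_cpp(List a, List b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector x = a[i], y = b[i];
    int t = x.size() + y.size();
    out[i] = lev_bounded_core(x.begin(), x.size(), y.begin(), y.size(), t);
  }
  return out;
}

// Bounded distance of one query against many values; t+1 encodes "> t".
// [[Rcpp::export]]
IntegerVector lev_query_cpp(IntegerVector q, List vals, int t) {
  int n = vals.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = vals[i];
    out[i] = lev_bounded_core(q.begin(), q.size(), v.begin(), v.size(), t);
  }
  return out;
}

// For unique string values with multiplicities, returns a U x (t+1) matrix:
// column l (0-based) holds, for each unique value, the total record count
// within Levenshtein distance l (its own multiplicity included).
// Pairs are pruned by length difference after sorting by length.
// [[Rcpp::export]]
IntegerMatrix kl_counts_cpp(List vals, IntegerVector counts, int t) {
  int U = vals.size();
  std::vector< std::vector<int> > v(U);
  std::vector<int> len(U);
  for (int i = 0; i < U; ++i) {
    IntegerVector x = vals[i];
    v[i].assign(x.begin(), x.end());
    len[i] = x.size();
  }
  std::vector<int> ord(U);
  for (int i = 0; i < U; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return len[x] < len[y]; });
  IntegerMatrix out(U, t + 1);
  for (int i = 0; i < U; ++i)
    for (int l = 0; l <= t; ++l) out(i, l) = counts[i];
  for (int ii = 0; ii < U; ++ii) {
    int i = ord[ii];
    const int* pi = v[i].empty() ? nullptr : v[i].data();
    for (int jj = ii + 1; jj < U; ++jj) {
      int j = ord[jj];
      if (len[j] - len[i] > t) break;
      const int* pj = v[j].empty() ? nullptr : v[j].data();
      int d = lev_bounded_core(pi, len[i], pj, len[j], t);
      if (d <= t) {
        for (int l = d; l <= t; ++l) {
          out(i, l) += counts[j];
          out(j, l) += counts[i];
        }
      }
    }
    if ((ii & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
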