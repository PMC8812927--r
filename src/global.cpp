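#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Banded global (Needleman-Wunsch, unit cost) alignment with an expanding
// band.  If the banded distance d satisfies d <= band, the optimal
// alignment stays within the band, so d is exact; otherwise the band is
// doubled.  Traceback tie-break prefers match > substitution > deletion
// (gap in query) > insertion (gap in reference) for deterministic column
// labels.  Ops in the returned CIGAR: '=' match, 'X' substitution,
// 'I' query-only base, 'D' reference-only base.

static const int INF = 1 << 29;

static bool banded_pass(const std::string& a, const std::string& b, int B,
                        int& dist, std::string& ops_out) {
  int m = (int)a.size(), n = (int)b.size();
  if (std::abs(n - m) > B) return false;
  int W = 2 * B + 1;
  std::vector<int> prev((size_t)W, INF), cur((size_t)W, INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 255);

  // row 0: j = jj - B (i = 0)
  for (int jj = 0; jj < W; ++jj) {
    int j = jj - B;
    if (j >= 0 && j <= n) { prev[jj] = j; tb[jj] = 2; } // leading D run
  }
  for (int i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    size_t row = (size_t)i * W;
    for (int jj = 0; jj < W; ++jj) {
      int j = jj + i - B;
      if (j < 0 || j > n) continue;
      int best = INF;
      uint8_t op = 255;
      if (j == 0) { best = i; op = 3; }
      if (j > 0) {
        int d = prev[jj]; // (i-1, j-1) same diagonal offset
        if (d < INF) {
          bool match = a[i - 1] == b[j - 1];
          int v = d + (match ? 0 : 1);
          if (v < best) { best = v; op = match ? 0 : 1; }
        }
        if (jj > 0 && cur[jj - 1] < INF && cur[jj - 1] + 1 < best) {
          best = cur[jj - 1] + 1; op = 2; // D: consume reference
        }
      }
      if (jj + 1 < W && prev[jj + 1] < INF && prev[jj + 1] + 1 < best) {
        best = prev[jj + 1] + 1; op = 3; // I: consume query
      }
      cur[jj] = best;
      tb[row + jj] = op;
    }
    std::swap(prev, cur);
  }
  int jj_end = n - m + B;
  if (jj_end < 0 || jj_end >= W || prev[jj_end] >= INF) return false;
  dist = prev[jj_end];
  if (dist > B) return false;

  std::string ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t op = tb[(size_t)i * W + (j - i + B)];
    switch (op) {
    case 0: ops.push_back('='); --i; --j; break;
    case 1: ops.push_back('X'); --i; --j; break;
    case 2: ops.push_back('D'); --j; break;
    case 3: ops.push_back('I'); --i; break;
    default: stop("internal error: broken traceback");
    }
  }
  std::reverse(ops.begin(), ops.end());
  ops_out = ops;
  return true;
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int band_init, int band_max) {
  int m = (int)a.size(), n = (int)b.size();
  int B = std::max(band_init, std::abs(n - m) + 1);
  int dist = 0;
  std::string ops;
  if (m == 0 || n == 0) {
    dist = std::max(m, n);
    ops.assign((size_t)m, 'I');
    ops.append((size_t)n, 'D');
  } else {
    bool ok = false;
    while (B <= band_max) {
      if (banded_pass(a, b, B, dist, ops)) { ok = true; break; }
      B *= 2;
    }
    if (!ok)
      stop("sequences differ by more than %d edits; increase band_max", band_max);
  }
  // run-length encode
  std::string cigar;
  long matches = 0;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    if (ops[p] == '=') matches += (long)(q - p);
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
  long cols = (long)ops.size();
  return List::create(_["distance"] = dist, _["cigar"] = cigar,
                      _["matches"] = (double)matches,
                      _["columns"] = (double)cols);
}
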