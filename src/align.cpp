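#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Exhaustive short-read aligner for fixture-scale problems.  Finds every
// location where a read aligns end-to-end with edit distance <= max_edits.
// Completeness comes from the pigeonhole principle: an alignment with at
// most e edits leaves at least one of e+1 non-overlapping k-mers of the
// read exactly matching the reference, on a diagonal within +-e of the
// alignment start.  Candidate loci are verified with an infix dynamic
// program over a padded window, which also collapses overlapping
// near-equal placements to the single best one per locus.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map; // kmer -> (contig, pos)
};

static void index_contig(KmerIndex& idx, int ci, const std::string& s) {
  int k = idx.k;
  int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid >= k) idx.map[kmer].push_back({ci, i - k + 1});
  }
}

struct Hit {
  int contig;
  int start;
  int end;   // half-open reference end
  int dist;
  std::string cigar;
};

// Infix alignment of read into window (read must align end to end; window
// start/end are free).  Returns best distance, or INT_MAX if > max_edits;
// fills start offset within window and CIGAR (M/I/D, M covers match and
// mismatch).  Deterministic tie-breaks: leftmost alignment end, then
// diagonal > reference-gap (D) > read-gap (I) during traceback.
static int infix_align(const std::string& read, const std::string& win,
                       int max_edits, int& w_off, std::string& cigar) {
  int m = (int)read.size(), n = (int)win.size();
  std::vector<int> dp((size_t)(m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) dp[j] = 0;
  for (int i = 1; i <= m; ++i) {
    size_t row = (size_t)i * (n + 1), prev = row - (n + 1);
    dp[row] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = dp[prev + j - 1] + (read[i - 1] == win[j - 1] ? 0 : 1);
      int del = dp[row + j - 1] + 1;   // gap in read: consumes window (D)
      int ins = dp[prev + j] + 1;      // gap in window: consumes read (I)
      int v = sub < del ? sub : del;
      dp[row + j] = v < ins ? v : ins;
    }
  }
  size_t last = (size_t)m * (n + 1);
  int best = dp[last], bj = 0;
  for (int j = 1; j <= n; ++j)
    if (dp[last + j] < best) { best = dp[last + j]; bj = j; }
  if (best > max_edits) return INT_MAX;

  // traceback
  std::string ops;
  int i = m, j = bj;
  while (i > 0) {
    int cur = dp[(size_t)i * (n + 1) + j];
    if (j > 0 && dp[(size_t)(i - 1) * (n + 1) + j - 1] +
                     (read[i - 1] == win[j - 1] ? 0 : 1) == cur) {
      ops.push_back('M'); --i; --j;
    } else if (j > 0 && dp[(size_t)i * (n + 1) + j - 1] + 1 == cur) {
      ops.push_back('D'); --j;
    } else {
      ops.push_back('I'); --i;
    }
  }
  w_off = j;
  std::reverse(ops.begin(), ops.end());
  cigar.clear();
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
  return best;
}

static void align_one_strand(const std::string& read, const KmerIndex& idx,
                             const std::vector<std::string>& contigs,
                             int max_edits, std::vector<Hit>& hits) {
  int L = (int)read.size();
  int k = idx.k;
  if (L < k) return;
  // seed offsets: e+1 pigeonhole pieces plus the final k-mer
  std::vector<int> offs;
  for (int i = 0; i <= max_edits; ++i) {
    int o = i * k;
    if (o + k <= L) offs.push_back(o);
  }
  if (L - k > (offs.empty() ? -1 : offs.back())) offs.push_back(L - k);

  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // candidate starts per contig
  std::unordered_map<int, std::vector<int>> cand;
  for (int o : offs) {
    uint64_t kmer = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int c = base_code(read[o + i]);
      if (c < 0) { ok = false; break; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    auto it = idx.map.find(kmer);
    if (it == idx.map.end()) continue;
    for (const auto& cp : it->second) cand[cp.first].push_back(cp.second - o);
  }

  for (auto& kv : cand) {
    int ci = kv.first;
    const std::string& ref = contigs[ci];
    int clen = (int)ref.size();
    std::vector<int>& starts = kv.second;
    std::sort(starts.begin(), starts.end());
    starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
    size_t a = 0;
    while (a < starts.size()) {
      size_t b = a;
      while (b + 1 < starts.size() &&
             starts[b + 1] - starts[b] <= 2 * max_edits + 1) ++b;
      int w0 = std::max(0, starts[a] - max_edits);
      int w1 = std::min(clen, starts[b] + L + max_edits);
      if (w1 - w0 >= L - max_edits) {
        int w_off = 0;
        std::string cigar;
        int d = infix_align(read, ref.substr(w0, w1 - w0), max_edits, w_off, cigar);
        if (d != INT_MAX) {
          // reference span from CIGAR
          int span = 0, len = 0;
          for (char c : cigar) {
            if (c >= '0' && c <= '9') len = len * 10 + (c - '0');
            else { if (c == 'M' || c == 'D') span += len; len = 0; }
          }
          hits.push_back({ci, w0 + w_off, w0 + w_off + span, d, cigar});
        }
      }
      a = b + 1;
    }
  }
}

// [[Rcpp::export]]
List cpp_exhaustive_align(CharacterVector read_seqs, CharacterVector rc_seqs,
                          CharacterVector contig_seqs, int max_edits, int kmer) {
  int ncontig = contig_seqs.size();
  std::vector<std::string> contigs(ncontig);
  for (int i = 0; i < ncontig; ++i) contigs[i] = as<std::string>(contig_seqs[i]);
  KmerIndex idx;
  idx.k = kmer;
  for (int i = 0; i < ncontig; ++i) index_contig(idx, i, contigs[i]);

  std::vector<int> o_read, o_contig, o_start, o_dist;
  std::vector<bool> o_rev;
  std::vector<std::string> o_cigar;

  int nreads = read_seqs.size();
  for (int r = 0; r < nreads; ++r) {
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = as<std::string>(strand == 0 ? read_seqs[r] : rc_seqs[r]);
      std::vector<Hit> hits;
      align_one_strand(s, idx, contigs, max_edits, hits);
      // merge overlapping placements at one locus: keep the best
      std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
        if (a.contig != b.contig) return a.contig < b.contig;
        if (a.start != b.start) return a.start < b.start;
        return a.dist < b.dist;
      });
      std::vector<Hit> kept;
      for (const Hit& h : hits) {
        if (!kept.empty() && kept.back().contig == h.contig &&
            h.start < kept.back().end) {
          if (h.dist < kept.back().dist) kept.back() = h;
        } else {
          kept.push_back(h);
        }
      }
      for (const Hit& h : kept) {
        o_read.push_back(r + 1);
        o_contig.push_back(h.contig + 1);
        o_start.push_back(h.start);
        o_dist.push_back(h.dist);
        o_rev.push_back(strand == 1);
        o_cigar.push_back(h.cigar);
      }
    }
  }

  return List::create(_["read"] = wrap(o_read), _["contig"] = wrap(o_contig),
                      _["start"] = wrap(o_start), _["is_reverse"] = wrap(o_rev),
                      _["edit_distance"] = wrap(o_dist),
                      _["cigar"] = wrap(o_cigar));
}
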