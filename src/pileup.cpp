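#include <Rcpp.h>
#include <map>
#include <vector>
#include <string>
using namespace Rcpp;

struct CigarOp {
  char op;
  int len;
};

static std::vector<CigarOp> parse_cigar_ops(const std::string& cig) {
  std::vector<CigarOp> ops;
  long len = 0;
  bool have_len = false;
  for (char c : cig) {
    if (c >= '0' && c <= '9') {
      len = len * 10 + (c - '0');
      have_len = true;
    } else {
      if (!have_len || len < 1) stop("invalid CIGAR '%s'", cig);
      ops.push_back({c, (int)len});
      len = 0;
      have_len = false;
    }
  }
  if (have_len) stop("invalid CIGAR '%s' (trailing length)", cig);
  if (ops.empty()) stop("empty CIGAR");
  return ops;
}

// One read "piece": the read content attributed to a single assembly
// position.  first_idx/last_idx are 0-based indices into the aligned
// (clip-stripped) read sequence; -1 marks a deletion piece that consumes
// no read bases.
struct Piece {
  int pos;
  std::string val;
  int first_idx;
  int last_idx;
};

// Strip soft/hard clips; returns core ops and the clip-stripped sequence.
static void strip_clips(const std::vector<CigarOp>& ops, const std::string& seq,
                        std::vector<CigarOp>& core, std::string& aseq) {
  size_t lo = 0, hi = ops.size();
  int lead = 0, tail = 0;
  while (lo < hi && (ops[lo].op == 'S' || ops[lo].op == 'H')) {
    if (ops[lo].op == 'S') lead += ops[lo].len;
    ++lo;
  }
  while (hi > lo && (ops[hi - 1].op == 'S' || ops[hi - 1].op == 'H')) {
    if (ops[hi - 1].op == 'S') tail += ops[hi - 1].len;
    --hi;
  }
  core.assign(ops.begin() + lo, ops.begin() + hi);
  for (const CigarOp& o : core)
    if (o.op == 'S' || o.op == 'H') stop("clip op inside CIGAR body");
  if ((int)seq.size() < lead + tail) stop("CIGAR clips longer than sequence");
  aseq = seq.substr(lead, seq.size() - lead - tail);
}

// Walk core CIGAR ops, emitting one piece per covered reference position.
// An insertion attaches its bases to the piece of the preceding reference
// position; an insertion before the first reference-consuming op is
// discarded.
static std::vector<Piece> walk_core(const std::vector<CigarOp>& core,
                                    int ref_start, const std::string& aseq) {
  std::vector<Piece> out;
  int rpos = ref_start;
  int a = 0;
  for (const CigarOp& o : core) {
    switch (o.op) {
    case 'M': case '=': case 'X':
      for (int i = 0; i < o.len; ++i) {
        if (a >= (int)aseq.size()) stop("CIGAR consumes more read bases than SEQ provides");
        out.push_back({rpos, std::string(1, aseq[a]), a, a});
        ++rpos;
        ++a;
      }
      break;
    case 'I':
      if (a + o.len > (int)aseq.size()) stop("CIGAR consumes more read bases than SEQ provides");
      if (!out.empty()) {
        Piece& p = out.back();
        p.val.append(aseq, a, o.len);
        if (p.first_idx < 0) p.first_idx = a;
        p.last_idx = a + o.len - 1;
      }
      a += o.len;
      break;
    case 'D':
      for (int i = 0; i < o.len; ++i) {
        out.push_back({rpos, "", -1, -1});
        ++rpos;
      }
      break;
    case 'N':
      stop("CIGAR op 'N' is not supported");
    default:
      stop("unknown CIGAR op '%c'", o.op);
    }
  }
  if (a != (int)aseq.size())
    stop("CIGAR read-consuming length does not match SEQ length");
  return out;
}

// Length of the terminal run of identical characters, + 1, capped at length.
static int terminal_trim(const std::string& s, bool from_start) {
  int n = (int)s.size();
  if (n == 0) return 0;
  int run = 1;
  if (from_start) {
    while (run < n && s[run] == s[0]) ++run;
  } else {
    while (run < n && s[n - 1 - run] == s[n - 1]) ++run;
  }
  int t = run + 1;
  return t > n ? n : t;
}

// Keep pieces[0..k): drop from the first piece touching any read index
// >= cutoff (trailing deletion pieces fall after it and drop too).
static size_t end_keep_count(const std::vector<Piece>& pieces, int cutoff) {
  if (cutoff <= 0) return 0;
  for (size_t i = 0; i < pieces.size(); ++i)
    if (pieces[i].last_idx >= cutoff) return i;
  return pieces.size();
}

// Number of leading pieces to drop: through the last piece touching any
// read index < lead_cut.
static size_t start_drop_count(const std::vector<Piece>& pieces, int lead_cut) {
  size_t d = 0;
  for (size_t i = 0; i < pieces.size(); ++i)
    if (pieces[i].first_idx >= 0 && pieces[i].first_idx < lead_cut) d = i + 1;
  return d;
}

// [[Rcpp::export]]
List cpp_build_pileup(CharacterVector contig_names, IntegerVector contig_lens,
                      IntegerVector aln_contig, IntegerVector aln_start,
                      CharacterVector aln_cigar, CharacterVector aln_seq,
                      NumericVector aln_weight, bool trim_both) {
  int ncontig = contig_names.size();
  int naln = aln_contig.size();
  std::vector<std::vector<double>> depth(ncontig);
  std::vector<std::vector<std::map<std::string, int>>> counts(ncontig);
  for (int c = 0; c < ncontig; ++c) {
    depth[c].assign(contig_lens[c], 0.0);
    counts[c].resize(contig_lens[c]);
  }
  IntegerVector retained(naln);

  for (int r = 0; r < naln; ++r) {
    int ci = aln_contig[r] - 1;
    if (ci < 0 || ci >= ncontig) stop("alignment %d references unknown contig", r + 1);
    std::string cig = as<std::string>(aln_cigar[r]);
    std::string seq = as<std::string>(aln_seq[r]);
    std::vector<CigarOp> ops = parse_cigar_ops(cig);
    std::vector<CigarOp> core;
    std::string aseq;
    strip_clips(ops, seq, core, aseq);
    if (aseq.empty()) { retained[r] = 0; continue; }
    std::vector<Piece> pieces = walk_core(core, aln_start[r], aseq);

    int A = (int)aseq.size();
    int t_end = terminal_trim(aseq, false);
    size_t keep = end_keep_count(pieces, A - t_end);
    size_t drop0 = 0;
    if (trim_both) {
      int t_lead = terminal_trim(aseq, true);
      drop0 = start_drop_count(pieces, t_lead);
    }
    if (drop0 > keep) drop0 = keep;

    int kept = 0;
    double w = aln_weight[r];
    int clen = contig_lens[ci];
    for (size_t i = drop0; i < keep; ++i) {
      int p = pieces[i].pos;
      if (p < 0 || p >= clen)
        stop("alignment %d overruns contig '%s'", r + 1,
             as<std::string>(contig_names[ci]).c_str());
      counts[ci][p][pieces[i].val] += 1;
      depth[ci][p] += w;
      ++kept;
    }
    retained[r] = kept;
  }

  List out(ncontig);
  for (int c = 0; c < ncontig; ++c) {
    size_t nrec = 0;
    for (const auto& m : counts[c]) nrec += m.size();
    IntegerVector pos((R_xlen_t)nrec), cnt((R_xlen_t)nrec);
    CharacterVector piece((R_xlen_t)nrec);
    R_xlen_t j = 0;
    for (int p = 0; p < contig_lens[c]; ++p) {
      for (const auto& kv : counts[c][p]) {
        pos[j] = p;
        piece[j] = kv.first;
        cnt[j] = kv.second;
        ++j;
      }
    }
    out[c] = List::create(_["depth"] = NumericVector(depth[c].begin(), depth[c].end()),
                          _["pos"] = pos, _["piece"] = piece, _["count"] = cnt);
  }
  out.attr("names") = contig_names;
  out.attr("retained") = retained;
  return out;
}
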