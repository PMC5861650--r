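// Semi-global ("glocal") affine-gap alignment of reads against reference
// amplicons: the read aligns end-to-end (terminal read gaps penalized as
// insertions), reference end gaps are free.  Used both as a single-pair
// aligner with full traceback and as a batch read-pair -> best-amplicon
// assigner with fast paths (exact substring, ungapped scan with overhangs,
// banded DP refinement around the scan diagonal).

#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <cstring>
#include <unordered_map>
using namespace Rcpp;

static const int NEG = -1000000000;

struct Scheme {
  int match, mismatch, gap_open, gap_extend;
  double min_identity, min_aligned_fraction;
};

struct Aln {
  bool has = false;
  int score = NEG;
  int ref_start = 0, ref_end = 0;
  std::string cigar;
  int n_match = 0, n_cols = 0;
  char strand = '+';
  bool from_scan = false;   // produced by the ungapped scan (may underestimate)
  int scan_mis = 0, scan_offset = 0;
  bool valid = false;
};

static char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// ---------------------------------------------------------------------------
// Ungapped scan over all offsets, read overhangs beyond the reference ends
// penalized as affine gaps.  Complete for substitution-only alignments.
// ---------------------------------------------------------------------------
struct ScanRes {
  int score = NEG;
  int offset = 0;   // ref position of read base 0 (may be negative)
  int mis = 0, overlap = 0;
};

static ScanRes scan_range(const std::string& r, const std::string& ref,
                          const Scheme& sc, int floor_score,
                          int o_from, int o_to) {
  int m = (int)r.size(), n = (int)ref.size();
  ScanRes best;
  best.score = floor_score;
  bool found = false;
  const char* rp = r.data();
  const char* fp = ref.data();
  int step = sc.match - sc.mismatch; // score loss per mismatch
  o_from = std::max(o_from, -(m - 1));
  o_to = std::min(o_to, n - 1);
  for (int o = o_from; o <= o_to; ++o) {
    int lo = std::max(0, -o), hi = std::min(m, n - o);
    int olen = hi - lo;
    if (olen <= 0) continue;
    int hl = lo, hr = m - hi;
    int pen = 0;
    if (hl > 0) pen += sc.gap_open + sc.gap_extend * hl;
    if (hr > 0) pen += sc.gap_open + sc.gap_extend * hr;
    int cur = sc.match * olen + pen;
    if (cur <= best.score) continue;
    int mis = 0;
    const char* a = rp + lo;
    const char* b = fp + o + lo;
    for (int k = 0; k < olen; ++k) {
      if (a[k] != b[k]) {
        ++mis;
        cur -= step;
        if (cur <= best.score) break;
      }
    }
    if (cur > best.score) {
      best.score = cur; best.offset = o; best.mis = mis; best.overlap = olen;
      found = true;
    }
  }
  if (!found) best.score = NEG;
  return best;
}

static ScanRes scan_best(const std::string& r, const std::string& ref,
                         const Scheme& sc, int floor_score) {
  return scan_range(r, ref, sc, floor_score, -((int)r.size() - 1),
                    (int)ref.size() - 1);
}

// ---------------------------------------------------------------------------
// 12-mer seeding: restrict candidate alignment diagonals of a read against
// an amplicon to those supported by exact shared 12-mers.  An alignment
// passing the identity threshold on 150-nt reads retains long exact
// stretches, so absence of any shared seed implies no passable alignment.
// ---------------------------------------------------------------------------
static const int SEED_K = 12;

struct AmpIndex {
  std::unordered_map<uint32_t, std::vector<int>> pos;
};

static bool encode_kmer(const char* s, uint32_t& key) {
  uint32_t k = 0;
  for (int i = 0; i < SEED_K; ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: return false;
    }
    k = (k << 2) | b;
  }
  key = k;
  return true;
}

static AmpIndex build_amp_index(const std::string& ref) {
  AmpIndex idx;
  int n = (int)ref.size();
  for (int p = 0; p + SEED_K <= n; ++p) {
    uint32_t key;
    if (encode_kmer(ref.data() + p, key)) idx.pos[key].push_back(p);
  }
  return idx;
}

// candidate diagonal clusters (offset ranges) for read vs indexed amplicon
static std::vector<std::pair<int, int>> seed_diagonals(const std::string& r,
                                                       const AmpIndex& idx) {
  std::vector<int> diags;
  int m = (int)r.size();
  for (int q = 0; q + SEED_K <= m; q += 4) {
    uint32_t key;
    if (!encode_kmer(r.data() + q, key)) continue;
    auto it = idx.pos.find(key);
    if (it == idx.pos.end()) continue;
    for (int p : it->second) diags.push_back(p - q);
  }
  std::vector<std::pair<int, int>> out;
  if (diags.empty()) return out;
  std::sort(diags.begin(), diags.end());
  int lo = diags[0], hi = diags[0];
  for (size_t i = 1; i < diags.size(); ++i) {
    if (diags[i] - hi <= 35) hi = diags[i];
    else { out.emplace_back(lo, hi); lo = hi = diags[i]; }
  }
  out.emplace_back(lo, hi);
  return out;
}

static void append_op(std::string& cig, char op, int len) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

static Aln aln_from_scan(const std::string& r, const std::string& ref,
                         const Scheme& sc, const ScanRes& s, char strand) {
  Aln a;
  if (s.score <= NEG) return a;
  int m = (int)r.size(), n = (int)ref.size();
  int lo = std::max(0, -s.offset), hi = std::min(m, n - s.offset);
  a.has = true;
  a.score = s.score;
  a.strand = strand;
  a.from_scan = true;
  a.scan_mis = s.mis;
  a.scan_offset = s.offset;
  a.ref_start = std::max(0, s.offset);
  a.ref_end = std::min(n, s.offset + m);
  a.n_match = (hi - lo) - s.mis;
  a.n_cols = m;  // every column consumes a read base (overhangs are I ops)
  std::string cig;
  append_op(cig, 'I', lo);
  // runs of =/X across the overlap
  int runlen = 0; char runop = 0;
  for (int k = lo; k < hi; ++k) {
    char op = (r[k] == ref[s.offset + k]) ? '=' : 'X';
    if (op == runop) ++runlen;
    else { append_op(cig, runop, runlen); runop = op; runlen = 1; }
  }
  append_op(cig, runop, runlen);
  append_op(cig, 'I', m - hi);
  a.cigar = cig;
  return a;
}

// ---------------------------------------------------------------------------
// Gotoh glocal DP with optional banding around a diagonal. Traceback ties
// resolved deterministically: MATCH/SUB > DEL > INS.
// ---------------------------------------------------------------------------
struct DpBuf {
  std::vector<int> M, X, Y;           // X: insertion (consumes read), Y: deletion
  std::vector<unsigned char> tM, tX, tY;
  void resize(size_t sz) {
    if (M.size() < sz) {
      M.resize(sz); X.resize(sz); Y.resize(sz);
      tM.resize(sz); tX.resize(sz); tY.resize(sz);
    }
  }
};

static DpBuf g_buf;

static Aln align_glocal(const std::string& r, const std::string& ref,
                        const Scheme& sc, int diag, int band, char strand) {
  int m = (int)r.size(), n = (int)ref.size();
  Aln out;
  if (m == 0 || n == 0) return out;
  bool banded = band >= 0;
  size_t W = (size_t)(n + 1);
  g_buf.resize((size_t)(m + 1) * W);
  int* M = g_buf.M.data(); int* X = g_buf.X.data(); int* Y = g_buf.Y.data();
  unsigned char* tM = g_buf.tM.data();
  unsigned char* tX = g_buf.tX.data();
  unsigned char* tY = g_buf.tY.data();
  int go = sc.gap_open, ge = sc.gap_extend;

  auto rowlo = [&](int i) {
    return banded ? std::max(0, diag + i - band) : 0;
  };
  auto rowhi = [&](int i) {
    return banded ? std::min(n, diag + i + band) : n;
  };

  // row 0: free reference prefix
  {
    int lo = std::max(0, rowlo(0) - 1), hi = std::min(n, rowhi(0) + 1);
    for (int j = lo; j <= hi; ++j) {
      M[j] = 0; X[j] = NEG; Y[j] = NEG;
    }
  }
  for (int i = 1; i <= m; ++i) {
    size_t ro = (size_t)i * W, po = (size_t)(i - 1) * W;
    int lo = rowlo(i), hi = rowhi(i);
    int ilo = std::max(0, lo - 1), ihi = std::min(n, hi + 1);
    for (int j = ilo; j <= ihi; ++j) {
      M[ro + j] = NEG; X[ro + j] = NEG; Y[ro + j] = NEG;
    }
    char rc_ = r[i - 1];
    for (int j = lo; j <= hi; ++j) {
      // X: insertion (read base vs gap), from row above same column
      {
        int fm = M[po + j] + go + ge;
        int fx = X[po + j] + ge;
        int fy = Y[po + j] + go + ge;
        // priority M > Y > X on ties
        int v; unsigned char t;
        if (fm >= fy && fm >= fx) { v = fm; t = 0; }
        else if (fy >= fx) { v = fy; t = 2; }
        else { v = fx; t = 1; }
        X[ro + j] = v; tX[ro + j] = t;
      }
      if (j >= 1) {
        // M: diagonal
        int s = (rc_ == ref[j - 1]) ? sc.match : sc.mismatch;
        int dm = M[po + j - 1], dx = X[po + j - 1], dy = Y[po + j - 1];
        int v; unsigned char t;
        if (dm >= dy && dm >= dx) { v = dm; t = 0; }
        else if (dy >= dx) { v = dy; t = 2; }
        else { v = dx; t = 1; }
        M[ro + j] = (v <= NEG / 2) ? NEG : v + s;
        tM[ro + j] = t;
        // Y: deletion (gap vs ref base), from left same row
        int gm = M[ro + j - 1] + go + ge;
        int gx = X[ro + j - 1] + go + ge;
        int gy = Y[ro + j - 1] + ge;
        if (gm >= gy && gm >= gx) { v = gm; t = 0; }
        else if (gy >= gx) { v = gy; t = 2; }
        else { v = gx; t = 1; }
        Y[ro + j] = v; tY[ro + j] = t;
      }
    }
  }

  // best over final row: free reference suffix; trailing deletions excluded
  size_t fo = (size_t)m * W;
  int best = NEG, bj = -1; unsigned char bstate = 0;
  for (int j = rowlo(m); j <= rowhi(m); ++j) {
    if (M[fo + j] > best) { best = M[fo + j]; bj = j; bstate = 0; }
    if (X[fo + j] > best) { best = X[fo + j]; bj = j; bstate = 1; }
  }
  if (bj < 0 || best <= NEG / 2) return out;

  // traceback
  std::vector<std::pair<char, int>> ops;
  int i = m, j = bj; unsigned char st = bstate;
  int n_match = 0, n_cols = 0;
  auto push = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.emplace_back(op, 1);
    ++n_cols;
  };
  while (i > 0) {
    size_t ro = (size_t)i * W;
    if (st == 0) {
      char op = (r[i - 1] == ref[j - 1]) ? '=' : 'X';
      if (op == '=') ++n_match;
      push(op);
      st = tM[ro + j]; --i; --j;
    } else if (st == 1) {
      push('I');
      st = tX[ro + j]; --i;
    } else {
      push('D');
      st = tY[ro + j]; --j;
    }
  }
  out.has = true;
  out.score = best;
  out.ref_start = j;
  out.ref_end = bj;
  out.n_match = n_match;
  out.n_cols = n_cols;
  out.strand = strand;
  std::string cig;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    append_op(cig, it->first, it->second);
  out.cigar = cig;
  return out;
}

// compact "op:refpos:len" summary of I/D ops (semicolon-separated);
// insertions sit between ref bases refpos-1 and refpos
static std::string indel_summary(const std::string& cigar, int ref_start) {
  std::string out;
  int pos = ref_start;
  size_t k = 0;
  while (k < cigar.size()) {
    int len = 0;
    while (k < cigar.size() && isdigit(cigar[k])) len = len * 10 + (cigar[k++] - '0');
    char op = cigar[k++];
    if (op == 'I' || op == 'D') {
      if (!out.empty()) out += ';';
      out += op;
      out += ':';
      out += std::to_string(pos);
      out += ':';
      out += std::to_string(len);
    }
    if (op == '=' || op == 'X' || op == 'D') pos += len;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_align_glocal(std::string read, std::string ref,
                      int match, int mismatch, int gap_open, int gap_extend) {
  Scheme sc{match, mismatch, gap_open, gap_extend, 0.0, 0.0};
  Aln a = align_glocal(read, ref, sc, 0, -1, '+');
  return List::create(
    _["score"] = a.has ? a.score : NA_INTEGER,
    _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
    _["cigar"] = a.cigar, _["n_match"] = a.n_match, _["n_cols"] = a.n_cols);
}

// ---------------------------------------------------------------------------
// Batch assignment of read pairs to amplicons.
// ---------------------------------------------------------------------------

static void set_valid(Aln& a, int readlen, const Scheme& sc) {
  if (!a.has || readlen == 0) { a.valid = false; return; }
  double identity = a.n_cols > 0 ? (double)a.n_match / (double)a.n_cols : 0.0;
  double frac = (double)readlen / (double)readlen; // read aligns end-to-end
  a.valid = identity >= sc.min_identity && frac >= sc.min_aligned_fraction;
}

// best alignment of one mate against one amplicon (both strands): exact
// substring short-circuit, then seeded ungapped scan with overhangs
static Aln mate_vs_amp(const std::string& s, const std::string& sr,
                       const std::string& amp, const AmpIndex& idx,
                       const Scheme& sc) {
  Aln a;
  int m = (int)s.size();
  if (m == 0) return a;
  size_t pf = amp.find(s);
  if (pf != std::string::npos) {
    a.has = true; a.score = sc.match * m;
    a.ref_start = (int)pf; a.ref_end = (int)pf + m;
    a.n_match = m; a.n_cols = m; a.strand = '+';
    a.cigar = std::to_string(m) + "=";
    return a;
  }
  size_t pr = amp.find(sr);
  if (pr != std::string::npos) {
    a.has = true; a.score = sc.match * m;
    a.ref_start = (int)pr; a.ref_end = (int)pr + m;
    a.n_match = m; a.n_cols = m; a.strand = '-';
    a.cigar = std::to_string(m) + "=";
    return a;
  }
  ScanRes best;
  best.score = NEG;
  char best_strand = '+';
  const std::string* best_read = &s;
  for (int st = 0; st < 2; ++st) {
    const std::string& rd = st == 0 ? s : sr;
    if (m <= 2 * SEED_K) {
      // too short to seed reliably: full scan is cheap at this length
      ScanRes r = scan_best(rd, amp, sc, best.score);
      if (r.score > best.score) {
        best = r; best_strand = st == 0 ? '+' : '-'; best_read = &rd;
      }
      continue;
    }
    for (auto& d : seed_diagonals(rd, idx)) {
      ScanRes r = scan_range(rd, amp, sc, best.score, d.first - 35,
                             d.second + 35);
      if (r.score > best.score) {
        best = r; best_strand = st == 0 ? '+' : '-'; best_read = &rd;
      }
    }
  }
  if (best.score <= NEG) return a;
  return aln_from_scan(*best_read, amp, sc, best, best_strand);
}

// [[Rcpp::export]]
List cpp_assign_pairs(CharacterVector r1, CharacterVector r2,
                      CharacterVector amp_seq, LogicalVector amp_is_wt,
                      int match, int mismatch, int gap_open, int gap_extend,
                      double min_identity, double min_aligned_fraction,
                      int band_width = 45, int candidate_margin = 120,
                      int scan_clean_mis = 2) {
  Scheme sc{match, mismatch, gap_open, gap_extend,
            min_identity, min_aligned_fraction};
  int np = r1.size();
  int na = amp_seq.size();
  std::vector<std::string> amps(na);
  std::vector<AmpIndex> amp_idxs(na);
  for (int a = 0; a < na; ++a) {
    amps[a] = as<std::string>(amp_seq[a]);
    amp_idxs[a] = build_amp_index(amps[a]);
  }

  IntegerVector amp_idx(np), pair_score(np);
  LogicalVector single_mate(np);
  IntegerVector m1_score(np), m1_start(np), m1_match(np), m1_cols(np);
  IntegerVector m2_score(np), m2_start(np), m2_match(np), m2_cols(np);
  IntegerVector m1_end(np), m2_end(np);
  CharacterVector m1_cigar(np), m2_cigar(np), m1_strand(np), m2_strand(np);
  CharacterVector m1_indels(np), m2_indels(np);
  LogicalVector m1_valid(np), m2_valid(np);

  std::vector<Aln> res1(na), res2(na);
  for (int i = 0; i < np; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2[i]);
    std::string s1r = revcomp(s1), s2r = revcomp(s2);

    for (int mate = 0; mate < 2; ++mate) {
      const std::string& s = mate == 0 ? s1 : s2;
      const std::string& sr = mate == 0 ? s1r : s2r;
      std::vector<Aln>& res = mate == 0 ? res1 : res2;
      int gbest = NEG;
      for (int a = 0; a < na; ++a) {
        res[a] = mate_vs_amp(s, sr, amps[a], amp_idxs[a], sc);
        if (res[a].has && res[a].score > gbest) gbest = res[a].score;
      }
      // banded DP refinement for scan results that might hide an indel;
      // the candidate threshold is frozen at the pre-refinement best so a
      // competitor refined earlier cannot mask the true amplicon
      int thresh = gbest - candidate_margin;
      for (int a = 0; a < na; ++a) {
        Aln& cur = res[a];
        if (!cur.has || !cur.from_scan) continue;
        if (cur.score < thresh) continue;
        if (cur.scan_mis <= scan_clean_mis) continue;
        const std::string& sAl = cur.strand == '+' ? s : sr;
        Aln dp = align_glocal(sAl, amps[a], sc, cur.scan_offset, band_width,
                              cur.strand);
        if (dp.has && dp.score > cur.score) cur = dp;
      }
      for (int a = 0; a < na; ++a) set_valid(res[a], (int)s.size(), sc);
    }

    // pick best amplicon: both mates valid preferred; single-mate rescue
    // prefers the anchored primer-side mate (R1), which carries the junction
    // signal, over an R2-only hit; ties then prefer wildtype amplicons, then
    // the lower amplicon index (caller passes amplicons sorted by id)
    int best_a = -1, best_sc_ = NEG;
    bool best_single = false, best_v1 = false;
    for (int pass = 0; pass < 2 && best_a < 0; ++pass) {
      for (int a = 0; a < na; ++a) {
        bool v1 = res1[a].valid, v2 = res2[a].valid;
        int sc_pair;
        if (pass == 0) {
          if (!(v1 && v2)) continue;
          sc_pair = res1[a].score + res2[a].score;
        } else {
          if (!(v1 || v2)) continue;
          sc_pair = v1 ? res1[a].score : res2[a].score;
        }
        bool better = false;
        if (best_a < 0) better = true;
        else if (pass == 1 && v1 != best_v1) better = v1;
        else if (sc_pair > best_sc_) better = true;
        else if (sc_pair == best_sc_) {
          bool cw = amp_is_wt[a], bw = amp_is_wt[best_a];
          if (cw && !bw) better = true;
        }
        if (better) { best_a = a; best_sc_ = sc_pair; best_v1 = v1; }
      }
      if (pass == 1 && best_a >= 0) best_single = true;
    }

    if (best_a < 0) {
      amp_idx[i] = NA_INTEGER; pair_score[i] = NA_INTEGER;
      single_mate[i] = false;
      m1_valid[i] = m2_valid[i] = false;
      m1_score[i] = m2_score[i] = NA_INTEGER;
      m1_start[i] = m2_start[i] = NA_INTEGER;
      m1_end[i] = m2_end[i] = NA_INTEGER;
      m1_match[i] = m2_match[i] = NA_INTEGER;
      m1_cols[i] = m2_cols[i] = NA_INTEGER;
      m1_cigar[i] = NA_STRING; m2_cigar[i] = NA_STRING;
      m1_strand[i] = NA_STRING; m2_strand[i] = NA_STRING;
      m1_indels[i] = NA_STRING; m2_indels[i] = NA_STRING;
      continue;
    }
    amp_idx[i] = best_a + 1;
    pair_score[i] = best_sc_;
    single_mate[i] = best_single;
    const Aln& a1 = res1[best_a];
    const Aln& a2 = res2[best_a];
    m1_valid[i] = a1.valid; m2_valid[i] = a2.valid;
    m1_score[i] = a1.has ? a1.score : NA_INTEGER;
    m2_score[i] = a2.has ? a2.score : NA_INTEGER;
    m1_start[i] = a1.has ? a1.ref_start : NA_INTEGER;
    m2_start[i] = a2.has ? a2.ref_start : NA_INTEGER;
    m1_end[i] = a1.has ? a1.ref_end : NA_INTEGER;
    m2_end[i] = a2.has ? a2.ref_end : NA_INTEGER;
    m1_match[i] = a1.n_match; m2_match[i] = a2.n_match;
    m1_cols[i] = a1.n_cols; m2_cols[i] = a2.n_cols;
    m1_cigar[i] = a1.has ? a1.cigar : std::string("");
    m2_cigar[i] = a2.has ? a2.cigar : std::string("");
    m1_indels[i] = a1.has ? indel_summary(a1.cigar, a1.ref_start) : std::string("");
    m2_indels[i] = a2.has ? indel_summary(a2.cigar, a2.ref_start) : std::string("");
    m1_strand[i] = std::string(1, a1.strand);
    m2_strand[i] = std::string(1, a2.strand);
  }

  return List::create(
    _["amp_idx"] = amp_idx, _["pair_score"] = pair_score,
    _["single_mate"] = single_mate,
    _["m1_valid"] = m1_valid, _["m1_strand"] = m1_strand,
    _["m1_score"] = m1_score, _["m1_ref_start"] = m1_start,
    _["m1_ref_end"] = m1_end,
    _["m1_cigar"] = m1_cigar, _["m1_indels"] = m1_indels,
    _["m1_match"] = m1_match, _["m1_cols"] = m1_cols,
    _["m2_valid"] = m2_valid, _["m2_strand"] = m2_strand,
    _["m2_score"] = m2_score, _["m2_ref_start"] = m2_start,
    _["m2_ref_end"] = m2_end,
    _["m2_cigar"] = m2_cigar, _["m2_indels"] = m2_indels,
    _["m2_match"] = m2_match, _["m2_cols"] = m2_cols);
}

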