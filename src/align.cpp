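// k-mer seeded Smith-Waterman read aligner.
//
// The index hashes every k-mer (stride = step) of the forward genome strand;
// query k-mers vote for diagonals, diagonal clusters are extended by a full
// affine-gap local DP over a banded genome window, and the best and
// second-best placements yield score, CIGAR and a gap-based mapping quality.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char RC[4] = {'T', 'G', 'C', 'A'};

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base2code(s[s.size() - 1 - i]);
    r[i] = (c < 0) ? 'N' : RC[c];
  }
  return r;
}

struct KmerIndex {
  std::string seq;       // genome, upper-case
  int k;
  int step;
  std::unordered_map<uint32_t, std::vector<int32_t> > table; // 0-based pos
};

// pack a k-mer starting at seq[pos]; returns false if any non-ACGT base
static bool pack_kmer(const std::string& seq, int pos, int k, uint32_t* out) {
  uint32_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base2code(seq[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint32_t)c;
  }
  *out = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string seq, int k, int step) {
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  if (step < 1) stop("step must be >= 1");
  if ((int)seq.size() < k) stop("genome shorter than k");
  KmerIndex* idx = new KmerIndex();
  std::transform(seq.begin(), seq.end(), seq.begin(), ::toupper);
  idx->seq = seq;
  idx->k = k;
  idx->step = step;
  int last = (int)seq.size() - k;
  for (int p = 0; p <= last; p += step) {
    uint32_t key;
    if (pack_kmer(seq, p, k, &key)) idx->table[key].push_back(p);
  }
  XPtr<KmerIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp_, std::string kmer) {
  XPtr<KmerIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("query length != k");
  std::transform(kmer.begin(), kmer.end(), kmer.begin(), ::toupper);
  uint32_t key;
  if (!pack_kmer(kmer, 0, xp->k, &key)) return IntegerVector(0);
  auto it = xp->table.find(key);
  if (it == xp->table.end()) return IntegerVector(0);
  IntegerVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1; // 1-based
  return out;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp_) { XPtr<KmerIndex> xp(xp_); return xp->k; }

// [[Rcpp::export]]
int cpp_index_len(SEXP xp_) { XPtr<KmerIndex> xp(xp_); return (int)xp->seq.size(); }

struct Placement {
  int score = 0;
  int ref_start = 0;   // 0-based inclusive, in genome
  int ref_end = 0;     // 0-based exclusive
  int q_start = 0;     // 0-based inclusive, in query orientation used
  int q_end = 0;       // exclusive
  bool reverse = false;
  std::string cigar;   // with soft clips, in SAM (reference) orientation
};

// full affine-gap local DP of query vs a genome window; traceback for best cell
static Placement window_sw(const std::string& g, int wbeg, int wend,
                           const std::string& q, bool reverse,
                           int match, int mismatch, int gap_open, int gap_extend,
                           bool want_cigar) {
  const int n = (int)q.size();
  const int m = wend - wbeg;
  // H = best ending here; E = gap in query (deletion from ref consumes ref);
  // F = gap in ref (insertion, consumes query)
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), INT32_MIN / 4),
      F((n + 1) * (m + 1), INT32_MIN / 4);
  // traceback: 0 stop, 1 diag, 2 up(E? ), encode per matrix
  std::vector<uint8_t> TH, TE, TF;
  if (want_cigar) {
    TH.assign((n + 1) * (m + 1), 0);
    TE.assign((n + 1) * (m + 1), 0);
    TF.assign((n + 1) * (m + 1), 0);
  }
  int best = 0, bi = 0, bj = 0;
  const int W = m + 1;
  for (int i = 1; i <= n; ++i) {
    const int qc = base2code(q[i - 1]);
    for (int j = 1; j <= m; ++j) {
      const int id = i * W + j;
      // E: deletion (ref consumed, query gap) — move along j
      int e_open = H[id - 1] + gap_open + gap_extend;
      int e_ext  = E[id - 1] + gap_extend;
      int e = std::max(e_open, e_ext);
      if (want_cigar) TE[id] = (e_ext > e_open) ? 1 : 0;
      E[id] = e;
      // F: insertion (query consumed, ref gap) — move along i
      int f_open = H[id - W] + gap_open + gap_extend;
      int f_ext  = F[id - W] + gap_extend;
      int f = std::max(f_open, f_ext);
      if (want_cigar) TF[id] = (f_ext > f_open) ? 1 : 0;
      F[id] = f;
      int gc = base2code(g[wbeg + j - 1]);
      int sub = (qc >= 0 && qc == gc) ? match : mismatch;
      int diag = H[id - W - 1] + sub;
      int h = std::max(std::max(diag, 0), std::max(e, f));
      H[id] = h;
      if (want_cigar) {
        uint8_t t = 0;
        if (h == 0) t = 0;
        else if (h == diag) t = 1;
        else if (h == e) t = 2;
        else t = 3;
        TH[id] = t;
      }
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  Placement pl;
  pl.score = best;
  pl.reverse = reverse;
  if (best <= 0) return pl;
  if (!want_cigar) {
    pl.ref_end = wbeg + bj;
    pl.q_end = bi;
    return pl;
  }
  // traceback
  std::vector<std::pair<char, int> > ops; // in reverse
  int i = bi, j = bj, state = 0; // 0=H,1=E,2=F
  auto push = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back(std::make_pair(op, 1));
  };
  while (i > 0 && j > 0) {
    int id = i * W + j;
    if (state == 0) {
      uint8_t t = TH[id];
      if (t == 0) break;
      if (t == 1) { push('M'); --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      push('D'); // ref consumed, query gap
      uint8_t t = TE[id];
      --j;
      if (t == 0) state = 0;
    } else {
      push('I');
      uint8_t t = TF[id];
      --i;
      if (t == 0) state = 0;
    }
  }
  pl.ref_start = wbeg + j;
  pl.ref_end = wbeg + bj;
  pl.q_start = i;
  pl.q_end = bi;
  // assemble CIGAR in reference orientation with soft clips
  std::string cg;
  int lead = pl.q_start, trail = n - pl.q_end;
  std::reverse(ops.begin(), ops.end());
  if (lead > 0) cg += std::to_string(lead) + "S";
  for (auto& o : ops) cg += std::to_string(o.second) + std::string(1, o.first);
  if (trail > 0) cg += std::to_string(trail) + "S";
  pl.cigar = cg;
  return pl;
}

struct AlnResult {
  bool mapped = false;
  int pos = NA_INTEGER;      // 1-based leftmost on genome
  int score = NA_INTEGER;
  int second = NA_INTEGER;   // NA if none
  int mapq = NA_INTEGER;
  bool reverse = false;
  std::string cigar;
};

static AlnResult align_one(const KmerIndex& idx, const std::string& read_,
                           int match, int mismatch, int gap_open, int gap_extend,
                           int band, int min_score, int max_clusters) {
  AlnResult res;
  std::string fwd = read_;
  std::transform(fwd.begin(), fwd.end(), fwd.begin(), ::toupper);
  std::string rev = revcomp(fwd);
  const int n = (int)fwd.size();
  const int k = idx.k;
  const int L = (int)idx.seq.size();
  if (n < k) return res;

  struct Cand { int diag_lo, diag_hi, votes; bool reverse; };
  std::vector<Cand> cands;
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& q = strand ? rev : fwd;
    std::unordered_map<int, int> votes; // diagonal -> count
    for (int j = 0; j + k <= n; ++j) {
      uint32_t key;
      if (!pack_kmer(q, j, k, &key)) continue;
      auto it = idx.table.find(key);
      if (it == idx.table.end()) continue;
      if ((int)it->second.size() > 64) continue; // repeat k-mer, uninformative
      for (int32_t g : it->second) votes[g - j]++;
    }
    // cluster diagonals within band
    std::vector<std::pair<int, int> > dv(votes.begin(), votes.end());
    std::sort(dv.begin(), dv.end());
    size_t i = 0;
    while (i < dv.size()) {
      int lo = dv[i].first, hi = dv[i].first, v = dv[i].second;
      size_t j2 = i + 1;
      while (j2 < dv.size() && dv[j2].first - hi <= band) {
        hi = dv[j2].first; v += dv[j2].second; ++j2;
      }
      Cand c; c.diag_lo = lo; c.diag_hi = hi; c.votes = v; c.reverse = (strand == 1);
      cands.push_back(c);
      i = j2;
    }
  }
  if (cands.empty()) return res;
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.votes > b.votes; });
  if ((int)cands.size() > max_clusters) cands.resize(max_clusters);

  // evaluate each cluster without traceback; keep best & runner-up
  int besti = -1, best = -1, second = -1;
  std::vector<Placement> pls(cands.size());
  for (size_t c = 0; c < cands.size(); ++c) {
    const Cand& cd = cands[c];
    int wbeg = std::max(0, cd.diag_lo - band);
    int wend = std::min(L, cd.diag_hi + n + band);
    if (wend <= wbeg) continue;
    const std::string& q = cd.reverse ? rev : fwd;
    pls[c] = window_sw(idx.seq, wbeg, wend, q, cd.reverse,
                       match, mismatch, gap_open, gap_extend, false);
    int s = pls[c].score;
    if (s > best) { second = best; best = s; besti = (int)c; }
    else if (s > second) second = s;
  }
  if (besti < 0 || best < min_score) return res;

  // redo best with traceback
  const Cand& cd = cands[besti];
  int wbeg = std::max(0, cd.diag_lo - band);
  int wend = std::min(L, cd.diag_hi + n + band);
  const std::string& q = cd.reverse ? rev : fwd;
  Placement pl = window_sw(idx.seq, wbeg, wend, q, cd.reverse,
                           match, mismatch, gap_open, gap_extend, true);
  res.mapped = true;
  res.pos = pl.ref_start + 1;
  res.score = pl.score;
  res.reverse = pl.reverse;
  res.cigar = pl.cigar;
  if (second < 0) { res.second = NA_INTEGER; res.mapq = 60; }
  else {
    res.second = second;
    int gap = pl.score - second;
    res.mapq = (gap <= 0) ? 0 : std::min(60, 2 * gap);
  }
  return res;
}

// [[Rcpp::export]]
List cpp_align_batch(SEXP xp_, CharacterVector reads,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int band, int min_score, int max_clusters) {
  XPtr<KmerIndex> xp(xp_);
  const int N = reads.size();
  LogicalVector mapped(N), reverse(N);
  IntegerVector pos(N), score(N), second(N), mapq(N);
  CharacterVector cigar(N);
  for (int i = 0; i < N; ++i) {
    AlnResult r = align_one(*xp, as<std::string>(reads[i]), match, mismatch,
                            gap_open, gap_extend, band, min_score, max_clusters);
    mapped[i] = r.mapped;
    pos[i] = r.pos;
    score[i] = r.mapped ? r.score : NA_INTEGER;
    second[i] = r.second;
    mapq[i] = r.mapped ? r.mapq : NA_INTEGER;
    reverse[i] = r.reverse;
    if (r.mapped) cigar[i] = r.cigar; else cigar[i] = NA_STRING;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["mapped"] = mapped, _["pos"] = pos, _["score"] = score,
                      _["second_score"] = second, _["mapq"] = mapq,
                      _["reverse"] = reverse, _["cigar"] = cigar);
}
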