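// Local alignment engine: full-matrix Smith-Waterman (Gotoh affine gaps)
// for proteins, and exact k-mer seeded banded extension for nucleotides.
// Gap of length k costs gap_open + k * gap_extend throughout.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

struct AlnStats {
  int score = 0;
  int q0 = 0, q1 = 0, s0 = 0, s1 = 0; // 0-based half-open
  int len = 0, ident = 0;
  bool found = false;
};

static const int NEG = -1000000000;

// ---------------------------------------------------------------------------
// Full-matrix Smith-Waterman with affine gaps and traceback.
// sub128: 128x128 substitution scores indexed by ASCII code (column-major,
// as passed from an R integer matrix). Reusable workspace avoids per-call
// allocation in batched searches.
// ---------------------------------------------------------------------------
struct SwWork {
  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;
  void ensure(size_t cells) {
    if (H.size() < cells) {
      H.resize(cells); E.resize(cells); F.resize(cells);
      tbH.resize(cells); tbE.resize(cells); tbF.resize(cells);
    }
  }
};

static void sw_full(const std::string& a, const std::string& b,
                    const int* sub128, int go, int ge, AlnStats& out,
                    SwWork& wk) {
  const int m = (int)a.size(), n = (int)b.size();
  wk.ensure((size_t)(m + 1) * (n + 1));
  int* H = wk.H.data();
  int* E = wk.E.data();
  int* F = wk.F.data();
  unsigned char* tbH = wk.tbH.data();
  unsigned char* tbE = wk.tbE.data();
  unsigned char* tbF = wk.tbF.data();
  auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  // boundaries: first row/column only (inner cells are all overwritten)
  for (int j = 0; j <= n; ++j) {
    H[idx(0, j)] = 0; E[idx(0, j)] = NEG; tbH[idx(0, j)] = 0;
  }
  for (int i = 0; i <= m; ++i) {
    H[idx(i, 0)] = 0; F[idx(i, 0)] = NEG; tbH[idx(i, 0)] = 0;
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ca = (unsigned char)a[i - 1] & 127;
    for (int j = 1; j <= n; ++j) {
      const size_t k = idx(i, j);
      // E: gap in b (consume a_i)
      int eH = H[idx(i - 1, j)] - go - ge;
      int eE = E[idx(i - 1, j)] - ge;
      if (eE > eH) { E[k] = eE; tbE[k] = 1; } else { E[k] = eH; tbE[k] = 0; }
      // F: gap in a (consume b_j)
      int fH = H[idx(i, j - 1)] - go - ge;
      int fF = F[idx(i, j - 1)] - ge;
      if (fF > fH) { F[k] = fF; tbF[k] = 1; } else { F[k] = fH; tbF[k] = 0; }
      const int cb = (unsigned char)b[j - 1] & 127;
      int diag = H[idx(i - 1, j - 1)] + sub128[ca + 128 * cb];
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[k] > h) { h = E[k]; t = 2; }
      if (F[k] > h) { h = F[k]; t = 3; }
      H[k] = h; tbH[k] = t;
      if (h > best) { best = h; bi = i; bj = j; } // first max kept (row-major)
    }
  }
  out.score = best;
  out.found = best > 0;
  if (!out.found) return;
  // traceback
  int i = bi, j = bj, state = 0; // 0=H,1=E,2=F
  int len = 0, ident = 0;
  while (true) {
    if (state == 0) {
      unsigned char t = tbH[idx(i, j)];
      if (t == 0) break;
      if (t == 1) {
        ++len;
        if (a[i - 1] == b[j - 1]) ++ident;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++len;
      state = tbE[idx(i, j)] ? 1 : 0;
      --i;
    } else {
      ++len;
      state = tbF[idx(i, j)] ? 2 : 0;
      --j;
    }
  }
  out.q0 = i; out.q1 = bi; out.s0 = j; out.s1 = bj;
  out.len = len; out.ident = ident;
}

// [[Rcpp::export]]
List cpp_sw_protein(std::string a, std::string b, IntegerMatrix sub128,
                    int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("empty sequence");
  if ((double)a.size() * (double)b.size() > 6e7)
    stop("sequences too long for full-matrix alignment");
  AlnStats st;
  SwWork wk;
  sw_full(a, b, sub128.begin(), gap_open, gap_extend, st, wk);
  return List::create(_["found"] = st.found, _["score"] = st.score,
                      _["q_start"] = st.q0, _["q_end"] = st.q1,
                      _["s_start"] = st.s0, _["s_end"] = st.s1,
                      _["length"] = st.len, _["identities"] = st.ident);
}

// ---------------------------------------------------------------------------
// Nucleotide: banded local alignment within diagonal band [lo_d, hi_d]
// (diagonal d = s - q, 0-based). Simple match/mismatch scoring; N never
// matches anything (scores as mismatch).
// ---------------------------------------------------------------------------
static void banded_nt(const std::string& a, const std::string& b,
                      int lo_d, int hi_d, int match, int mismatch,
                      int go, int ge, AlnStats& out) {
  const int m = (int)a.size(), n = (int)b.size();
  const int W = hi_d - lo_d + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<int> E((size_t)(m + 1) * W, NEG);
  std::vector<int> F((size_t)(m + 1) * W, NEG);
  std::vector<unsigned char> tb((size_t)(m + 1) * W, 0); // packed: H 2 bits, E 1, F 1
  auto idx = [W](int i, int o) { return (size_t)i * W + o; };

  int best = 0, bi = 0, bo = 0;
  for (int i = 1; i <= m; ++i) {
    const char ca = a[i - 1];
    for (int o = 0; o < W; ++o) {
      const int s = i + lo_d + o; // 1-based subject position
      if (s < 1 || s > n) { H[idx(i, o)] = NEG / 2; continue; }
      const size_t k = idx(i, o);
      int e = NEG, f = NEG;
      unsigned char te = 0, tf = 0;
      if (o + 1 < W) { // from (i-1, o+1): gap in b
        int prevH = H[idx(i - 1, o + 1)];
        int prevE = E[idx(i - 1, o + 1)];
        if (prevH > NEG / 4) e = prevH - go - ge;
        if (prevE > NEG / 4 && prevE - ge > e) { e = prevE - ge; te = 1; }
      }
      if (o - 1 >= 0 && s - 1 >= 1) { // from (i, o-1): gap in a
        int prevH = H[idx(i, o - 1)];
        int prevF = F[idx(i, o - 1)];
        if (prevH > NEG / 4) f = prevH - go - ge;
        if (prevF > NEG / 4 && prevF - ge > f) { f = prevF - ge; tf = 1; }
      }
      E[k] = e; F[k] = f;
      int diag = NEG;
      {
        int prev;
        if (i - 1 == 0 || s - 1 == 0) prev = 0; // matrix boundary
        else prev = H[idx(i - 1, o)];           // NEG/2 when outside band
        if (prev > NEG / 4) {
          const char cb = b[s - 1];
          const bool isN = (ca == 'N' || cb == 'N');
          diag = prev + ((!isN && ca == cb) ? match : -mismatch);
        }
      }
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      H[k] = h;
      tb[k] = (unsigned char)(t | (te << 2) | (tf << 3));
      if (h > best) { best = h; bi = i; bo = o; }
    }
  }
  out.score = best;
  out.found = best > 0;
  if (!out.found) return;
  int i = bi, o = bo, state = 0;
  int len = 0, ident = 0;
  while (true) {
    const size_t k = idx(i, o);
    if (state == 0) {
      unsigned char t = tb[k] & 3;
      if (t == 0) break;
      if (t == 1) {
        const int s = i + lo_d + o;
        ++len;
        if (a[i - 1] == b[s - 1] && a[i - 1] != 'N') ++ident;
        --i; // diag keeps o
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: came from (i-1, o+1)
      ++len;
      state = (tb[k] >> 2) & 1 ? 1 : 0;
      --i; ++o;
    } else { // F: came from (i, o-1)
      ++len;
      state = (tb[k] >> 3) & 1 ? 2 : 0;
      --o;
    }
  }
  out.q0 = i; out.q1 = bi;
  out.s0 = i + lo_d + o; out.s1 = bi + lo_d + bo;
  out.len = len; out.ident = ident;
}

// --- k-mer machinery -------------------------------------------------------

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string& s, int k, KmerIndex& ix) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int v = base2(s[i]);
    if (v < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)v) & mask;
    if (++valid >= k) ix[code].push_back(i - k + 1);
  }
}

struct Seed { int d; int s; };

// collect seed diagonals of query (forward) against an indexed subject
static void collect_seeds(const std::string& q, int k, const KmerIndex& ix,
                          std::vector<Seed>& seeds) {
  const int m = (int)q.size();
  if (m < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < m; ++i) {
    int v = base2(q[i]);
    if (v < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)v) & mask;
    if (++valid >= k) {
      auto it = ix.find(code);
      if (it != ix.end()) {
        const int qpos = i - k + 1;
        for (int sp : it->second) seeds.push_back({sp - qpos, sp});
      }
    }
  }
}

// cluster seeds into bands and run banded extension; keep hits per cluster
static void extend_clusters(const std::string& q, const std::string& s,
                            std::vector<Seed>& seeds, int match, int mismatch,
                            int go, int ge, int pad,
                            std::vector<AlnStats>& hits) {
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    return x.d != y.d ? x.d < y.d : x.s < y.s;
  });
  const int m = (int)q.size();
  const int max_diam = 2 * pad; // cap band width
  std::vector<std::pair<int,int> > ranges; // [lo_d, hi_d] per cluster
  int lo = seeds[0].d, hi = seeds[0].d, slast = seeds[0].s;
  for (size_t i = 1; i <= seeds.size(); ++i) {
    bool brk = (i == seeds.size());
    if (!brk) {
      const Seed& sd = seeds[i];
      brk = (sd.d - hi > 2 * pad) || (sd.d - lo > max_diam) ||
            (sd.d == hi && sd.s - slast > 3 * m);
    }
    if (brk) {
      ranges.push_back({lo, hi});
      if (i < seeds.size()) { lo = hi = seeds[i].d; slast = seeds[i].s; }
    } else {
      hi = std::max(hi, seeds[i].d);
      slast = seeds[i].s;
    }
  }
  for (auto& r : ranges) {
    AlnStats st;
    banded_nt(q, s, r.first - pad, r.second + pad, match, mismatch, go, ge, st);
    if (st.found) hits.push_back(st);
  }
}

// [[Rcpp::export]]
DataFrame cpp_nt_hits(std::string query, std::string subject, int k,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int band_pad) {
  KmerIndex ix;
  build_index(subject, k, ix);
  std::vector<Seed> seeds;
  collect_seeds(query, k, ix, seeds);
  std::vector<AlnStats> hits;
  extend_clusters(query, subject, seeds, match, mismatch, gap_open,
                  gap_extend, band_pad, hits);
  std::sort(hits.begin(), hits.end(), [](const AlnStats& x, const AlnStats& y) {
    if (x.score != y.score) return x.score > y.score;
    if (x.q0 != y.q0) return x.q0 < y.q0;
    return x.s0 < y.s0;
  });
  const int nh = (int)hits.size();
  IntegerVector sc(nh), q0(nh), q1(nh), s0(nh), s1(nh), ln(nh), id(nh);
  for (int i = 0; i < nh; ++i) {
    sc[i] = hits[i].score; q0[i] = hits[i].q0; q1[i] = hits[i].q1;
    s0[i] = hits[i].s0; s1[i] = hits[i].s1; ln[i] = hits[i].len;
    id[i] = hits[i].ident;
  }
  return DataFrame::create(_["score"] = sc, _["q_start"] = q0, _["q_end"] = q1,
                           _["s_start"] = s0, _["s_end"] = s1,
                           _["length"] = ln, _["identities"] = id);
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Batched read recruitment: best qualifying hit per read across a genome
// panel, both strands. Genomes must be passed in the desired tie-break
// order (lexicographically smallest ID first).
// [[Rcpp::export]]
DataFrame cpp_recruit_batch(CharacterVector reads, CharacterVector genomes,
                            int k, int match, int mismatch, int gap_open,
                            int gap_extend, int band_pad,
                            double id_min, double cov_min) {
  const int ng = genomes.size();
  std::vector<std::string> gs(ng);
  std::vector<KmerIndex> ixs(ng);
  for (int g = 0; g < ng; ++g) {
    gs[g] = as<std::string>(genomes[g]);
    build_index(gs[g], k, ixs[g]);
  }
  std::vector<int> o_read, o_gen, o_q0, o_q1, o_s0, o_s1, o_len, o_id, o_sc, o_str;
  const int nr = reads.size();
  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const std::string rev = revcomp(fwd);
    const int m = (int)fwd.size();
    AlnStats best; int bg = -1, bstr = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      for (int g = 0; g < ng; ++g) {
        std::vector<Seed> seeds;
        collect_seeds(q, k, ixs[g], seeds);
        if (seeds.empty()) continue;
        std::vector<AlnStats> hits;
        extend_clusters(q, gs[g], seeds, match, mismatch, gap_open,
                        gap_extend, band_pad, hits);
        for (auto& h : hits) {
          if (h.len <= 0) continue;
          const double ident = (double)h.ident / (double)h.len;
          const double cov = (double)(h.q1 - h.q0) / (double)m;
          if (ident + 1e-12 < id_min || cov + 1e-12 < cov_min) continue;
          if (h.score > best.score ||
              (h.score == best.score && bg >= 0 && g < bg)) {
            best = h; bg = g; bstr = strand;
          } else if (bg < 0) { best = h; bg = g; bstr = strand; }
        }
      }
    }
    if (bg >= 0 && best.found) {
      int q0 = best.q0, q1 = best.q1;
      if (bstr == 1) { q0 = m - best.q1; q1 = m - best.q0; }
      o_read.push_back(r + 1); o_gen.push_back(bg + 1);
      o_q0.push_back(q0); o_q1.push_back(q1);
      o_s0.push_back(best.s0); o_s1.push_back(best.s1);
      o_len.push_back(best.len); o_id.push_back(best.ident);
      o_sc.push_back(best.score); o_str.push_back(bstr == 0 ? 1 : -1);
    }
  }
  return DataFrame::create(_["read"] = o_read, _["genome"] = o_gen,
                           _["q_start"] = o_q0, _["q_end"] = o_q1,
                           _["s_start"] = o_s0, _["s_end"] = o_s1,
                           _["length"] = o_len, _["identities"] = o_id,
                           _["score"] = o_sc, _["strand"] = o_str);
}

// ---------------------------------------------------------------------------
// All-vs-all protein search with an exact word prefilter: pairs sharing no
// word of size `word` are never aligned. Returns all computed hits; the
// caller applies identity/E-value thresholds.
// ---------------------------------------------------------------------------
static void protein_words(const std::string& s, int word,
                          std::unordered_set<uint64_t>& out) {
  const int n = (int)s.size();
  for (int i = 0; i + word <= n; ++i) {
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < word; ++j) {
      char c = s[i + j];
      if (c < 'A' || c > 'Z') { ok = false; break; }
      code = code * 27 + (uint64_t)(c - 'A');
    }
    if (ok) out.insert(code);
  }
}

// [[Rcpp::export]]
DataFrame cpp_allvsall_protein(CharacterVector A, CharacterVector B,
                               bool self, int word, int min_word_hits,
                               IntegerMatrix sub128,
                               int gap_open, int gap_extend) {
  const int na = A.size(), nb = B.size();
  std::vector<std::string> as_(na), bs(nb);
  for (int i = 0; i < na; ++i) as_[i] = as<std::string>(A[i]);
  for (int j = 0; j < nb; ++j) bs[j] = as<std::string>(B[j]);
  // word -> list of B indices
  std::unordered_map<uint64_t, std::vector<int> > windex;
  for (int j = 0; j < nb; ++j) {
    std::unordered_set<uint64_t> w;
    protein_words(bs[j], word, w);
    for (uint64_t c : w) windex[c].push_back(j);
  }
  std::vector<int> o_i, o_j, o_sc, o_q0, o_q1, o_s0, o_s1, o_len, o_id;
  std::vector<int> cand(nb, 0);
  SwWork wk;
  for (int i = 0; i < na; ++i) {
    std::fill(cand.begin(), cand.end(), 0);
    std::unordered_set<uint64_t> w;
    protein_words(as_[i], word, w);
    for (uint64_t c : w) {
      auto it = windex.find(c);
      if (it == windex.end()) continue;
      for (int j : it->second) ++cand[j];  // distinct shared words
    }
    for (int j = 0; j < nb; ++j) {
      if (cand[j] < min_word_hits) continue;
      if (self && j <= i) continue;
      AlnStats st;
      sw_full(as_[i], bs[j], sub128.begin(), gap_open, gap_extend, st, wk);
      if (!st.found) continue;
      o_i.push_back(i + 1); o_j.push_back(j + 1); o_sc.push_back(st.score);
      o_q0.push_back(st.q0); o_q1.push_back(st.q1);
      o_s0.push_back(st.s0); o_s1.push_back(st.s1);
      o_len.push_back(st.len); o_id.push_back(st.ident);
    }
  }
  return DataFrame::create(_["i"] = o_i, _["j"] = o_j, _["score"] = o_sc,
                           _["q_start"] = o_q0, _["q_end"] = o_q1,
                           _["s_start"] = o_s0, _["s_end"] = o_s1,
                           _["length"] = o_len, _["identities"] = o_id);
}
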