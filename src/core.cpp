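// Alignment and simulation kernels.
//
// All stochastic functions draw from R's RNG stream (via Rcpp's RNGScope),
// so set.seed() on the R side makes them reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = -1000000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_char(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Banded overlap (end-gap-free global) alignment.
//
// Unit scores: match +1, mismatch -1, gap -2.  End gaps in either sequence
// are free and their columns are not counted, so identity is
// matches / aligned columns over the traceback path -- the vsearch-style
// definition with terminal gaps excluded.
// ---------------------------------------------------------------------------

struct AlnStats {
  int score, matches, columns;
  int a0, a1, b0, b1; // half-open aligned spans
};

// True global (Needleman-Wunsch) banded alignment; terminal gap runs are
// penalized in the score but excluded from the identity columns, matching
// vsearch's iddef 2 identity on its global alignments.
static bool overlap_align(const std::string &a, const std::string &b,
                          int band, AlnStats &st,
                          int mat = 2, int mis = -4, int gap = -16) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) return false;
  band = std::max(band, std::abs(la - lb) + 2);
  std::vector<int> H((size_t)(la + 1) * (lb + 1), NEG_INF);
  std::vector<signed char> T((size_t)(la + 1) * (lb + 1), 0); // 1 diag 2 up 3 left 0 start
  const int W = lb + 1;
  for (int j = 0; j <= std::min(lb, band); ++j) { H[j] = gap * j; T[j] = 3; }
  for (int i = 0; i <= std::min(la, band); ++i) {
    H[(size_t)i * W] = gap * i;
    T[(size_t)i * W] = 2;
  }
  T[0] = 0;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(lb, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      size_t idx = (size_t)i * W + j;
      int diag = H[idx - W - 1];
      int sc = (diag == NEG_INF) ? NEG_INF
        : diag + (a[i - 1] == b[j - 1] ? mat : mis);
      signed char tb = 1;
      int up = H[idx - W];
      if (up != NEG_INF && up + gap > sc) { sc = up + gap; tb = 2; }
      int left = H[idx - 1];
      if (left != NEG_INF && left + gap > sc) { sc = left + gap; tb = 3; }
      H[idx] = sc;
      T[idx] = (sc == NEG_INF) ? 0 : tb;
    }
  }
  int best = H[(size_t)la * W + lb];
  if (best == NEG_INF) return false;
  st.score = best; st.a1 = la; st.b1 = lb;
  // collect the path, then drop terminal gap runs from the identity count
  std::vector<signed char> path;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    signed char tb = T[(size_t)i * W + j];
    if (tb == 0) break;
    path.push_back(tb);
    if (tb == 1) { --i; --j; }
    else if (tb == 2) --i;
    else --j;
  }
  st.a0 = i; st.b0 = j;
  // path is stored end-to-start; trim gap runs at both ends
  size_t lo = 0, hi = path.size();
  while (hi > lo && path[hi - 1] != 1) --hi; // start of alignment
  while (lo < hi && path[lo] != 1) ++lo;     // end of alignment
  int matches = 0, columns = 0;
  int ai = la, bj = lb;
  for (size_t k = 0; k < path.size(); ++k) {
    bool inside = (k >= lo && k < hi);
    if (path[k] == 1) {
      if (inside) {
        ++columns;
        if (a[ai - 1] == b[bj - 1]) ++matches;
      }
      --ai; --bj;
    } else if (path[k] == 2) {
      if (inside) ++columns;
      --ai;
    } else {
      if (inside) ++columns;
      --bj;
    }
  }
  st.matches = matches; st.columns = columns;
  return true;
}

static int band_width(size_t la, size_t lb, double band_frac) {
  int b = (int)std::ceil(band_frac * (double)std::max(la, lb));
  return std::max(8, b);
}

// [[Rcpp::export]]
double cpp_identity(std::string a, std::string b, double band_frac = 0.2) {
  AlnStats st;
  if (!overlap_align(a, b, band_width(a.size(), b.size(), band_frac), st))
    return 0.0;
  if (st.columns == 0) return 0.0;
  return (double)st.matches / (double)st.columns;
}

// Greedy length-sorted, first-match clustering (vsearch cluster_fast
// emulation).  `seqs` must already be sorted (decreasing length, ties
// lexicographic); returns 1-based cluster ids, centroids are the first
// member of each cluster.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double t,
                                 double band_frac = 0.2) {
  int n = seqs.size();
  IntegerVector cl(n);
  std::vector<std::string> centroids;
  std::vector<int> centroid_cl;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int assigned = 0;
    for (size_t c = 0; c < centroids.size(); ++c) {
      AlnStats st;
      int band = band_width(s.size(), centroids[c].size(), band_frac);
      if (overlap_align(s, centroids[c], band, st) && st.columns > 0 &&
          (double)st.matches / (double)st.columns >= t) {
        assigned = centroid_cl[c];
        break;
      }
    }
    if (!assigned) {
      centroids.push_back(s);
      assigned = (int)centroids.size();
      centroid_cl.push_back(assigned);
    }
    cl[i] = assigned;
  }
  return cl;
}

// Star-alignment consensus: members are aligned to the centroid and their
// bases projected onto centroid columns; per column majority wins, ties go
// to the centroid base, a winning deletion drops the column.
// [[Rcpp::export]]
std::string cpp_consensus(std::string centroid, CharacterVector members,
                          double band_frac = 0.2) {
  int L = (int)centroid.size();
  std::vector<std::array<int, 5>> votes((size_t)L, {0, 0, 0, 0, 0}); // A C G T -
  for (int m = 0; m < members.size(); ++m) {
    std::string s = as<std::string>(members[m]);
    AlnStats st;
    int band = band_width(s.size(), centroid.size(), band_frac);
    if (!overlap_align(s, centroid, band, st)) continue;
    // redo traceback to project member bases on centroid positions
    // (cheap: realign storing projection)
    const int la = (int)s.size(), lb = L;
    int bw = std::max(band, std::abs(la - lb) + 2);
    std::vector<int> H((size_t)(la + 1) * (lb + 1), NEG_INF);
    std::vector<signed char> T((size_t)(la + 1) * (lb + 1), 0);
    const int W = lb + 1;
    for (int j = 0; j <= std::min(lb, bw); ++j) H[j] = 0;
    for (int i = 0; i <= std::min(la, bw); ++i) H[(size_t)i * W] = 0;
    for (int i = 1; i <= la; ++i) {
      int jlo = std::max(1, i - bw), jhi = std::min(lb, i + bw);
      for (int j = jlo; j <= jhi; ++j) {
        size_t idx = (size_t)i * W + j;
        int diag = H[idx - W - 1];
        int sc = (diag == NEG_INF) ? NEG_INF
          : diag + (s[i - 1] == centroid[j - 1] ? 1 : -1);
        signed char tb = 1;
        int up = H[idx - W];
        if (up != NEG_INF && up - 2 > sc) { sc = up - 2; tb = 2; }
        int left = H[idx - 1];
        if (left != NEG_INF && left - 2 > sc) { sc = left - 2; tb = 3; }
        H[idx] = sc; T[idx] = (sc == NEG_INF) ? 0 : tb;
      }
    }
    int best = NEG_INF, bi = -1, bj = -1;
    for (int j = 0; j <= lb; ++j)
      if (H[(size_t)la * W + j] > best) { best = H[(size_t)la * W + j]; bi = la; bj = j; }
    for (int i = 0; i <= la; ++i)
      if (H[(size_t)i * W + lb] > best) { best = H[(size_t)i * W + lb]; bi = i; bj = lb; }
    if (best == NEG_INF) continue;
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
      signed char tb = T[(size_t)i * W + j];
      if (tb == 0) break;
      if (tb == 1) {
        int c = base_code(s[i - 1]);
        if (c >= 0) votes[j - 1][c]++;
        --i; --j;
      } else if (tb == 2) {
        --i; // insertion in member: ignored
      } else {
        votes[j - 1][4]++; // deletion in member
        --j;
      }
    }
  }
  std::string out;
  out.reserve(L);
  static const char *BASES = "ACGT-";
  for (int j = 0; j < L; ++j) {
    int tot = 0, bestc = -1, bestv = 0;
    bool tie = false;
    for (int c = 0; c < 5; ++c) {
      tot += votes[j][c];
      if (votes[j][c] > bestv) { bestv = votes[j][c]; bestc = c; tie = false; }
      else if (votes[j][c] == bestv && votes[j][c] > 0) tie = true;
    }
    char ch;
    if (tot == 0 || tie || bestc < 0) ch = centroid[j];
    else ch = BASES[bestc];
    if (ch != '-') out.push_back(ch);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full Smith-Waterman local alignment (unit scores, gap -2); returns
// score, matches, columns and half-open aligned spans on both sequences.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_local_align(std::string a, std::string b) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int> H((size_t)(la + 1) * (lb + 1), 0);
  std::vector<signed char> T((size_t)(la + 1) * (lb + 1), 0);
  const int W = lb + 1;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      size_t idx = (size_t)i * W + j;
      int sc = H[idx - W - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
      signed char tb = 1;
      if (H[idx - W] - 2 > sc) { sc = H[idx - W] - 2; tb = 2; }
      if (H[idx - 1] - 2 > sc) { sc = H[idx - 1] - 2; tb = 3; }
      if (sc <= 0) { sc = 0; tb = 0; }
      H[idx] = sc; T[idx] = tb;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, columns = 0;
  while (i > 0 && j > 0 && T[(size_t)i * W + j] != 0) {
    signed char tb = T[(size_t)i * W + j];
    if (tb == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (tb == 2) --i;
    else --j;
    ++columns;
  }
  return NumericVector::create(
    _["score"] = best, _["matches"] = matches, _["columns"] = columns,
    _["a_start"] = i, _["a_end"] = bi, _["b_start"] = j, _["b_end"] = bj);
}

// ---------------------------------------------------------------------------
// k-mer machinery
// ---------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> KmerIndex;

static void index_sequence(const std::string &s, int id, int k, KmerIndex &idx) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int p = 0; p < n; ++p) {
    int c = base_code(s[p]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) idx[key].push_back({(int32_t)id, (int32_t)(p - k + 1)});
  }
}

// Membership screen: does each of `seqs` share an exact k-mer (either
// strand) with any of `refs`?  Returns the 1-based index of the most
// frequently hit reference (0 = no hit).
// [[Rcpp::export]]
IntegerVector cpp_kmer_screen(CharacterVector seqs, CharacterVector refs,
                              int k = 16, int stride = 2) {
  KmerIndex idx;
  for (int r = 0; r < refs.size(); ++r) {
    std::string s = as<std::string>(refs[r]);
    index_sequence(s, r + 1, k, idx);
    index_sequence(revcomp(s), r + 1, k, idx);
  }
  int n = seqs.size();
  IntegerVector out(n);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    std::unordered_map<int, int> hits;
    if (L >= k) {
      for (int p = 0; p + k <= L; p += stride) {
        uint64_t key = 0;
        bool ok = true;
        for (int q = 0; q < k; ++q) {
          int c = base_code(s[p + q]);
          if (c < 0) { ok = false; break; }
          key = ((key << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it != idx.end())
          for (size_t h = 0; h < it->second.size(); ++h)
            hits[it->second[h].first]++;
      }
    }
    int bestr = 0, bestv = 0;
    for (std::unordered_map<int, int>::iterator it = hits.begin(); it != hits.end(); ++it)
      if (it->second > bestv) { bestv = it->second; bestr = it->first; }
    out[i] = bestr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed-and-extend read mapper.
//
// Candidate contigs are found via exact k-mer seeds on both strands; each
// candidate diagonal cluster is scored by a banded alignment that is global
// in the read and free in the contig window (match +1, mismatch -1, gap -2).
// map_class: 1 unique, 2 multi, 0 unmapped (best score < min_frac * readlen).
// Per-base aligned pairs are emitted for unique reads only.
// ---------------------------------------------------------------------------

struct GlocalResult {
  int score;
  int c_start, c_end; // on contig, half-open
  // pairs
  std::vector<int> rpos, cpos; // read offset (in aligned orientation), contig pos
  int nm;
};

// Banded alignment of a read against a contig window: global in the read
// (so terminal mismatches such as deamination damage stay aligned), free
// in the contig, with read overhangs soft-clipped for free only where the
// window touches a physical contig boundary -- short catalog contigs are
// routinely shorter than the insert, so reads run off their ends.
static bool glocal_align(const std::string &read, const std::string &contig,
                         int diag, int band, GlocalResult &res, bool traceback) {
  const int m = (int)read.size();
  const int clen = (int)contig.size();
  int ws = std::max(0, diag - band);
  int we = std::min(clen, diag + m + band);
  int n = we - ws;
  if (n <= 0) return false;
  const bool free_left = (ws == 0), free_right = (we == clen);
  int center = diag - ws;
  std::vector<int> H((size_t)(m + 1) * (n + 1), NEG_INF);
  std::vector<signed char> T((size_t)(m + 1) * (n + 1), 0);
  const int W = n + 1;
  for (int j = 0; j <= n; ++j) H[j] = 0; // free leading contig gap
  for (int i = 1; i <= m; ++i) {
    size_t idx0 = (size_t)i * W;
    H[idx0] = free_left ? 0 : -2 * i; // leading read bases: clip or gap
    int jlo = std::max(1, i + center - band), jhi = std::min(n, i + center + band);
    for (int j = jlo; j <= jhi; ++j) {
      size_t idx = idx0 + j;
      int diagv = H[idx - W - 1];
      int sc = (diagv == NEG_INF) ? NEG_INF
        : diagv + (read[i - 1] == contig[ws + j - 1] ? 1 : -1);
      signed char tb = 1;
      int up = H[idx - W];
      if (up != NEG_INF && up - 2 > sc) { sc = up - 2; tb = 2; }
      int left = H[idx - 1];
      if (left != NEG_INF && left - 2 > sc) { sc = left - 2; tb = 3; }
      H[idx] = sc; T[idx] = (sc == NEG_INF) ? 0 : tb;
    }
  }
  int best = NEG_INF, bi = m, bj = -1;
  for (int j = 0; j <= n; ++j) {
    int v = H[(size_t)m * W + j];
    if (v > best) { best = v; bi = m; bj = j; }
  }
  if (free_right) {
    for (int i = 0; i <= m; ++i) {
      int v = H[(size_t)i * W + n];
      if (v > best) { best = v; bi = i; bj = n; }
    }
  }
  if (best == NEG_INF) return false;
  res.score = best;
  res.c_end = ws + bj;
  if (!traceback) return true;
  res.rpos.clear(); res.cpos.clear(); res.nm = 0;
  int i = bi, j = bj;
  while (i > 0) {
    if (j == 0) {
      if (free_left) break; // clipped read prefix
      --i; res.nm++; continue; // penalized leading read gap
    }
    signed char tb = T[(size_t)i * W + j];
    if (tb == 1) {
      res.rpos.push_back(i - 1);
      res.cpos.push_back(ws + j - 1);
      if (read[i - 1] != contig[ws + j - 1]) res.nm++;
      --i; --j;
    } else if (tb == 2) { res.nm++; --i; }
    else if (tb == 3) { res.nm++; --j; }
    else { --i; }
  }
  res.c_start = ws + j;
  std::reverse(res.rpos.begin(), res.rpos.end());
  std::reverse(res.cpos.begin(), res.cpos.end());
  return true;
}

struct Candidate { int contig, strand, diag; };

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector seqs, List quals, CharacterVector contigs,
                   int k = 15, int score_margin = 4, int band = 12,
                   double min_score_frac = 0.5, int stride = 5,
                   int debug_read = 0) {
  const int nr = seqs.size(), nc = contigs.size();
  std::vector<std::string> ctg(nc);
  KmerIndex idx;
  for (int c = 0; c < nc; ++c) {
    ctg[c] = as<std::string>(contigs[c]);
    index_sequence(ctg[c], c, k, idx);
  }
  IntegerVector r_contig(nr), r_start(nr), r_end(nr), r_score(nr),
    r_second(nr), r_class(nr), r_nm(nr), r_strand(nr);
  std::vector<int> p_read, p_cpos, p_rbase, p_refbase, p_qual, p_roff5;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(seqs[i]);
    const int m = (int)fwd.size();
    IntegerVector qv = quals[i];
    std::vector<Candidate> cands;
    std::string oriented[2];
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = (strand == 0) ? fwd : (oriented[1] = revcomp(fwd));
      if (strand == 0) oriented[0] = fwd;
      if (m < k) continue;
      // collect (contig, diag) hits
      std::unordered_map<int64_t, int> diag_hits;
      for (int p = 0; p + k <= m; p += stride) {
        uint64_t key = 0; bool ok = true;
        for (int q = 0; q < k; ++q) {
          int c = base_code(s[p + q]);
          if (c < 0) { ok = false; break; }
          key = ((key << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        if (it->second.size() > 64) continue; // over-represented seed
        for (size_t h = 0; h < it->second.size(); ++h) {
          int cidx = it->second[h].first;
          int diag = it->second[h].second - p;
          diag_hits[((int64_t)cidx << 32) | (uint32_t)(diag + (1 << 30))]++;
        }
      }
      // cluster diagonals per contig within +-band
      std::vector<std::pair<int, int>> dh; // (contig, diag)
      for (std::unordered_map<int64_t, int>::iterator it = diag_hits.begin();
           it != diag_hits.end(); ++it) {
        int cidx = (int)(it->first >> 32);
        int diag = (int)((uint32_t)(it->first & 0xffffffffULL)) - (1 << 30);
        dh.push_back({cidx, diag});
      }
      std::sort(dh.begin(), dh.end());
      for (size_t h = 0; h < dh.size(); ++h) {
        if (h > 0 && dh[h].first == dh[h - 1].first &&
            dh[h].second - dh[h - 1].second <= band)
          continue; // same diagonal cluster
        Candidate cd; cd.contig = dh[h].first; cd.strand = strand; cd.diag = dh[h].second;
        cands.push_back(cd);
      }
    }
    int best = NEG_INF, second = NEG_INF, bestc = -1;
    for (size_t cd = 0; cd < cands.size(); ++cd) {
      GlocalResult gr;
      if (!glocal_align(oriented[cands[cd].strand], ctg[cands[cd].contig],
                        cands[cd].diag, band, gr, false))
        continue;
      if (debug_read == i + 1)
        Rcpp::Rcout << "cand contig=" << cands[cd].contig + 1
                    << " strand=" << cands[cd].strand
                    << " diag=" << cands[cd].diag
                    << " score=" << gr.score << "\n";
      if (gr.score > best) { second = best; best = gr.score; bestc = (int)cd; }
      else if (gr.score > second) second = gr.score;
    }
    if (bestc < 0 || best < min_score_frac * m) {
      r_class[i] = 0; r_contig[i] = 0;
      continue;
    }
    bool unique = (second == NEG_INF) || (best - second >= score_margin);
    r_class[i] = unique ? 1 : 2;
    Candidate &cb = cands[bestc];
    GlocalResult gr;
    glocal_align(oriented[cb.strand], ctg[cb.contig], cb.diag, band, gr, true);
    r_contig[i] = cb.contig + 1;
    r_strand[i] = cb.strand == 0 ? 1 : -1;
    r_start[i] = gr.c_start; r_end[i] = gr.c_end;
    r_score[i] = best; r_second[i] = (second == NEG_INF) ? NA_INTEGER : second;
    r_nm[i] = gr.nm;
    if (unique) {
      const std::string &s = oriented[cb.strand];
      const std::string &cg = ctg[cb.contig];
      for (size_t p = 0; p < gr.rpos.size(); ++p) {
        int rp = gr.rpos[p]; // position in aligned orientation
        int orig = (cb.strand == 0) ? rp : (m - 1 - rp);
        p_read.push_back(i + 1);
        p_cpos.push_back(gr.cpos[p]);
        p_rbase.push_back(base_code(s[rp]));
        p_refbase.push_back(base_code(cg[gr.cpos[p]]));
        p_qual.push_back(qv[orig]);
        p_roff5.push_back(orig);
      }
    }
  }
  return List::create(
    _["contig"] = r_contig, _["strand"] = r_strand, _["start"] = r_start,
    _["end"] = r_end, _["score"] = r_score, _["second"] = r_second,
    _["map_class"] = r_class, _["nm"] = r_nm,
    _["pair_read"] = wrap(p_read), _["pair_cpos"] = wrap(p_cpos),
    _["pair_rbase"] = wrap(p_rbase), _["pair_refbase"] = wrap(p_refbase),
    _["pair_qual"] = wrap(p_qual), _["pair_roff5"] = wrap(p_roff5));
}

// ---------------------------------------------------------------------------
// Ungapped end-overlap detection for contig extension.
// side = 1 (right end): read prefix vs contig suffix, overhang = read suffix.
// side = 0 (left end): read suffix vs contig prefix, overhang = read prefix.
// Returns, per read, the longest overlap length with identity >=
// min_identity (0 if none reaches min_overlap).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_best_overlap(std::string contig, CharacterVector reads,
                               int min_overlap, double min_identity, int side) {
  const int cl = (int)contig.size();
  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    const int rl = (int)r.size();
    int maxo = std::min(rl, cl);
    int found = 0;
    for (int o = maxo; o >= min_overlap; --o) {
      int allowed = (int)std::floor((1.0 - min_identity) * o + 1e-9);
      int mm = 0;
      bool ok = true;
      if (side == 1) {
        for (int p = 0; p < o; ++p)
          if (r[p] != contig[cl - o + p] && ++mm > allowed) { ok = false; break; }
      } else {
        for (int p = 0; p < o; ++p)
          if (r[rl - o + p] != contig[p] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { found = o; break; }
    }
    out[i] = found;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Library simulation helpers
// ---------------------------------------------------------------------------

// Post-mortem deamination: C->T with prob p_max*rho^i from the 5' end,
// G->A with prob p_max*rho^j from the 3' end.  Returns damaged sequences
// and 0-based damaged offsets.
// [[Rcpp::export]]
List cpp_apply_damage(CharacterVector seqs, double p_max, double rho) {
  int n = seqs.size();
  CharacterVector out(n);
  List pos(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int L = (int)s.size();
    std::vector<int> dmg;
    double p5 = p_max;
    for (int p = 0; p < L; ++p) {
      if (s[p] == 'C' && p5 > 0 && unif_rand() < p5) {
        s[p] = 'T'; dmg.push_back(p);
      }
      p5 *= rho;
      if (p5 < 1e-12) break;
    }
    double p3 = p_max;
    for (int p = L - 1; p >= 0; --p) {
      if (s[p] == 'G' && p3 > 0 && unif_rand() < p3) {
        s[p] = 'A'; dmg.push_back(p);
      }
      p3 *= rho;
      if (p3 < 1e-12) break;
    }
    std::sort(dmg.begin(), dmg.end());
    out[i] = s;
    pos[i] = wrap(dmg);
  }
  return List::create(_["seq"] = out, _["positions"] = pos);
}

// i.i.d. substitution sequencing errors at rate e.
// [[Rcpp::export]]
List cpp_point_errors(CharacterVector seqs, double e) {
  static const char *B = "ACGT";
  int n = seqs.size();
  CharacterVector out(n);
  IntegerVector nerr(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int cnt = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < e) {
        int c = base_code(s[p]);
        if (c < 0) continue;
        int nb = (c + 1 + (int)(unif_rand() * 3)) % 4;
        s[p] = B[nb];
        ++cnt;
      }
    }
    out[i] = s; nerr[i] = cnt;
  }
  return List::create(_["seq"] = out, _["n_err"] = nerr);
}

// Per-base PHRED qualities ~ round(Normal(mean_q, sd)) clamped to [2, 41],
// encoded PHRED+33.
// [[Rcpp::export]]
CharacterVector cpp_phred_strings(IntegerVector lens, double mean_q, double sd) {
  int n = lens.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    int L = lens[i];
    std::string s((size_t)L, '!');
    for (int p = 0; p < L; ++p) {
      int q = (int)std::lround(mean_q + sd * norm_rand());
      if (q < 2) q = 2;
      if (q > 41) q = 41;
      s[p] = (char)(q + 33);
    }
    out[i] = s;
  }
  return out;
}
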