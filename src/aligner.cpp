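#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: break;
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// Genome pair HSPs: exact k-mer seeds, ungapped X-drop extension.
// Match +1 / mismatch -2; blocks trimmed to their maximum-scoring extent.
// Indel-containing homology shows up as adjacent blocks on shifted diagonals;
// the similarity formula merges them by interval union.
// ---------------------------------------------------------------------------

struct Block { int qs, qe, ss, se, ident; bool minus; };

static void scan_strand(const std::string& a, const std::string& b,
                        int k, int xdrop, int min_len, bool minus,
                        std::vector<Block>& out) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la < k || lb < k) return;
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  std::unordered_map<uint32_t, std::vector<int>> index;
  index.reserve(la * 2);
  uint32_t h = 0; int run = 0;
  for (int i = 0; i < la; ++i) {
    int c = base_code(a[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      auto& v = index[h];
      if ((int)v.size() < 64) v.push_back(i - k + 1);
    }
  }
  std::unordered_map<long long, int> diag_end;  // diagonal -> covered end in b
  h = 0; run = 0;
  for (int j = 0; j < lb; ++j) {
    int c = base_code(b[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run < k) continue;
    auto it = index.find(h);
    if (it == index.end()) continue;
    int j0 = j - k + 1;
    for (int i0 : it->second) {
      long long d = (long long)i0 - j0;
      auto de = diag_end.find(d);
      if (de != diag_end.end() && de->second > j0) continue;
      // extend right from seed end
      int score = k, best = k;
      int i = i0 + k, jj = j0 + k;
      int bi = i, bj = jj;
      while (i < la && jj < lb) {
        score += (a[i] == b[jj] && base_code(a[i]) >= 0) ? 1 : -2;
        ++i; ++jj;
        if (score > best) { best = score; bi = i; bj = jj; }
        if (best - score > xdrop) break;
      }
      // extend left from seed start
      int score2 = 0, best2 = 0;
      int li = i0, lj = j0, bli = i0, blj = j0;
      while (li > 0 && lj > 0) {
        score2 += (a[li - 1] == b[lj - 1] && base_code(a[li - 1]) >= 0) ? 1 : -2;
        --li; --lj;
        if (score2 > best2) { best2 = score2; bli = li; blj = lj; }
        if (best2 - score2 > xdrop) break;
      }
      int qs = bli, qe = bi, ss = blj, se = bj;
      int ident = 0;
      for (int t = 0; t < qe - qs; ++t)
        if (a[qs + t] == b[ss + t] && base_code(a[qs + t]) >= 0) ++ident;
      diag_end[d] = se;
      if (qe - qs >= min_len && 3 * ident >= 2 * (qe - qs)) {
        Block blk; blk.qs = qs; blk.qe = qe; blk.ss = ss; blk.se = se;
        blk.ident = ident; blk.minus = minus;
        out.push_back(blk);
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
DataFrame cpp_hsp_blocks(std::string a, std::string b,
                         int k = 13, int xdrop = 50, int min_len = 20) {
  std::vector<Block> out;
  scan_strand(a, b, k, xdrop, min_len, false, out);
  std::string brc = revcomp_str(b);
  scan_strand(a, brc, k, xdrop, min_len, true, out);
  const int lb = (int)b.size();
  int n = (int)out.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), ident(n), alen(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = out[i].qs; qe[i] = out[i].qe;
    if (out[i].minus) { ss[i] = lb - out[i].se; se[i] = lb - out[i].ss; }
    else { ss[i] = out[i].ss; se[i] = out[i].se; }
    ident[i] = out[i].ident; alen[i] = out[i].qe - out[i].qs;
    strand[i] = out[i].minus ? "-" : "+";
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["strand"] = strand,
                           _["identical_positions"] = ident,
                           _["aligned_length"] = alen,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Protein all-vs-all: shared-kmer prefilter then affine Smith-Waterman.
// ---------------------------------------------------------------------------

static int sw_score(const std::vector<int>& x, const std::vector<int>& y,
                    const IntegerMatrix& S, int gap_open, int gap_ext) {
  const int m = (int)x.size(), n = (int)y.size();
  std::vector<int> H(n + 1, 0), E(n + 1, 0);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0, F = 0;
    for (int j = 1; j <= n; ++j) {
      int Hup = H[j];
      E[j] = std::max(E[j] - gap_ext, H[j] - gap_open - gap_ext);
      F = std::max(F - gap_ext, H[j - 1] - gap_open - gap_ext);
      int sc = (x[i - 1] >= 0 && y[j - 1] >= 0) ? S(x[i - 1], y[j - 1]) : -1;
      int h = Hdiag + sc;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      H[j] = h; Hdiag = Hup;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(rng = false)]]
DataFrame cpp_protein_hits(CharacterVector seqs, IntegerMatrix score_mat,
                           std::string alphabet, int gap_open = 11,
                           int gap_ext = 1, int kmer = 4,
                           int min_shared = 2, int min_score = 30) {
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    code[(unsigned char)alphabet[i]] = (int)i;
  const int np = seqs.size();
  std::vector<std::vector<int>> enc(np);
  for (int p = 0; p < np; ++p) {
    std::string s = as<std::string>(seqs[p]);
    enc[p].reserve(s.size());
    for (char c : s) enc[p].push_back(code[(unsigned char)c]);
  }
  // kmer -> sorted unique protein list
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  buckets.reserve(1 << 20);
  for (int p = 0; p < np; ++p) {
    const auto& e = enc[p];
    if ((int)e.size() < kmer) continue;
    std::vector<uint64_t> seen;
    for (size_t i = 0; i + kmer <= e.size(); ++i) {
      uint64_t hsh = 0; bool ok = true;
      for (int t = 0; t < kmer; ++t) {
        if (e[i + t] < 0 || e[i + t] >= 20) { ok = false; break; }
        hsh = hsh * 25u + (uint64_t)e[i + t];
      }
      if (!ok) continue;
      seen.push_back(hsh);
    }
    std::sort(seen.begin(), seen.end());
    seen.erase(std::unique(seen.begin(), seen.end()), seen.end());
    for (uint64_t hsh : seen) {
      auto& v = buckets[hsh];
      if ((int)v.size() < 256) v.push_back(p);
    }
  }
  std::unordered_map<uint64_t, int> shared;
  shared.reserve(1 << 20);
  for (auto& kv : buckets) {
    const auto& v = kv.second;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y)
        ++shared[((uint64_t)v[x] << 32) | (uint64_t)v[y]];
  }
  std::vector<int> pi, pj, sc;
  for (auto& kv : shared) {
    if (kv.second < min_shared) continue;
    int i = (int)(kv.first >> 32), j = (int)(kv.first & 0xFFFFFFFFu);
    int s = sw_score(enc[i], enc[j], score_mat, gap_open, gap_ext);
    if (s >= min_score) { pi.push_back(i + 1); pj.push_back(j + 1); sc.push_back(s); }
  }
  return DataFrame::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                           _["score"] = wrap(sc));
}

// [[Rcpp::export(rng = false)]]
int cpp_sw_pair(std::string a, std::string b, IntegerMatrix score_mat,
                std::string alphabet, int gap_open = 11, int gap_ext = 1) {
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    code[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> x, y;
  for (char c : a) x.push_back(code[(unsigned char)c]);
  for (char c : b) y.push_back(code[(unsigned char)c]);
  return sw_score(x, y, score_mat, gap_open, gap_ext);
}

// ---------------------------------------------------------------------------
// Spacer matching: semi-global DP (spacer global, genome local) with unit
// costs; every gap column counts one effective mismatch. Candidates are all
// alignment end positions with cost <= cap; per-end traceback (preferring
// diagonal, then spacer-gap, then genome-gap) yields substitution and gap
// statistics plus the longest exact run.
// ---------------------------------------------------------------------------

struct Cand { int gs, ge, subs, gap_pos, max_event, longest_run; };

// traceback inside a DP matrix stored row-major ((m+1) x (w+1))
static Cand traceback(const std::vector<int>& dp, int m, int w,
                      const std::string& sp, const std::string& gw, int jend) {
  Cand c; c.subs = 0; c.gap_pos = 0; c.max_event = 0; c.longest_run = 0;
  int i = m, j = jend, run = 0, event = 0;
  int last = 0;  // 0 = diagonal/none, 1 = up (spacer gap), 2 = left (genome gap)
  while (i > 0) {
    int cur = dp[(size_t)i * (w + 1) + j];
    bool mm = true;
    if (j > 0) mm = !(sp[i - 1] == gw[j - 1] && base_code(sp[i - 1]) >= 0);
    bool can_diag = j > 0 &&
      cur == dp[(size_t)(i - 1) * (w + 1) + (j - 1)] + (mm ? 1 : 0);
    bool can_up = cur == dp[(size_t)(i - 1) * (w + 1) + j] + 1;
    bool can_left = j > 0 && cur == dp[(size_t)i * (w + 1) + (j - 1)] + 1;
    // prefer continuing an open gap (consolidates tied gap placements into
    // a single event), otherwise diagonal, then up, then left
    int move;
    if (last == 1 && can_up) move = 1;
    else if (last == 2 && can_left) move = 2;
    else if (can_diag) move = 0;
    else if (can_up) move = 1;
    else move = 2;
    if (move == 0) {
      if (mm) { ++c.subs; run = 0; }
      else { ++run; if (run > c.longest_run) c.longest_run = run; }
      if (event > c.max_event) c.max_event = event;
      event = 0;
      --i; --j;
    } else if (move == 1) {
      ++c.gap_pos; ++event; run = 0; --i;
    } else {
      ++c.gap_pos; ++event; run = 0; --j;
    }
    last = move;
    if (event > c.max_event) c.max_event = event;
  }
  c.gs = j; c.ge = jend;
  return c;
}

static void dp_candidates(const std::string& sp, const std::string& gw,
                          int cap, std::vector<Cand>& out) {
  const int m = (int)sp.size(), w = (int)gw.size();
  std::vector<int> dp((size_t)(m + 1) * (w + 1));
  for (int j = 0; j <= w; ++j) dp[j] = 0;  // free start in genome
  for (int i = 1; i <= m; ++i) {
    dp[(size_t)i * (w + 1)] = i;  // spacer prefix unmatched = gaps
    for (int j = 1; j <= w; ++j) {
      bool mm = !(sp[i - 1] == gw[j - 1] && base_code(sp[i - 1]) >= 0);
      int v = dp[(size_t)(i - 1) * (w + 1) + (j - 1)] + (mm ? 1 : 0);
      int u = dp[(size_t)(i - 1) * (w + 1) + j] + 1;
      int l = dp[(size_t)i * (w + 1) + (j - 1)] + 1;
      int best = v < u ? v : u;
      if (l < best) best = l;
      dp[(size_t)i * (w + 1) + j] = best;
    }
  }
  for (int j = 1; j <= w; ++j) {
    if (dp[(size_t)m * (w + 1) + j] <= cap) {
      Cand c = traceback(dp, m, w, sp, gw, j);
      out.push_back(c);
    }
  }
}

static DataFrame cands_to_df(const std::vector<Cand>& cc,
                             const std::vector<bool>& minus, int lg) {
  int n = (int)cc.size();
  IntegerVector gs(n), ge(n), subs(n), gp(n), me(n), lr(n), eff(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    if (minus[i]) { gs[i] = lg - cc[i].ge; ge[i] = lg - cc[i].gs; }
    else { gs[i] = cc[i].gs; ge[i] = cc[i].ge; }
    subs[i] = cc[i].subs; gp[i] = cc[i].gap_pos; me[i] = cc[i].max_event;
    lr[i] = cc[i].longest_run; eff[i] = cc[i].subs + cc[i].gap_pos;
    strand[i] = minus[i] ? "-" : "+";
  }
  return DataFrame::create(_["start"] = gs, _["end"] = ge,
                           _["strand"] = strand, _["substitutions"] = subs,
                           _["gap_positions"] = gp, _["max_gap_event"] = me,
                           _["longest_run"] = lr,
                           _["effective_mismatches"] = eff,
                           _["stringsAsFactors"] = false);
}

// Seeded route: exact word-length anchors locate windows, DP inside windows.
// [[Rcpp::export(rng = false)]]
DataFrame cpp_spacer_candidates(std::string spacer, std::string genome,
                                int word = 10, int cap = 20) {
  const int m = (int)spacer.size(), lg = (int)genome.size();
  std::vector<Cand> cc; std::vector<bool> mn;
  for (int strand = 0; strand < 2; ++strand) {
    std::string g = strand ? revcomp_str(genome) : genome;
    if ((int)g.size() < word || m < word) continue;
    // index genome words
    std::unordered_map<uint32_t, std::vector<int>> idx;
    const uint32_t mask = (word < 16) ? ((1u << (2 * word)) - 1u) : 0xFFFFFFFFu;
    uint32_t h = 0; int run = 0;
    for (int j = 0; j < (int)g.size(); ++j) {
      int c = base_code(g[j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask;
      if (++run >= word) idx[h].push_back(j - word + 1);
    }
    std::vector<std::pair<int,int>> windows;  // candidate [lo, hi)
    h = 0; run = 0;
    for (int i = 0; i < m; ++i) {
      int c = base_code(spacer[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask;
      if (++run < word) continue;
      int i0 = i - word + 1;
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      for (int j0 : it->second) {
        int lo = j0 - i0 - (cap + 2);
        int hi = j0 - i0 + m + (cap + 2);
        if (lo < 0) lo = 0;
        if (hi > (int)g.size()) hi = (int)g.size();
        windows.push_back(std::make_pair(lo, hi));
      }
    }
    std::sort(windows.begin(), windows.end());
    // merge overlapping windows
    std::vector<std::pair<int,int>> merged;
    for (auto& wd : windows) {
      if (!merged.empty() && wd.first <= merged.back().second)
        merged.back().second = std::max(merged.back().second, wd.second);
      else merged.push_back(wd);
    }
    for (auto& wd : merged) {
      std::string gw = g.substr(wd.first, wd.second - wd.first);
      std::vector<Cand> local;
      dp_candidates(spacer, gw, cap, local);
      for (auto& c : local) {
        c.gs += wd.first; c.ge += wd.first;
        cc.push_back(c); mn.push_back(strand == 1);
      }
    }
  }
  return cands_to_df(cc, mn, lg);
}

// Exhaustive route: full-genome DP on both strands (oracle).
// [[Rcpp::export(rng = false)]]
DataFrame cpp_spacer_scan(std::string spacer, std::string genome,
                          int cap = 20) {
  const int lg = (int)genome.size();
  std::vector<Cand> cc; std::vector<bool> mn;
  for (int strand = 0; strand < 2; ++strand) {
    std::string g = strand ? revcomp_str(genome) : genome;
    std::vector<Cand> local;
    dp_candidates(spacer, g, cap, local);
    for (auto& c : local) { cc.push_back(c); mn.push_back(strand == 1); }
  }
  return cands_to_df(cc, mn, lg);
}
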