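#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Watson-Crick + G:U wobble, DNA alphabet (U encoded as T)
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  }
  return false;
}

// pair class: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
static inline int pair_class(char s, char t) {
  switch (s) {
  case 'A': return t == 'T' ? 0 : 2;
  case 'T': return t == 'A' ? 0 : (t == 'G' ? 1 : 2);
  case 'G': return t == 'C' ? 0 : (t == 'T' ? 1 : 2);
  case 'C': return t == 'G' ? 0 : 2;
  }
  return 2;
}

// [[Rcpp::export]]
int nussinov_pairs_cpp(std::string seq, int min_loop) {
  int n = (int) seq.size();
  if (n < 2) return 0;
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = std::max(M[i + 1][j], M[i][j - 1]);
      if (can_pair(seq[i], seq[j]))
        best = std::max(best, (i + 1 <= j - 1 ? M[i + 1][j - 1] : 0) + 1);
      for (int k = i + 1; k < j; ++k)
        best = std::max(best, M[i][k] + M[k + 1][j]);
      M[i][j] = best;
    }
  }
  return M[0][n - 1];
}

// Best single stem-loop (no multiloop branching): V[i][j] maximizes
// pairs - lambda * (unpaired bases inside the stem span), the hairpin loop
// itself and the region outside the chosen span are free. Returns the span
// >= min_span maximizing 2*V/span, with the pair count of that structure.
// [[Rcpp::export]]
List stem_fold_cpp(std::string seq, int min_loop, double lambda, int min_span) {
  int n = (int) seq.size();
  std::vector< std::vector<double> > V(n, std::vector<double>(n, 0.0));
  std::vector< std::vector<int> > P(n, std::vector<int>(n, 0));
  for (int span = 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double v = 0.0; int p = 0;
      if (V[i + 1][j] - lambda > v) { v = V[i + 1][j] - lambda; p = P[i + 1][j]; }
      if (V[i][j - 1] - lambda > v) { v = V[i][j - 1] - lambda; p = P[i][j - 1]; }
      if (j - i > min_loop && can_pair(seq[i], seq[j])) {
        double vp = V[i + 1][j - 1] + 1.0;
        if (vp > v) { v = vp; p = P[i + 1][j - 1] + 1; }
      }
      V[i][j] = v; P[i][j] = p;
    }
  }
  double best_score = 0.0, best_v = 0.0;
  int bi = 0, bj = -1, bp = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_span - 1; j < n; ++j) {
      double sc = 2.0 * V[i][j] / (double)(j - i + 1);
      if (sc > best_score + 1e-12) {
        best_score = sc; bi = i; bj = j; bp = P[i][j]; best_v = V[i][j];
      }
    }
  }
  // traceback for the hairpin loop bounds (arm assignment)
  int li = bi, lj = bj;
  if (bj > bi) {
    int i = bi, j = bj;
    const double eps = 1e-9;
    while (j - i > 0) {
      if (j - i > min_loop && can_pair(seq[i], seq[j]) &&
          std::fabs(V[i][j] - (V[i + 1][j - 1] + 1.0)) < eps &&
          P[i][j] == P[i + 1][j - 1] + 1) { ++i; --j; continue; }
      if (std::fabs(V[i][j] - (V[i + 1][j] - lambda)) < eps &&
          P[i][j] == P[i + 1][j]) { ++i; continue; }
      if (std::fabs(V[i][j] - (V[i][j - 1] - lambda)) < eps &&
          P[i][j] == P[i][j - 1]) { --j; continue; }
      break;  // hairpin loop (value 0 region)
    }
    li = i; lj = j;
  }
  return List::create(
    _["score"] = best_score,
    _["value"] = best_v,
    _["pairs"] = bp,
    _["stem_start"] = bi + 1,
    _["stem_end"] = bj + 1,
    _["loop_start"] = li + 1,
    _["loop_end"] = lj + 1);
}

struct Cell { double cost; int move; int pi; int pbs; int pbt; };
// moves: 0 none, 1 pair, 2 srna bulge, 3 target bulge

// Minimum-penalty antisense alignment of an sRNA against a transcript with
// the alignment's 3'-most target base anchored at j1 (1-based). The sRNA is
// read 5'->3'; sRNA position 1 pairs target position j1, and the alignment
// walks upstream on the target. Positions in [core_lo, core_hi] (from the
// sRNA 5' end) carry core_mult-times penalties; bulges are forbidden
// opposite protected positions. If require_full, the alignment must consume
// target positions down to exactly j_low (window start).
static bool align_anchor(const std::string &s, const std::string &t, int j1,
                         double mism, double gu, double bulge,
                         int core_lo, int core_hi, double core_mult,
                         int max_bulges, int prot_lo, int prot_hi,
                         bool require_full, int j_low,
                         double &out_score, int &out_start, int &out_cleave,
                         std::string &out_pairing) {
  int m = (int) s.size();
  int B = max_bulges;
  // state: (i-1, bs, bt); i = next sRNA position (1..m+1)
  const double INF = 1e18;
  std::vector<Cell> dp((m + 1) * (B + 1) * (B + 1));
  auto idx = [&](int i, int bs, int bt) { return ((i - 1) * (B + 1) + bs) * (B + 1) + bt; };
  for (auto &c : dp) { c.cost = INF; c.move = 0; }
  dp[idx(1, 0, 0)].cost = 0.0;
  auto wt = [&](int i) { return (i >= core_lo && i <= core_hi) ? core_mult : 1.0; };
  for (int i = 1; i <= m; ++i) {
    for (int bs = 0; bs <= B; ++bs) {
      for (int bt = 0; bt <= B; ++bt) {
        Cell &cur = dp[idx(i, bs, bt)];
        if (cur.cost >= INF) continue;
        // target index paired next: consumed = (i-1-bs) + bt
        int j = j1 - ((i - 1 - bs) + bt);
        bool prot = (i >= prot_lo && i <= prot_hi);
        // pair / mismatch
        if (j >= 1 && j <= (int) t.size()) {
          int cls = pair_class(s[i - 1], t[j - 1]);
          double pen = (cls == 0 ? 0.0 : (cls == 1 ? gu : mism)) * wt(i);
          Cell &nx = dp[idx(i + 1, bs, bt)];
          if (cur.cost + pen < nx.cost) {
            nx.cost = cur.cost + pen; nx.move = 1; nx.pi = i; nx.pbs = bs; nx.pbt = bt;
          }
        }
        if (bs + bt < B && !prot) {
          // sRNA bulge: s[i] unpaired
          Cell &nx = dp[idx(i + 1, bs + 1, bt)];
          double pen = bulge * wt(i);
          if (cur.cost + pen < nx.cost) {
            nx.cost = cur.cost + pen; nx.move = 2; nx.pi = i; nx.pbs = bs; nx.pbt = bt;
          }
          // target bulge: t[j] unpaired (consumed with no sRNA partner)
          if (j >= 1 && j <= (int) t.size()) {
            Cell &nx2 = dp[idx(i, bs, bt + 1)];
            if (cur.cost + pen < nx2.cost) {
              nx2.cost = cur.cost + pen; nx2.move = 3; nx2.pi = i; nx2.pbs = bs; nx2.pbt = bt;
            }
          }
        }
      }
    }
  }
  double best = INF; int bbs = 0, bbt = 0;
  for (int bs = 0; bs <= B; ++bs) {
    for (int bt = 0; bt <= B; ++bt) {
      double c = dp[idx(m + 1, bs, bt)].cost;
      if (c >= INF) continue;
      int jend = j1 - ((m - bs) + bt);  // last consumed target pos - 1
      if (jend + 1 < 1) continue;
      if (require_full && jend != j_low - 1) continue;
      if (c < best) { best = c; bbs = bs; bbt = bt; }
    }
  }
  if (best >= INF) return false;
  // traceback
  std::string pairing(m, '?');
  int i = m + 1, bs = bbs, bt = bbt;
  int cleave = NA_INTEGER;
  while (!(i == 1 && bs == 0 && bt == 0)) {
    Cell &c = dp[idx(i, bs, bt)];
    int pi = c.pi, pbs = c.pbs, pbt = c.pbt;
    if (c.move == 1) {
      int j = j1 - ((pi - 1 - pbs) + pbt);
      int cls = pair_class(s[pi - 1], t[j - 1]);
      pairing[pi - 1] = (cls == 0 ? '|' : (cls == 1 ? 'o' : '.'));
      if (pi == 10) cleave = j;
      i = pi; bs = pbs; bt = pbt;
    } else if (c.move == 2) {
      pairing[pi - 1] = '-';
      i = pi; bs = pbs; bt = pbt;
    } else {  // target bulge
      i = pi; bs = pbs; bt = pbt;
    }
  }
  out_score = best;
  out_start = j1 - ((m - bbs) + bbt) + 1;
  out_cleave = cleave;
  out_pairing = pairing;
  return true;
}

// [[Rcpp::export]]
DataFrame target_scan_cpp(std::string srna, std::string tx,
                          double mism, double gu, double bulge,
                          int core_lo, int core_hi, double core_mult,
                          int max_bulges, int prot_lo, int prot_hi,
                          double cutoff) {
  int n = (int) tx.size(), m = (int) srna.size();
  std::vector<int> starts, ends, cleaves;
  std::vector<double> scores;
  std::vector<std::string> pairings;
  for (int j1 = m - max_bulges; j1 <= n; ++j1) {
    if (j1 < 1) continue;
    double sc; int st, cl; std::string pr;
    if (!align_anchor(srna, tx, j1, mism, gu, bulge, core_lo, core_hi,
                      core_mult, max_bulges, prot_lo, prot_hi,
                      false, 0, sc, st, cl, pr)) continue;
    if (sc <= cutoff + 1e-9) {
      starts.push_back(st); ends.push_back(j1); cleaves.push_back(cl);
      scores.push_back(sc); pairings.push_back(pr);
    }
  }
  return DataFrame::create(
    _["site_start"] = wrap(starts), _["site_end"] = wrap(ends),
    _["score"] = wrap(scores), _["cleavage_pos"] = wrap(cleaves),
    _["pairing"] = wrap(pairings), _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List score_window_cpp(std::string srna, std::string window,
                      double mism, double gu, double bulge,
                      int core_lo, int core_hi, double core_mult,
                      int max_bulges, int prot_lo, int prot_hi) {
  double sc; int st, cl; std::string pr;
  int j1 = (int) window.size();
  bool ok = align_anchor(srna, window, j1, mism, gu, bulge, core_lo, core_hi,
                         core_mult, max_bulges, prot_lo, prot_hi,
                         true, 1, sc, st, cl, pr);
  if (!ok) return List::create(_["score"] = R_PosInf);
  return List::create(_["score"] = sc, _["site_start"] = st,
                      _["site_end"] = j1, _["cleavage_pos"] = cl,
                      _["pairing"] = pr);
}

// ---- exact-match k-mer anchor index ----

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}
static inline char comp_base(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G';
               case 'G': return 'C'; case 'T': return 'A'; }
  return 'N';
}

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<uint64_t> offsets;  // cumulative start of each chrom
  std::unordered_multimap<uint64_t, uint64_t> table;  // kmer -> global pos
};

// [[Rcpp::export]]
SEXP kmer_index_build(CharacterVector names, CharacterVector seqs, int k) {
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  uint64_t off = 0;
  for (int c = 0; c < seqs.size(); ++c) {
    idx->names.push_back(as<std::string>(names[c]));
    idx->seqs.push_back(as<std::string>(seqs[c]));
    idx->offsets.push_back(off);
    const std::string &s = idx->seqs.back();
    int n = (int) s.size();
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) b) & mask;
      if (++valid >= k) idx->table.insert({key, off + (uint64_t)(i - k + 1)});
    }
    off += (uint64_t) n;
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
DataFrame kmer_index_map(SEXP xp, CharacterVector queries) {
  XPtr<KmerIndex> idx(xp);
  int k = idx->k;
  std::vector<int> out_q, out_start;
  std::vector<int> out_chrom;
  std::vector<bool> out_minus;
  int nc = (int) idx->seqs.size();
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int L = (int) q.size();
    if (L < k) continue;
    for (int pass = 0; pass < 2; ++pass) {
      std::string qq = q;
      if (pass == 1) {  // reverse complement
        std::string r(L, 'N');
        for (int i = 0; i < L; ++i) r[L - 1 - i] = comp_base(q[i]);
        qq = r;
      }
      uint64_t key = 0;
      bool ok = true;
      for (int i = 0; i < k; ++i) {
        int b = base2bits(qq[i]);
        if (b < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t) b;
      }
      if (!ok) continue;
      auto rng = idx->table.equal_range(key);
      for (auto it = rng.first; it != rng.second; ++it) {
        uint64_t gp = it->second;
        // locate chromosome
        int c = nc - 1;
        while (c > 0 && idx->offsets[c] > gp) --c;
        uint64_t pos = gp - idx->offsets[c];
        const std::string &s = idx->seqs[c];
        if (pos + (uint64_t) L > s.size()) continue;
        bool match = true;
        for (int i = k; i < L; ++i)
          if (s[pos + i] != qq[i]) { match = false; break; }
        if (!match) continue;
        out_q.push_back(qi + 1);
        out_chrom.push_back(c + 1);
        out_start.push_back((int) pos);
        out_minus.push_back(pass == 1);
      }
    }
  }
  return DataFrame::create(_["query"] = wrap(out_q),
                           _["chrom"] = wrap(out_chrom),
                           _["start"] = wrap(out_start),
                           _["minus"] = wrap(out_minus),
                           _["stringsAsFactors"] = false);
}
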