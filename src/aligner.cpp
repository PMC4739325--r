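// Seed-and-extend local DNA alignment with affine gaps.
//
// Scoring: +match per identical base, -mismatch per substitution, a gap of
// length L costs gap_open + L * gap_extend.  'N' never matches anything
// (scored as a mismatch), so low-complexity masked sequence cannot inflate
// identity.  Alignment requires at least one exact k-mer seed shared between
// the two sequences; seeds are chained by diagonal and each chained group is
// refined by banded affine dynamic programming with full traceback.  Inputs
// small enough for exact DP are refined over the full rectangle, so the
// result there equals the unrestricted Smith-Waterman affine-gap optimum.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

static inline std::vector<int8_t> encode_dna(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = 4; break;  // N and anything else
    }
  }
  return v;
}

struct Seed { int q, t; };          // 0-based start positions
struct Chain { int qlo, qhi, tlo, thi, dlo, dhi, nseeds; };

struct Aln {
  int q_start, q_end, t_start, t_end;   // 0-based half-open
  int score, matches, mismatches, gapcols;
  std::vector<std::pair<int,int>> ops;  // (op, len): 0=M 1=X 2=I(q only) 3=D(t only)
};

// Exact k-mer seeds between a (query) and b (target); k <= 15, 2-bit packed.
// Occurrences of a k-mer in the target are capped to keep repeats tractable.
static std::vector<Seed> find_seeds(const std::vector<int8_t>& a,
                                    const std::vector<int8_t>& b,
                                    int k, int max_occ) {
  std::vector<Seed> seeds;
  if ((int)a.size() < k || (int)b.size() < k) return seeds;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  std::unordered_map<uint32_t, std::vector<int>> idx;
  idx.reserve(b.size());
  {
    uint32_t h = 0; int run = 0;
    for (size_t i = 0; i < b.size(); ++i) {
      if (b[i] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)b[i]) & mask;
      if (++run >= k) {
        std::vector<int>& v = idx[h];
        if ((int)v.size() <= max_occ) v.push_back((int)(i + 1 - k));
      }
    }
  }
  uint32_t h = 0; int run = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] > 3) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)a[i]) & mask;
    if (++run >= k) {
      auto it = idx.find(h);
      if (it != idx.end() && (int)it->second.size() <= max_occ) {
        int q = (int)(i + 1 - k);
        for (int t : it->second) seeds.push_back({q, t});
      }
    }
  }
  return seeds;
}

// Greedy diagonal chaining: seeds sorted by query position are appended to
// the most recent chain whose end is nearby in query and on a close diagonal.
static std::vector<Chain> chain_seeds(std::vector<Seed>& seeds, int k,
                                      int max_qgap, int max_ddrift) {
  std::vector<Chain> chains;
  if (seeds.empty()) return chains;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    if (x.q != y.q) return x.q < y.q;
    return x.t < y.t;
  });
  for (const Seed& s : seeds) {
    int d = s.t - s.q;
    bool placed = false;
    // scan recent chains (bounded) for a compatible one
    int lo = std::max(0, (int)chains.size() - 64);
    for (int ci = (int)chains.size() - 1; ci >= lo; --ci) {
      Chain& c = chains[ci];
      if (s.q - c.qhi > max_qgap) continue;
      if (d >= c.dlo - max_ddrift && d <= c.dhi + max_ddrift &&
          s.t + k > c.tlo && s.q + k > c.qlo) {
        c.qhi = std::max(c.qhi, s.q + k);
        c.thi = std::max(c.thi, s.t + k);
        c.qlo = std::min(c.qlo, s.q);
        c.tlo = std::min(c.tlo, s.t);
        c.dlo = std::min(c.dlo, d);
        c.dhi = std::max(c.dhi, d);
        c.nseeds++;
        placed = true;
        break;
      }
    }
    if (!placed) chains.push_back({s.q, s.q + k, s.t, s.t + k, d, d, 1});
  }
  return chains;
}

// Banded affine local DP with traceback over rows [q0,q1) x cols [t0,t1),
// restricted to diagonals d = (t - t0) - (q - q0) in [dlo, dhi].
// Traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 up/I, 3 left/D),
// bit 2 E(up) extended, bit 3 F(left) extended.
static bool banded_sw(const std::vector<int8_t>& a, const std::vector<int8_t>& b,
                      int q0, int q1, int t0, int t1, int dlo, int dhi,
                      int match, int mismatch, int gap_open, int gap_extend,
                      double max_cells, Aln& out) {
  const int n = q1 - q0, m = t1 - t0;
  if (n <= 0 || m <= 0) return false;
  dlo = std::max(dlo, -(n - 1));
  dhi = std::min(dhi, m - 1);
  if (dlo > dhi) return false;
  const int W = dhi - dlo + 1;
  if ((double)(n + 1) * W > max_cells)
    stop("alignment subproblem too large (%d rows x %d band); increase banding limits", n, W);
  const int GO = gap_open + gap_extend;   // cost of opening a length-1 gap
  const int GE = gap_extend;

  // local index: for row i (1..n), column j maps to j - (i + dlo) in [0, W)
  std::vector<int> Hprev(W + 2, 0), Hcur(W + 2, 0), Eprev(W + 2, NEG_INF),
      Ecur(W + 2, NEG_INF), Fcur(W + 2, NEG_INF);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);
  int best = 0, bi = -1, bj = -1;

  // row 0: H = 0 in-band, E/F = -inf (handled by init)
  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    const int8_t ca = a[q0 + i - 1];
    const int jlo = std::max(1, i + dlo), jhi = std::min(m, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      const int l = j - (i + dlo);          // local index, 0..W-1
      // previous row local indices: same l is (i-1, j-1); l+1 is (i-1, j)
      const bool diag_ok = (j - 1 >= (i - 1) + dlo) && (j - 1 <= (i - 1) + dhi) && (j - 1 >= 0);
      const bool up_ok   = (j >= (i - 1) + dlo) && (j <= (i - 1) + dhi);
      const bool left_ok = (j - 1 >= i + dlo) && (j - 1 >= 1);
      uint8_t tbb = 0;
      // E: gap consuming query (vertical), from (i-1, j)
      int e = NEG_INF;
      if (up_ok && i >= 2) {
        int open_e = Hprev[l + 1] - GO;
        int ext_e = Eprev[l + 1] - GE;
        if (ext_e > open_e) { e = ext_e; tbb |= 4; } else e = open_e;
      } else if (up_ok) {
        e = Hprev[l + 1] - GO;
      }
      // F: gap consuming target (horizontal), from (i, j-1)
      int f = NEG_INF;
      if (left_ok) {
        int open_f = Hcur[l - 1] - GO;
        int ext_f = Fcur[l - 1] - GE;
        if (ext_f > open_f) { f = ext_f; tbb |= 8; } else f = open_f;
      }
      int dscore = NEG_INF;
      if (diag_ok) {
        const int8_t cb = b[t0 + j - 1];
        int s = (ca <= 3 && ca == cb) ? match : -mismatch;
        dscore = Hprev[l] + s;
      }
      int h = 0; uint8_t src = 0;
      if (dscore > h) { h = dscore; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[l] = h; Ecur[l] = e; Fcur[l] = f;
      tb[(size_t)i * W + l] = (uint8_t)(tbb | src);
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (best <= 0) return false;

  // traceback
  std::vector<int> rops;  // op per column, reversed
  int i = bi, j = bj;
  int state = 0;  // 0 = in H
  while (i > 0 && j > 0) {
    const int l = j - (i + dlo);
    if (l < 0 || l >= W) break;
    uint8_t t8 = tb[(size_t)i * W + l];
    if (state == 0) {
      uint8_t src = t8 & 3;
      if (src == 0) break;
      if (src == 1) {
        const int8_t ca = a[q0 + i - 1], cb = b[t0 + j - 1];
        rops.push_back((ca <= 3 && ca == cb) ? 0 : 1);
        --i; --j;
      } else if (src == 2) state = 2;
      else state = 3;
    } else if (state == 2) {        // E: vertical gap, consumes query
      rops.push_back(2);
      bool ext = (t8 & 4) != 0;
      --i;
      if (!ext) state = 0;
    } else {                        // F: horizontal gap, consumes target
      rops.push_back(3);
      bool ext = (t8 & 8) != 0;
      --j;
      if (!ext) state = 0;
    }
  }
  out.q_start = q0 + i; out.q_end = q0 + bi;
  out.t_start = t0 + j; out.t_end = t0 + bj;
  out.score = best;
  out.matches = out.mismatches = out.gapcols = 0;
  out.ops.clear();
  for (auto it = rops.rbegin(); it != rops.rend(); ++it) {
    int op = *it;
    if (op == 0) out.matches++;
    else if (op == 1) out.mismatches++;
    else out.gapcols++;
    if (!out.ops.empty() && out.ops.back().first == op) out.ops.back().second++;
    else out.ops.push_back({op, 1});
  }
  return true;
}

static std::vector<Aln> align_core(const std::string& qa, const std::string& qb,
                                   int match, int mismatch, int gap_open,
                                   int gap_extend, int k, int band,
                                   int full_dp_limit, int max_occ,
                                   int max_chains, double max_cells) {
  std::vector<Aln> result;
  std::vector<int8_t> a = encode_dna(qa), b = encode_dna(qb);
  if ((int)a.size() < k || (int)b.size() < k) return result;
  std::vector<Seed> seeds = find_seeds(a, b, k, max_occ);
  if (seeds.empty()) return result;

  std::vector<Aln> alns;
  if ((int)a.size() <= full_dp_limit && (int)b.size() <= full_dp_limit &&
      (double)(a.size() + 1) * (b.size() + 1) <= max_cells) {
    // exact: full rectangle
    Aln al;
    if (banded_sw(a, b, 0, (int)a.size(), 0, (int)b.size(),
                  -(int)a.size(), (int)b.size(), match, mismatch, gap_open,
                  gap_extend, max_cells * 4, al))
      alns.push_back(al);
  } else {
    // Seeds jumping more than half the DP band off a chain's diagonal range
    // start a new chain, so homologous blocks separated by a gap the affine
    // penalty would not bridge are refined (and reported) separately.
    std::vector<Chain> chains = chain_seeds(seeds, k, 500, band / 2);
    std::sort(chains.begin(), chains.end(), [](const Chain& x, const Chain& y) {
      if (x.nseeds != y.nseeds) return x.nseeds > y.nseeds;
      if (x.qlo != y.qlo) return x.qlo < y.qlo;
      return x.tlo < y.tlo;
    });
    if ((int)chains.size() > max_chains) chains.resize(max_chains);
    const int pad = 100;
    for (const Chain& c : chains) {
      int q0 = std::max(0, c.qlo - pad), q1 = std::min((int)a.size(), c.qhi + pad);
      int t0 = std::max(0, c.tlo - pad), t1 = std::min((int)b.size(), c.thi + pad);
      // chain diagonals are global d = t - q; convert to subrect diagonals
      int dlo = (c.dlo - band) - (t0 - q0);
      int dhi = (c.dhi + band) - (t0 - q0);
      Aln al;
      if ((double)(q1 - q0 + 1) * (t1 - t0 + 1) <= max_cells) {
        // small subproblem: solve exactly
        dlo = -(q1 - q0); dhi = t1 - t0;
      }
      if (banded_sw(a, b, q0, q1, t0, t1, dlo, dhi, match, mismatch,
                    gap_open, gap_extend, max_cells, al))
        alns.push_back(al);
    }
  }
  // keep non-overlapping alignments by descending score (ties: coordinates)
  std::sort(alns.begin(), alns.end(), [](const Aln& x, const Aln& y) {
    if (x.score != y.score) return x.score > y.score;
    if (x.q_start != y.q_start) return x.q_start < y.q_start;
    return x.t_start < y.t_start;
  });
  // Keep alignments greedily by score; a lower-scoring alignment is dropped
  // only when it substantially overlaps a kept one (small boundary overhangs
  // between adjacent local alignments are tolerated).
  for (const Aln& al : alns) {
    bool clash = false;
    int al_min = std::min(al.q_end - al.q_start, al.t_end - al.t_start);
    for (const Aln& kept : result) {
      int kept_min = std::min(kept.q_end - kept.q_start,
                              kept.t_end - kept.t_start);
      int tol = std::min(32, std::min(al_min, kept_min) / 4);
      int ovq = std::min(al.q_end, kept.q_end) - std::max(al.q_start, kept.q_start);
      int ovt = std::min(al.t_end, kept.t_end) - std::max(al.t_start, kept.t_start);
      if (ovq > tol || ovt > tol) { clash = true; break; }
    }
    if (!clash && al.score > 0) result.push_back(al);
  }
  return result;
}

static List aln_to_list(const Aln& al) {
  IntegerMatrix ops(al.ops.size(), 2);
  for (size_t r = 0; r < al.ops.size(); ++r) {
    ops(r, 0) = al.ops[r].first;
    ops(r, 1) = al.ops[r].second;
  }
  colnames(ops) = CharacterVector::create("op", "len");
  return List::create(
      _["q_start"] = al.q_start, _["q_end"] = al.q_end,
      _["t_start"] = al.t_start, _["t_end"] = al.t_end,
      _["score"] = al.score, _["matches"] = al.matches,
      _["mismatches"] = al.mismatches, _["gapcols"] = al.gapcols,
      _["ops"] = ops);
}

// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string a, std::string b, int match, int mismatch,
                     int gap_open, int gap_extend, int k, int band,
                     int full_dp_limit, int max_occ, int max_chains,
                     double max_cells) {
  std::vector<Aln> alns = align_core(a, b, match, mismatch, gap_open,
                                     gap_extend, k, band, full_dp_limit,
                                     max_occ, max_chains, max_cells);
  List out(alns.size());
  for (size_t i = 0; i < alns.size(); ++i) out[i] = aln_to_list(alns[i]);
  return out;
}

// Batched top-score computation (used for empirical nulls): returns the best
// local alignment score of `a` against each target, 0 when no alignment.
// [[Rcpp::export(name = ".cpp_top_scores")]]
NumericVector cpp_top_scores(std::string a, List targets, int match,
                             int mismatch, int gap_open, int gap_extend,
                             int k, int band, int full_dp_limit, int max_occ,
                             int max_chains, double max_cells) {
  NumericVector out(targets.size());
  for (R_xlen_t i = 0; i < targets.size(); ++i) {
    std::string b = as<std::string>(targets[i]);
    std::vector<Aln> alns = align_core(a, b, match, mismatch, gap_open,
                                       gap_extend, k, band, full_dp_limit,
                                       max_occ, max_chains, max_cells);
    out[i] = alns.empty() ? 0.0 : (double)alns[0].score;
  }
  return out;
}
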