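// Haplotype-chain engine: per-chain optimal epigenotype sequences via a
// constrained Viterbi DP over the six-state alphabet, and the
// coordinate-ascent optimizer over read partitions and strand assignments.
//
// State conventions shared with the R layer:
//   bases/nucleotides: A=0 C=1 G=2 T=3 N=4
//   epigenotypes:      A=0 C=1 G=2 T=3 meC=4 meG=5
// Strand: fwd=0, rev=1.  All positions window-relative 0-based internally.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double NEG = -1e18;

// Internal DP states.  Methylation is only representable as a paired
// dinucleotide: meC opening a CpG pair (Mo) must be followed by meG
// closing it (Wc); in NOMe mode meG may also open a GpC pair (Wo) closed
// by meC (Mc).  This encodes strand compatibility: a methylated site is
// methylated on both strands or neither.
//   0..3 plain A,C,G,T; 4 Mo; 5 Wc; 6 Wo; 7 Mc
static const int SG6[8] = {0, 1, 2, 3, 4, 5, 5, 4};  // state -> epigenotype
static const int PROJ[8] = {0, 1, 2, 3, 1, 2, 2, 1}; // state -> nucleotide

struct Unit {
  std::vector<int> pos;   // window-relative, sorted
  std::vector<int> base;  // 0..4
  std::vector<double> lemit; // nb*12, index i*12 + r*6 + g
  std::vector<std::pair<int, int>> segs; // merged footprint intervals
  int lo, hi;             // bridged span (fragment extent)
  int nb;
};

struct Chain {
  std::vector<int> members;
  int lo = 0, hi = 0;
  std::vector<double> esum; // 6*L, index (j)*6+g
  double dp = 0.0;          // optimal DP score (emission + genotype prior)
  double pi0 = 0.0;         // structure-prior contribution
  double totbases = 0.0;
  bool alive = false;
  double score() const { return dp + pi0; }
};

static void conv_matrix(double a, double b, int rho, double M[4][6]) {
  for (int z = 0; z < 4; ++z)
    for (int g = 0; g < 6; ++g) M[z][g] = 0.0;
  double rh = 1.0 - rho;
  M[0][0] = 1.0;                // A|A
  M[3][3] = 1.0;                // T|T
  M[1][1] = rho + rh * a;       // C|C: rev reads see the partner G -> C
  M[3][1] = rh * (1.0 - a);     // T|C: successful conversion, fwd read
  M[2][2] = rh + rho * a;       // G|G
  M[0][2] = rho * (1.0 - a);    // A|G: conversion seen from the rev read
  M[1][4] = 1.0 - rh * b;       // C|meC: protected
  M[3][4] = rh * b;             // T|meC: inappropriate conversion
  M[2][5] = 1.0 - rho * b;      // G|meG
  M[0][5] = rho * b;            // A|meG
}

class Fitter {
public:
  int wlen = 0;
  bool nome = false;
  int K0 = 0, K1 = 0, K2 = 0, K3 = 0;
  double tol = 1e-7;
  int max_passes = 50;

  std::vector<Unit> units;
  std::vector<double> lp;  // wlen*4 genotype prior logs
  std::vector<int> pref_cpg, pref_iso_cpg, pref_iso_gpc; // prefix sums
  std::vector<Chain> chains;
  std::vector<int> chain_of;
  std::vector<int> strand;
  std::vector<double> single_score; // 2 per unit, dp+pi0 of the singleton
  std::vector<double> traj;
  double loglik = 0.0;
  int passes = 0;
  bool converged = false;

  void prepare(const List& units_in, int wstart, int wlen_, const LogicalMatrix& allowed,
               const IntegerVector& ctx, double q, double alpha_fail, double beta,
               int K0_, int K1_, int K2_, int K3_, bool nome_, int max_passes_, double tol_) {
    wlen = wlen_; nome = nome_;
    K0 = K0_; K1 = K1_; K2 = K2_; K3 = K3_;
    max_passes = max_passes_; tol = tol_;

    lp.assign((size_t)wlen * 4, 0.0);
    double lq = std::log(q), l1q = std::log(1.0 - q);
    for (int j = 0; j < wlen; ++j)
      for (int n = 0; n < 4; ++n)
        lp[(size_t)j * 4 + n] = allowed(j, n) ? lq : l1q;

    pref_cpg.assign(wlen + 1, 0);
    pref_iso_cpg.assign(wlen + 1, 0);
    pref_iso_gpc.assign(wlen + 1, 0);
    for (int j = 0; j < wlen; ++j) {
      pref_cpg[j + 1] = pref_cpg[j] + ((ctx[j] & 1) ? 1 : 0);
      pref_iso_cpg[j + 1] = pref_iso_cpg[j] + ((ctx[j] & 4) ? 1 : 0);
      pref_iso_gpc[j + 1] = pref_iso_gpc[j] + ((ctx[j] & 64) ? 1 : 0);
    }

    double Mf[4][6], Mr[4][6];
    conv_matrix(alpha_fail, beta, 0, Mf);
    conv_matrix(alpha_fail, beta, 1, Mr);

    int n = units_in.size();
    units.resize(n);
    for (int u = 0; u < n; ++u) {
      List ui = units_in[u];
      IntegerVector pos = ui["pos"], base = ui["base"];
      NumericVector eps = ui["eps"];
      IntegerMatrix segs = ui["segs"];
      Unit& U = units[u];
      U.nb = pos.size();
      U.pos.resize(U.nb); U.base.resize(U.nb);
      U.lemit.assign((size_t)U.nb * 12, 0.0);
      for (int i = 0; i < U.nb; ++i) {
        int p = pos[i] - wstart;
        if (p < 0 || p >= wlen) stop("read base outside window");
        U.pos[i] = p;
        U.base[i] = base[i];
        int z = base[i];
        double e = eps[i];
        if (z >= 0 && z < 4) {
          for (int g = 0; g < 6; ++g) {
            U.lemit[(size_t)i * 12 + 0 * 6 + g] =
              std::log((1.0 - 4.0 / 3.0 * e) * Mf[z][g] + e / 3.0);
            U.lemit[(size_t)i * 12 + 1 * 6 + g] =
              std::log((1.0 - 4.0 / 3.0 * e) * Mr[z][g] + e / 3.0);
          }
        } // N: stays 0 (likelihood-neutral)
      }
      std::vector<std::pair<int, int>> sg;
      for (int k = 0; k < segs.nrow(); ++k)
        sg.push_back({segs(k, 0) - wstart, segs(k, 1) - wstart});
      std::sort(sg.begin(), sg.end());
      for (auto& s : sg) {
        if (!U.segs.empty() && s.first <= U.segs.back().second + 1)
          U.segs.back().second = std::max(U.segs.back().second, s.second);
        else
          U.segs.push_back(s);
      }
      U.lo = U.segs.front().first;
      U.hi = U.segs.back().second;
    }
    chain_of.assign(n, -1);
    strand.assign(n, 0);
  }

  // Constrained Viterbi over one chain range.
  double dp_run(int lo, int hi, const std::vector<double>& esum,
                std::vector<int>* gout = nullptr) const {
    int L = hi - lo + 1;
    int nstate = nome ? 8 : 6;
    double prev[8], cur[8];
    std::vector<signed char> bp;
    if (gout) bp.assign((size_t)L * 8, -1);
    auto val = [&](int j, int s) {
      return esum[(size_t)j * 6 + SG6[s]] + lp[(size_t)(lo + j) * 4 + PROJ[s]];
    };
    for (int s = 0; s < 8; ++s) prev[s] = NEG;
    for (int s = 0; s < nstate; ++s) {
      bool startok = (s <= 4) || (nome && s == 6); // no pair-closing state first
      if (startok) prev[s] = val(0, s);
    }
    for (int j = 1; j < L; ++j) {
      // best predecessor among states that may be followed by anything:
      // plain nucleotides and pair-closing states
      double bestP = NEG; int argP = 0;
      for (int p = 0; p < nstate; ++p) {
        if (p == 4 || p == 6) continue; // pair-opening states force their close
        if (prev[p] > bestP) { bestP = prev[p]; argP = p; }
      }
      for (int s = 0; s < 8; ++s) cur[s] = NEG;
      for (int s = 0; s < nstate; ++s) {
        if (s == 5) { // Wc must follow Mo
          cur[5] = prev[4] + val(j, 5);
          if (gout) bp[(size_t)j * 8 + 5] = 4;
        } else if (s == 7) { // Mc must follow Wo
          cur[7] = prev[6] + val(j, 7);
          if (gout) bp[(size_t)j * 8 + 7] = 6;
        } else {
          cur[s] = bestP + val(j, s);
          if (gout) bp[(size_t)j * 8 + s] = (signed char)argP;
        }
      }
      for (int s = 0; s < 8; ++s) prev[s] = cur[s];
    }
    double best = NEG; int args = 0;
    for (int s = 0; s < nstate; ++s) {
      bool endok = (s <= 3) || s == 5 || (nome && s == 7); // no dangling opener
      if (endok && prev[s] > best) { best = prev[s]; args = s; }
    }
    if (gout) {
      gout->assign(L, 0);
      int s = args;
      for (int j = L - 1; j >= 0; --j) {
        (*gout)[j] = SG6[s];
        if (j > 0) s = bp[(size_t)j * 8 + s];
      }
    }
    return best;
  }

  static double pi0calc(int n, int L, double totb) {
    return n * (0.5 * std::log((double)L) + 2.0 * std::log(totb));
  }

  void build_esum(const std::vector<int>& members, int lo, int hi,
                  std::vector<double>& esum) const {
    esum.assign((size_t)(hi - lo + 1) * 6, 0.0);
    for (int m : members) {
      const Unit& U = units[m];
      const double* le = U.lemit.data() + strand[m] * 6;
      for (int i = 0; i < U.nb; ++i) {
        double* e = esum.data() + (size_t)(U.pos[i] - lo) * 6;
        const double* l = le + (size_t)i * 12;
        for (int g = 0; g < 6; ++g) e[g] += l[g];
      }
    }
  }

  Chain make_chain(const std::vector<int>& members) const {
    Chain c;
    c.members = members;
    c.lo = units[members[0]].lo; c.hi = units[members[0]].hi;
    c.totbases = 0.0;
    for (int m : members) {
      c.lo = std::min(c.lo, units[m].lo);
      c.hi = std::max(c.hi, units[m].hi);
      c.totbases += units[m].nb;
    }
    build_esum(members, c.lo, c.hi, c.esum);
    c.dp = dp_run(c.lo, c.hi, c.esum);
    c.pi0 = pi0calc((int)members.size(), c.hi - c.lo + 1, c.totbases);
    c.alive = true;
    return c;
  }

  bool feasible_add_range(int lo, int hi, int u) const {
    long bp = 0, c1 = 0, c2 = 0, c3 = 0;
    for (const auto& s : units[u].segs) {
      int a = std::max(s.first, lo), b = std::min(s.second, hi);
      if (a <= b) {
        bp += b - a + 1;
        c1 += pref_cpg[b + 1] - pref_cpg[a];
        c2 += pref_iso_cpg[b + 1] - pref_iso_cpg[a];
        c3 += pref_iso_gpc[b + 1] - pref_iso_gpc[a];
      }
    }
    return bp >= K0 && c1 >= K1 && c2 >= K2 && c3 >= K3;
  }

  bool feasible_add(const Chain& d, int u) const {
    return feasible_add_range(d.lo, d.hi, u);
  }

  // Is this set of units one feasible chain, i.e. buildable by adding
  // one read at a time from some seed read, each addition passing the
  // K thresholds with no coverage gap?  For a fixed seed the repeated
  // greedy scan is complete because feasibility is monotone in the
  // growing range; every seed is tried.
  bool set_buildable(const std::vector<int>& mem) const {
    size_t n = mem.size();
    if (n <= 1) return true;
    std::vector<char> used(n);
    for (size_t s0 = 0; s0 < n; ++s0) {
      std::fill(used.begin(), used.end(), 0);
      used[s0] = 1;
      size_t remaining = n - 1;
      int lo = units[mem[s0]].lo, hi = units[mem[s0]].hi;
      bool progress = true;
      while (remaining > 0 && progress) {
        progress = false;
        for (size_t k = 0; k < n; ++k) {
          if (used[k]) continue;
          const Unit& U = units[mem[k]];
          if (U.lo > hi + 1 || U.hi < lo - 1) continue;
          if (!feasible_add_range(lo, hi, mem[k])) continue;
          used[k] = 1;
          --remaining;
          lo = std::min(lo, U.lo);
          hi = std::max(hi, U.hi);
          progress = true;
        }
      }
      if (remaining == 0) return true;
    }
    return false;
  }

  bool merge_feasible(const Chain& c, const Chain& d) const {
    std::vector<int> mem = c.members;
    mem.insert(mem.end(), d.members.begin(), d.members.end());
    return set_buildable(mem);
  }

  // Tail-swap (recombination) move: exchange the parts of two
  // overlapping chains on either side of a breakpoint.  Mosaic chains -
  // two epi-alleles stitched end to end - are stable under single-read
  // moves because every read agrees with its local mosaic segment; a
  // tail swap repairs them in one step.  Both swapped sets must be
  // buildable, which keeps the configuration inside the feasible space.
  bool try_tail_swap() {
    double bestDelta = tol;
    int bi = -1, bj = -1;
    std::vector<int> best_m1, best_m2;
    for (size_t i = 0; i < chains.size(); ++i) {
      if (!chains[i].alive || chains[i].members.size() < 2) continue;
      for (size_t j = i + 1; j < chains.size(); ++j) {
        if (!chains[j].alive || chains[j].members.size() < 2) continue;
        int olo = std::max(chains[i].lo, chains[j].lo);
        int ohi = std::min(chains[i].hi, chains[j].hi);
        if (olo > ohi) continue;
        double oldsc = chains[i].score() + chains[j].score();
        // candidate breakpoints: a coarse grid across the overlap
        for (int t = 0; t <= 4; ++t) {
          int x = olo + (int)((long)(ohi - olo) * t / 4);
          std::vector<int> m1, m2;
          for (int m : chains[i].members) {
            int ctr = (units[m].lo + units[m].hi) / 2;
            (ctr <= x ? m1 : m2).push_back(m);
          }
          for (int m : chains[j].members) {
            int ctr = (units[m].lo + units[m].hi) / 2;
            (ctr <= x ? m2 : m1).push_back(m);
          }
          if (m1.empty() || m2.empty()) continue;
          if (!set_buildable(m1) || !set_buildable(m2)) continue;
          Chain c1 = make_chain(m1);
          Chain c2 = make_chain(m2);
          double delta = c1.score() + c2.score() - oldsc;
          if (delta > bestDelta) {
            bestDelta = delta;
            bi = (int)i;
            bj = (int)j;
            best_m1 = m1;
            best_m2 = m2;
          }
        }
      }
    }
    if (bi < 0) return false;
    chains[bi].alive = false;
    chains[bj].alive = false;
    register_chain(make_chain(best_m1));
    register_chain(make_chain(best_m2));
    loglik += bestDelta;
    traj.push_back(loglik);
    return true;
  }

  // One round of pairwise chain merges; used when single-read sweeps
  // stall.  Accepts the best strictly improving feasible merge.
  bool try_merge() {
    double bestDelta = tol;
    int bi = -1, bj = -1;
    for (size_t i = 0; i < chains.size(); ++i) {
      if (!chains[i].alive) continue;
      for (size_t j = i + 1; j < chains.size(); ++j) {
        if (!chains[j].alive) continue;
        if (chains[i].hi + 1 < chains[j].lo || chains[j].hi + 1 < chains[i].lo) continue;
        if (!merge_feasible(chains[i], chains[j])) continue;
        std::vector<int> mem = chains[i].members;
        mem.insert(mem.end(), chains[j].members.begin(), chains[j].members.end());
        Chain merged = make_chain(mem);
        double delta = merged.score() - chains[i].score() - chains[j].score();
        if (delta > bestDelta) {
          bestDelta = delta;
          bi = (int)i;
          bj = (int)j;
        }
      }
    }
    if (bi < 0) return false;
    std::vector<int> mem = chains[bi].members;
    mem.insert(mem.end(), chains[bj].members.begin(), chains[bj].members.end());
    Chain merged = make_chain(mem);
    chains[bi].alive = false;
    chains[bj].alive = false;
    register_chain(std::move(merged));
    loglik += bestDelta;
    traj.push_back(loglik);
    return true;
  }

  // Score of chain d with unit u added at strand r (does not modify d).
  double score_with(const Chain& d, int u, int r, std::vector<double>& scratch) const {
    const Unit& U = units[u];
    int lo2 = std::min(d.lo, U.lo), hi2 = std::max(d.hi, U.hi);
    int L2 = hi2 - lo2 + 1;
    scratch.assign((size_t)L2 * 6, 0.0);
    int off = d.lo - lo2;
    std::copy(d.esum.begin(), d.esum.end(), scratch.begin() + (size_t)off * 6);
    const double* le = U.lemit.data() + r * 6;
    for (int i = 0; i < U.nb; ++i) {
      double* e = scratch.data() + (size_t)(U.pos[i] - lo2) * 6;
      const double* l = le + (size_t)i * 12;
      for (int g = 0; g < 6; ++g) e[g] += l[g];
    }
    double dpv = dp_run(lo2, hi2, scratch);
    return dpv + pi0calc((int)d.members.size() + 1, L2, d.totbases + U.nb);
  }

  // Remaining members of c without unit u, decomposed into feasible
  // chains: each block is buildable by single-read additions (seed one
  // read, greedily add overlapping reads passing the K thresholds;
  // greedy is complete because feasibility is monotone in the growing
  // range).  Plain coverage components are not enough: removing a
  // bridging read can leave a contiguous remainder whose parts share too
  // few CpGs to be one feasible chain.
  std::vector<Chain> detach(const Chain& c, int u) const {
    std::vector<int> rest;
    for (int m : c.members) if (m != u) rest.push_back(m);
    std::vector<Chain> out;
    if (rest.empty()) return out;
    std::sort(rest.begin(), rest.end(), [&](int a, int b) {
      if (units[a].lo != units[b].lo) return units[a].lo < units[b].lo;
      return a < b;
    });
    size_t n = rest.size();
    std::vector<char> used(n, 0);
    size_t remaining = n;
    size_t seed = 0;
    while (remaining > 0) {
      while (used[seed]) ++seed;
      std::vector<int> blk{rest[seed]};
      used[seed] = 1;
      --remaining;
      int lo = units[rest[seed]].lo, hi = units[rest[seed]].hi;
      bool progress = true;
      while (progress && remaining > 0) {
        progress = false;
        for (size_t k = seed + 1; k < n; ++k) {
          if (used[k]) continue;
          const Unit& U = units[rest[k]];
          if (U.lo > hi + 1 || U.hi < lo - 1) continue;
          if (!feasible_add_range(lo, hi, rest[k])) continue;
          blk.push_back(rest[k]);
          used[k] = 1;
          --remaining;
          lo = std::min(lo, U.lo);
          hi = std::max(hi, U.hi);
          progress = true;
        }
      }
      out.push_back(make_chain(blk));
    }
    return out;
  }

  int register_chain(Chain&& c) {
    for (size_t k = 0; k < chains.size(); ++k) {
      if (!chains[k].alive) {
        chains[k] = std::move(c);
        for (int m : chains[k].members) chain_of[m] = (int)k;
        return (int)k;
      }
    }
    chains.push_back(std::move(c));
    int k = (int)chains.size() - 1;
    for (int m : chains[k].members) chain_of[m] = k;
    return k;
  }

  void init_singletons() {
    int n = (int)units.size();
    single_score.assign((size_t)n * 2, 0.0);
    std::vector<double> scratch;
    for (int i = 0; i < n; ++i) {
      double sc[2];
      for (int r = 0; r < 2; ++r) {
        strand[i] = r;
        std::vector<int> mem{i};
        Chain c = make_chain(mem);
        sc[r] = c.score();
        single_score[(size_t)i * 2 + r] = sc[r];
      }
      strand[i] = (sc[1] > sc[0]) ? 1 : 0;
      register_chain(make_chain(std::vector<int>{i}));
    }
    loglik = 0.0;
    for (auto& c : chains) if (c.alive) loglik += c.score();
    traj.clear();
    traj.push_back(loglik);
  }

  void fit(bool reverse_order = false) {
    init_singletons();
    int n = (int)units.size();
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      if (units[a].lo != units[b].lo) return units[a].lo < units[b].lo;
      return a < b;
    });
    if (reverse_order) std::reverse(order.begin(), order.end());
    std::vector<double> scratch;
    converged = false;
    for (passes = 0; passes < max_passes; ++passes) {
      bool any = false;
      for (int i : order) {
        int ci = chain_of[i];
        double base = chains[ci].score();
        std::vector<Chain> pieces = detach(chains[ci], i);
        double psum = 0.0;
        for (auto& p : pieces) psum += p.score();

        double bestDelta = tol;
        int bestDest = -2;  // -2 none, -1 singleton, >=0 chain index, or piece
        int bestPiece = -1;
        int bestStrand = strand[i];

        for (int r = 0; r < 2; ++r) {
          double delta = psum + single_score[(size_t)i * 2 + r] - base;
          if (delta > bestDelta) {
            bestDelta = delta; bestDest = -1; bestPiece = -1; bestStrand = r;
          }
        }
        const Unit& U = units[i];
        int save_strand = strand[i];
        for (size_t d = 0; d < chains.size(); ++d) {
          if (!chains[d].alive || (int)d == ci) continue;
          if (chains[d].hi + 1 < U.lo || U.hi + 1 < chains[d].lo) continue;
          if (!feasible_add(chains[d], i)) continue;
          for (int r = 0; r < 2; ++r) {
            strand[i] = r;
            double sc2 = score_with(chains[d], i, r, scratch);
            double delta = psum + sc2 - chains[d].score() - base;
            if (delta > bestDelta) {
              bestDelta = delta; bestDest = (int)d; bestPiece = -1; bestStrand = r;
            }
          }
        }
        for (size_t k = 0; k < pieces.size(); ++k) {
          if (pieces[k].hi + 1 < U.lo || U.hi + 1 < pieces[k].lo) continue;
          if (!feasible_add(pieces[k], i)) continue;
          for (int r = 0; r < 2; ++r) {
            strand[i] = r;
            double sc2 = score_with(pieces[k], i, r, scratch);
            double delta = (psum - pieces[k].score()) + sc2 - base;
            if (delta > bestDelta) {
              bestDelta = delta; bestDest = -3; bestPiece = (int)k; bestStrand = r;
            }
          }
        }
        strand[i] = save_strand;

        if (bestDest != -2) {
          // commit: dissolve ci into pieces, move i to its destination
          chains[ci].alive = false;
          std::vector<int> piece_ids;
          for (size_t k = 0; k < pieces.size(); ++k)
            piece_ids.push_back(register_chain(std::move(pieces[k])));
          strand[i] = bestStrand;
          if (bestDest == -1) {
            register_chain(make_chain(std::vector<int>{i}));
          } else if (bestDest >= 0) {
            std::vector<int> mem = chains[bestDest].members;
            mem.push_back(i);
            Chain merged = make_chain(mem);
            chains[bestDest].alive = false;
            register_chain(std::move(merged));
          } else { // piece destination
            int pid = piece_ids[bestPiece];
            std::vector<int> mem = chains[pid].members;
            mem.push_back(i);
            Chain merged = make_chain(mem);
            chains[pid].alive = false;
            register_chain(std::move(merged));
          }
          loglik += bestDelta;
          traj.push_back(loglik);
          any = true;
        }
      }
      if (!any) {
        // single-read moves exhausted: attempt chain-level moves (the
        // donor-side length loss can flatten the single-read path even
        // when a full merge improves the posterior; mosaics need a
        // recombination swap)
        bool moved_any = false;
        while (try_merge() || try_tail_swap()) moved_any = true;
        if (!moved_any) { converged = true; ++passes; break; }
      }
    }
    // exact final value (guards against accumulated float drift)
    loglik = 0.0;
    for (auto& c : chains) if (c.alive) loglik += c.score();
  }

  List collect(int wstart) {
    std::vector<int> alive;
    for (size_t k = 0; k < chains.size(); ++k) if (chains[k].alive) alive.push_back((int)k);
    std::sort(alive.begin(), alive.end(), [&](int a, int b) {
      if (chains[a].lo != chains[b].lo) return chains[a].lo < chains[b].lo;
      if (chains[a].hi != chains[b].hi) return chains[a].hi < chains[b].hi;
      return *std::min_element(chains[a].members.begin(), chains[a].members.end()) <
             *std::min_element(chains[b].members.begin(), chains[b].members.end());
    });
    int n = (int)units.size();
    IntegerVector chain_id(n), strands(n);
    List out_chains(alive.size());
    for (size_t k = 0; k < alive.size(); ++k) {
      Chain& c = chains[alive[k]];
      std::vector<int> g;
      double dpv = dp_run(c.lo, c.hi, c.esum, &g);
      (void)dpv;
      IntegerVector mem(c.members.size());
      std::vector<int> ms = c.members;
      std::sort(ms.begin(), ms.end());
      for (size_t j = 0; j < ms.size(); ++j) {
        mem[j] = ms[j] + 1;
        chain_id[ms[j]] = (int)k + 1;
      }
      out_chains[k] = List::create(
        _["members"] = mem,
        _["start"] = c.lo + wstart,
        _["end"] = c.hi + wstart,
        _["g"] = IntegerVector(g.begin(), g.end()),
        _["dp"] = c.dp,
        _["pi0"] = c.pi0
      );
    }
    for (int i = 0; i < n; ++i) strands[i] = strand[i];
    return List::create(
      _["chain_of"] = chain_id,
      _["strand"] = strands,
      _["chains"] = out_chains,
      _["loglik"] = loglik,
      _["trajectory"] = NumericVector(traj.begin(), traj.end()),
      _["passes"] = passes,
      _["converged"] = converged
    );
  }
};

// [[Rcpp::export]]
List cpp_fit(List units, int wstart, int wlen, LogicalMatrix allowed,
             IntegerVector ctx, double q, double alpha_fail, double beta,
             int K0, int K1, int K2, int K3, bool nome, int max_passes,
             double tol) {
  Fitter F;
  F.prepare(units, wstart, wlen, allowed, ctx, q, alpha_fail, beta,
            K0, K1, K2, K3, nome, max_passes, tol);
  if (F.units.empty()) {
    return List::create(
      _["chain_of"] = IntegerVector(0), _["strand"] = IntegerVector(0),
      _["chains"] = List(0), _["loglik"] = 0.0,
      _["trajectory"] = NumericVector::create(0.0),
      _["passes"] = 0, _["converged"] = true
    );
  }
  // deterministic two-start search: sweep the reads left-to-right and
  // right-to-left and keep the higher posterior (greedy ascent is
  // trajectory dependent; two deterministic starts blunt the worst
  // local optima without sacrificing reproducibility)
  Fitter R;
  R.prepare(units, wstart, wlen, allowed, ctx, q, alpha_fail, beta,
            K0, K1, K2, K3, nome, max_passes, tol);
  F.fit(false);
  R.fit(true);
  if (R.loglik > F.loglik + 1e-9) return R.collect(wstart);
  return F.collect(wstart);
}

// Optimal epigenotype chain for one fixed set of units and strands.
// [[Rcpp::export]]
List cpp_chain_score(List units, IntegerVector strands, int wstart, int wlen,
                     LogicalMatrix allowed, IntegerVector ctx, double q,
                     double alpha_fail, double beta, bool nome) {
  Fitter F;
  F.prepare(units, wstart, wlen, allowed, ctx, q, alpha_fail, beta,
            0, 0, 0, 0, nome, 1, 1e-7);
  int n = (int)F.units.size();
  if (n == 0) stop("empty chain");
  if (strands.size() != n) stop("one strand per unit required");
  std::vector<int> mem(n);
  for (int i = 0; i < n; ++i) {
    F.strand[i] = strands[i];
    mem[i] = i;
  }
  Chain c = F.make_chain(mem);
  std::vector<int> g;
  double dpv = F.dp_run(c.lo, c.hi, c.esum, &g);
  return List::create(
    _["start"] = c.lo + wstart,
    _["end"] = c.hi + wstart,
    _["g"] = IntegerVector(g.begin(), g.end()),
    _["dp"] = dpv,
    _["pi0"] = c.pi0
  );
}
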