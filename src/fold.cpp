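// Lightweight nearest-neighbor RNA folding.
//
// Two routines back the structural feature channels:
//   duplex_fold_cpp : intermolecular co-folding of a miRNA against a target
//                     window (no intramolecular pairs), in the spirit of
//                     duplex-only hybridization tools. Gaps (bulges /
//                     internal loops) are bounded and penalized linearly;
//                     helix stacking uses a Watson-Crick/G:U stacking table.
//   mfe_fold_cpp    : single-strand minimum-free-energy structure via a
//                     simplified Zuker recursion (stacking + hairpin +
//                     bounded internal/bulge loops, bifurcation without a
//                     multiloop penalty).
//
// Energies approximate the Turner nearest-neighbor parameters (kcal/mol at
// 37C). The engine is deliberately simpler than full Vienna-style folding;
// outputs are deterministic and satisfy the package's structural contracts
// (balanced brackets, non-positive duplex MFE whenever pairs are reported).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <array>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = 1e9;

static int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'U': return 3;
  default:  return 0; // N and anything else folds as A
  }
}

// pair codes: 0 none, 1 AU, 2 UA, 3 GC, 4 CG, 5 GU, 6 UG
static int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// Stacking energy of pair (i,j) on top of pair (i+1,j-1), 5'->3' outer pair
// first. Approximate Turner 2004 WC/GU values, symmetrized.
static double stack_energy(int outer, int inner) {
  static const double S[7][7] = {
    // none   AU     UA     GC     CG     GU     UG
    {0,     0,     0,     0,     0,     0,     0},
    {0, -0.93, -1.10, -2.24, -2.08, -0.55, -1.36}, // AU
    {0, -1.33, -0.93, -2.35, -2.11, -1.27, -1.00}, // UA
    {0, -2.11, -2.08, -3.26, -3.42, -1.53, -2.51}, // GC
    {0, -2.35, -2.24, -3.42, -3.26, -2.11, -1.41}, // CG
    {0, -1.00, -1.36, -1.41, -2.51, -0.50, +1.29}, // GU
    {0, -1.27, -0.55, -2.11, -1.53, -0.30, -0.50}  // UG
  };
  return S[outer][inner];
}

static double hairpin_energy(int size) {
  // positive penalty, min loop 3
  if (size < 3) return INF;
  static const double H[] = {0, 0, 0, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4};
  if (size <= 9) return H[size];
  return 6.4 + 1.75 * 0.616 * std::log((double)size / 9.0);
}

static double internal_energy(int l1, int l2) {
  // bulge / internal loop penalty (both sides of the helix interruption)
  int tot = l1 + l2;
  if (tot == 0) return 0.0; // stack handled separately
  double e;
  if (l1 == 0 || l2 == 0) e = 3.8 + 0.4 * (tot - 1);      // bulge
  else e = 1.7 + 0.4 * (tot - 2) + 0.3 * std::abs(l1 - l2); // internal
  return e;
}

// ---------------------------------------------------------------------------
// Duplex co-folding (intermolecular only).
//
// Sequence 1 (miRNA) 5'->3' pairs sequence 2 (target) antiparallel: if
// (i, j) pair, any further pair (i', j') with i' > i requires j' < j.
// [[Rcpp::export]]
List duplex_fold_cpp(std::string s1, std::string s2) {
  int n = s1.size(), m = s2.size();
  std::vector<int> a(n), b(m);
  for (int i = 0; i < n; ++i) a[i] = base_idx(s1[i]);
  for (int j = 0; j < m; ++j) b[j] = base_idx(s2[j]);
  const double init = 4.1;      // duplex initiation
  const int MAXGAP = 8;

  // E[i][j]: best energy (incl. initiation) of a duplex whose LAST pair
  // (reading seq1 5'->3') is (i, j).
  std::vector<std::vector<double> > E(n, std::vector<double>(m, INF));
  std::vector<std::vector<int> > Pi(n, std::vector<int>(m, -1));
  std::vector<std::vector<int> > Pj(n, std::vector<int>(m, -1));
  double best = INF; int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pc = pair_code(a[i], b[j]);
      if (!pc) continue;
      double e = init; int pi = -1, pj = -1;
      for (int g1 = 0; g1 <= MAXGAP && i - 1 - g1 >= 0; ++g1) {
        for (int g2 = 0; g2 <= MAXGAP && j + 1 + g2 < m; ++g2) {
          int ip = i - 1 - g1, jp = j + 1 + g2;
          if (E[ip][jp] >= INF) continue;
          int pprev = pair_code(a[ip], b[jp]);
          double loop = (g1 == 0 && g2 == 0)
            ? stack_energy(pprev, pc) : internal_energy(g1, g2);
          double cand = E[ip][jp] + loop;
          if (cand < e) { e = cand; pi = ip; pj = jp; }
        }
      }
      E[i][j] = e; Pi[i][j] = pi; Pj[i][j] = pj;
      if (e < best) { best = e; bi = i; bj = j; }
    }
  }

  std::string st1(n, '.'), st2(m, '.');
  double mfe = 0.0;
  int npairs = 0;
  if (best < 0.0) { // only report duplexes that are net favorable
    mfe = best;
    int i = bi, j = bj;
    while (i >= 0 && j >= 0) {
      st1[i] = '('; st2[j] = ')'; ++npairs;
      int ni = Pi[i][j], nj = Pj[i][j];
      i = ni; j = nj;
    }
  }
  return List::create(_["structure1"] = st1, _["structure2"] = st2,
                      _["mfe"] = mfe, _["n_pairs"] = npairs);
}

// ---------------------------------------------------------------------------
// Single-strand MFE folding (simplified Zuker).
// [[Rcpp::export]]
List mfe_fold_cpp(std::string s) {
  int n = s.size();
  std::vector<int> a(n);
  for (int i = 0; i < n; ++i) a[i] = base_idx(s[i]);
  if (n < 5) {
    return List::create(_["structure"] = std::string(n, '.'), _["mfe"] = 0.0);
  }
  const int MAXLOOP = 12; // max unpaired bases in an internal/bulge loop
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));
  // trace codes: V: 0 hairpin, 1 = stack/interior via (ti,tj);
  //              W: 0 unpaired i, 1 unpaired j, 2 paired (V), 3 bifurcation k
  std::vector<std::vector<int> > VtI(n, std::vector<int>(n, -1));
  std::vector<std::vector<int> > VtJ(n, std::vector<int>(n, -1));
  std::vector<std::vector<int> > Wt(n, std::vector<int>(n, 0));
  std::vector<std::vector<int> > Wk(n, std::vector<int>(n, -1));

  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pc = pair_code(a[i], a[j]);
      if (pc) {
        double e = hairpin_energy(j - i - 1);
        int ti = -1, tj = -1;
        // stack / internal / bulge to an inner pair (p,q)
        for (int p = i + 1; p <= std::min(j - 5, i + 1 + MAXLOOP); ++p) {
          int maxq = j - 1;
          int minq = std::max(p + 4, j - 1 - (MAXLOOP - (p - i - 1)));
          for (int q = maxq; q >= minq; --q) {
            int pc2 = pair_code(a[p], a[q]);
            if (!pc2 || V[p][q] >= INF) continue;
            int l1 = p - i - 1, l2 = j - q - 1;
            double loop = (l1 == 0 && l2 == 0)
              ? stack_energy(pc, pc2) : internal_energy(l1, l2);
            double cand = V[p][q] + loop;
            if (cand < e) { e = cand; ti = p; tj = q; }
          }
        }
        // closed bifurcation (multiloop, unpenalized beyond no bonus)
        for (int k = i + 5; k + 5 <= j - 1; ++k) {
          double cand = W[i + 1][k] + W[k + 1][j - 1] + 1.0; // mild ml penalty
          if (cand < e) { e = cand; ti = -2; tj = k; }
        }
        V[i][j] = e; VtI[i][j] = ti; VtJ[i][j] = tj;
      }
      // W recursion
      double w = W[i + 1 <= j ? i + 1 : j][j]; int t = 0, k0 = -1;
      double w2 = (j - 1 >= i) ? W[i][j - 1] : 0.0;
      if (w2 < w) { w = w2; t = 1; }
      if (V[i][j] < w) { w = V[i][j]; t = 2; }
      for (int k = i + 4; k < j - 4; ++k) {
        double cand = W[i][k] + W[k + 1][j];
        if (cand < w) { w = cand; t = 3; k0 = k; }
      }
      if (w > 0) { w = 0; t = 4; } // empty structure is always available
      W[i][j] = w; Wt[i][j] = t; Wk[i][j] = k0;
    }
  }

  std::string st(n, '.');
  // iterative traceback over (i, j, in_V) frames
  std::vector<std::array<int,3> > stack;
  stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    auto f = stack.back(); stack.pop_back();
    int i = f[0], j = f[1], inV = f[2];
    if (i >= j || j - i < 4) continue;
    if (!inV) {
      if (W[i][j] >= 0) continue;
      switch (Wt[i][j]) {
      case 0: stack.push_back({i + 1, j, 0}); break;
      case 1: stack.push_back({i, j - 1, 0}); break;
      case 2: stack.push_back({i, j, 1}); break;
      case 3: stack.push_back({i, Wk[i][j], 0});
              stack.push_back({Wk[i][j] + 1, j, 0}); break;
      default: break;
      }
    } else {
      st[i] = '('; st[j] = ')';
      int ti = VtI[i][j], tj = VtJ[i][j];
      if (ti == -1) continue;                  // hairpin
      if (ti == -2) {                          // closed bifurcation
        stack.push_back({i + 1, tj, 0});
        stack.push_back({tj + 1, j - 1, 0});
      } else {
        stack.push_back({ti, tj, 1});
      }
    }
  }
  double mfe = std::min(0.0, W[0][n - 1]);
  return List::create(_["structure"] = st, _["mfe"] = mfe);
}
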