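// Thermodynamic folding core: pseudoknot-free MFE dynamic programming
// (Zuker-style hairpin / stack / bulge-internal / affine-multiloop
// decomposition) and a McCaskill-style partition function with an outside
// recursion for base-pair probabilities.
//
// Sequences arrive as integer vectors (A=0, C=1, G=2, U=3, N=4).  The energy
// model arrives as a list built by energy_model(): a 5x5 per-pair energy
// matrix (NA = pair disallowed; N row/column always NA), loop penalty tables
// indexed by unpaired-loop size, a 6x6 stacking table indexed by pair type
// (AU, UA, GC, CG, GU, UG), and affine multiloop coefficients a + b*branches
// + c*unpaired.  Energies in kcal/mol throughout.
//
// The inside grammar is unambiguous (external: condition on whether the last
// base is paired; multiloop segment M: condition on the start of the last
// branch; branch-with-tail M1: condition on the tail length), so the same
// recursions serve both the min-energy and the Boltzmann-sum semirings and
// every admissible structure is counted exactly once.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>
using namespace Rcpp;

static const double INF = 1e9;

struct Model {
  double pairE[5][5];     // per-pair energy; >= INF/2 means disallowed
  int ptype[5][5];        // 0..5 for AU,UA,GC,CG,GU,UG; -1 otherwise
  double stack[6][6];     // stack[outer][inner]
  std::vector<double> hairpin, bulge, internal_; // indexed by size (1-based)
  double lxc;             // log extrapolation coefficient for long loops
  double ml_a, ml_b, ml_c;
  int min_hairpin;
  int max_internal;       // cap on total unpaired nt in a bulge/internal loop
  double RT;
};

static Model build_model(const List& m) {
  Model mod;
  NumericMatrix pe = m["pair_energy"];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) {
      double v = pe(a, b);
      mod.pairE[a][b] = NumericVector::is_na(v) ? INF : v;
    }
  // pair type codes for the six canonical pairs
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b) mod.ptype[a][b] = -1;
  mod.ptype[0][3] = 0; // AU
  mod.ptype[3][0] = 1; // UA
  mod.ptype[2][1] = 2; // GC
  mod.ptype[1][2] = 3; // CG
  mod.ptype[2][3] = 4; // GU
  mod.ptype[3][2] = 5; // UG
  NumericMatrix st = m["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) mod.stack[a][b] = st(a, b);
  mod.hairpin = as<std::vector<double> >(m["hairpin"]);
  mod.bulge = as<std::vector<double> >(m["bulge"]);
  mod.internal_ = as<std::vector<double> >(m["internal"]);
  mod.lxc = as<double>(m["lxc"]);
  NumericVector ml = m["multiloop"];
  mod.ml_a = ml[0]; mod.ml_b = ml[1]; mod.ml_c = ml[2];
  mod.min_hairpin = as<int>(m["min_hairpin"]);
  mod.max_internal = as<int>(m["max_internal"]);
  mod.RT = as<double>(m["RT"]);
  return mod;
}

static inline bool can_pair(const Model& M, int a, int b) {
  return M.pairE[a][b] < INF / 2;
}

static inline double tab_penalty(const std::vector<double>& tab, int size,
                                 double lxc) {
  if (size < 1) return INF;
  int len = (int) tab.size();
  if (size <= len) return tab[size - 1];
  return tab[len - 1] + lxc * std::log((double) size / len);
}

static inline double hairpin_E(const Model& M, int i, int j) {
  int size = j - i - 1;
  if (size < M.min_hairpin) return INF;
  return tab_penalty(M.hairpin, size, M.lxc);
}

// energy of the loop closed by (i,j) with inner pair (k,l)
static inline double interior_E(const Model& M, const std::vector<int>& s,
                                int i, int j, int k, int l) {
  int n1 = k - i - 1, n2 = j - l - 1;
  if (n1 == 0 && n2 == 0)
    return M.stack[M.ptype[s[i]][s[j]]][M.ptype[s[k]][s[l]]];
  if (n1 == 0 || n2 == 0) return tab_penalty(M.bulge, n1 + n2, M.lxc);
  return tab_penalty(M.internal_, n1 + n2, M.lxc);
}

// ---------------------------------------------------------------- MFE ----

struct MfeTables {
  int n;
  std::vector<double> V, M1, Mm, W;
  double& v(int i, int j)  { return V[(size_t) i * n + j]; }
  double& m1(int i, int j) { return M1[(size_t) i * n + j]; }
  double& mm(int i, int j) { return Mm[(size_t) i * n + j]; }
};

static void fill_mfe(const Model& M, const std::vector<int>& s, MfeTables& T) {
  int n = (int) s.size();
  T.n = n;
  T.V.assign((size_t) n * n, INF);
  T.M1.assign((size_t) n * n, INF);
  T.Mm.assign((size_t) n * n, INF);
  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V: structure closed by pair (i,j)
      if (can_pair(M, s[i], s[j]) && d - 1 >= M.min_hairpin) {
        double best = hairpin_E(M, i, j);
        int cap = M.max_internal;
        for (int n1 = 0; n1 <= cap; ++n1) {
          int k = i + 1 + n1;
          if (k >= j) break;
          for (int n2 = 0; n2 <= cap - n1; ++n2) {
            int l = j - 1 - n2;
            if (l <= k) break;
            double vkl = T.v(k, l);
            if (vkl >= INF / 2) continue;
            double e = interior_E(M, s, i, j, k, l) + vkl;
            if (e < best) best = e;
          }
        }
        for (int m = i + 2; m <= j - 2; ++m) {
          double left = T.mm(i + 1, m - 1), right = T.m1(m, j - 1);
          if (left >= INF / 2 || right >= INF / 2) continue;
          double e = M.ml_a + M.ml_b + left + right;
          if (e < best) best = e;
        }
        if (best < INF / 2) T.v(i, j) = M.pairE[s[i]][s[j]] + best;
      }
      // M1: one branch starting at i, unpaired tail to j
      {
        double best = (T.v(i, j) < INF / 2) ? T.v(i, j) + M.ml_b : INF;
        if (d >= 1 && T.m1(i, j - 1) < INF / 2) {
          double e = T.m1(i, j - 1) + M.ml_c;
          if (e < best) best = e;
        }
        T.m1(i, j) = best;
      }
      // M: >= 1 branch; condition on start k of the last branch
      {
        double best = INF;
        for (int k = i; k <= j; ++k) {
          double m1kj = T.m1(k, j);
          if (m1kj >= INF / 2) continue;
          double pre = M.ml_c * (k - i);
          if (k > i && T.mm(i, k - 1) < INF / 2 && T.mm(i, k - 1) < pre)
            pre = std::min(pre, T.mm(i, k - 1));
          double e = pre + m1kj;
          if (e < best) best = e;
        }
        T.mm(i, j) = best;
      }
    }
  }
  // M1/M for d = 0
  for (int i = 0; i < n; ++i) {
    // single nucleotide cannot hold a branch; leave INF (set above loop skips d=0)
  }
  T.W.assign(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    double best = T.W[j]; // j unpaired (preferred on ties)
    for (int i = 0; i <= j; ++i) {
      double vij = T.v(i, j);
      if (vij < INF / 2) {
        double e = T.W[i] + vij;
        if (e < best) best = e;
      }
    }
    T.W[j + 1] = best;
  }
}

static const double EPS = 1e-9;

// traceback with fixed tie-breaking: external prefers j unpaired, then the
// smallest i closing (i,j); inside V the scan order is hairpin, interior
// loops (n1 then n2 ascending), then multiloop with smallest split.
static void traceback_mfe(const Model& M, const std::vector<int>& s,
                          MfeTables& T, std::string& db) {
  int n = (int) s.size();
  db.assign(n, '.');
  struct Seg { int i, j, state; }; // 0=EXT,1=V,2=M,3=M1
  std::vector<Seg> st;
  st.push_back({0, n - 1, 0});
  while (!st.empty()) {
    Seg sg = st.back(); st.pop_back();
    int i = sg.i, j = sg.j;
    if (sg.state == 0) { // external region 0..j
      while (j >= i) {
        if (std::fabs(T.W[j + 1] - T.W[j]) < EPS) { --j; continue; }
        int found = -1;
        for (int k = i; k <= j; ++k) {
          if (T.v(k, j) < INF / 2 &&
              std::fabs(T.W[j + 1] - (T.W[k] + T.v(k, j))) < EPS) {
            found = k; break;
          }
        }
        st.push_back({found, j, 1});
        j = found - 1;
      }
    } else if (sg.state == 1) { // pair (i,j)
      db[i] = '('; db[j] = ')';
      double target = T.v(i, j) - M.pairE[s[i]][s[j]];
      if (std::fabs(target - hairpin_E(M, i, j)) < EPS) continue;
      bool done = false;
      int cap = M.max_internal;
      for (int n1 = 0; n1 <= cap && !done; ++n1) {
        int k = i + 1 + n1;
        if (k >= j) break;
        for (int n2 = 0; n2 <= cap - n1; ++n2) {
          int l = j - 1 - n2;
          if (l <= k) break;
          if (T.v(k, l) >= INF / 2) continue;
          if (std::fabs(target - (interior_E(M, s, i, j, k, l) + T.v(k, l)))
              < EPS) {
            st.push_back({k, l, 1});
            done = true; break;
          }
        }
      }
      if (done) continue;
      for (int m = i + 2; m <= j - 2; ++m) {
        if (T.mm(i + 1, m - 1) >= INF / 2 || T.m1(m, j - 1) >= INF / 2)
          continue;
        if (std::fabs(target - (M.ml_a + M.ml_b + T.mm(i + 1, m - 1) +
                                T.m1(m, j - 1))) < EPS) {
          st.push_back({i + 1, m - 1, 2});
          st.push_back({m, j - 1, 3});
          done = true; break;
        }
      }
      if (!done) stop("internal error: V traceback failed");
    } else if (sg.state == 2) { // M
      double target = T.mm(i, j);
      bool done = false;
      for (int k = i; k <= j && !done; ++k) {
        if (T.m1(k, j) >= INF / 2) continue;
        if (std::fabs(target - (M.ml_c * (k - i) + T.m1(k, j))) < EPS) {
          st.push_back({k, j, 3});
          done = true;
        } else if (k > i && T.mm(i, k - 1) < INF / 2 &&
                   std::fabs(target - (T.mm(i, k - 1) + T.m1(k, j))) < EPS) {
          st.push_back({i, k - 1, 2});
          st.push_back({k, j, 3});
          done = true;
        }
      }
      if (!done) stop("internal error: M traceback failed");
    } else { // M1: strip unpaired tail, then V
      while (j > i && T.m1(i, j - 1) < INF / 2 &&
             std::fabs(T.m1(i, j) - (T.m1(i, j - 1) + M.ml_c)) < EPS)
        --j;
      if (T.v(i, j) >= INF / 2 ||
          std::fabs(T.m1(i, j) - (T.v(i, j) + M.ml_b)) > EPS)
        stop("internal error: M1 traceback failed");
      st.push_back({i, j, 1});
    }
  }
}

// -------------------------------------------------- maximum-pairing path ----
// For models with all loop terms zero and one uniform per-pair energy the
// general DP reduces to maximum non-crossing matching (per-pair bonus times
// the maximum number of admissible pairs), computed in O(n^3/6).

static void fill_maxpair(const Model& M, const std::vector<int>& s,
                         std::vector<int>& D) {
  int n = (int) s.size();
  D.assign((size_t) n * n, 0);
  std::vector<int> K; // positions pairable with j, ascending
  for (int j = M.min_hairpin + 1; j < n; ++j) {
    K.clear();
    for (int k = 0; k <= j - M.min_hairpin - 1; ++k)
      if (can_pair(M, s[k], s[j])) K.push_back(k);
    for (int i = j - M.min_hairpin - 1; i >= 0; --i) {
      int best = D[(size_t) i * n + (j - 1)]; // j unpaired
      // only pairable k >= i matter
      std::vector<int>::const_iterator it =
          std::lower_bound(K.begin(), K.end(), i);
      for (; it != K.end(); ++it) {
        int k = *it;
        int v = 1 + D[(size_t) (k + 1) * n + (j - 1)];
        if (k > i) v += D[(size_t) i * n + (k - 1)];
        if (v > best) best = v;
      }
      D[(size_t) i * n + j] = best;
    }
  }
}

// Partition function + pair probabilities for uniform models (all loop
// terms zero, one per-pair energy): unpaired positions weigh 1, each pair
// weighs q, no internal-loop cap.  Region grammar conditioned on the last
// position, so every structure is generated exactly once.
static void partition_uniform(const Model& M, const std::vector<int>& s,
                              double q, double& Z, NumericMatrix& P) {
  int n = (int) s.size();
  int mh = M.min_hairpin;
  std::vector<double> Q((size_t) n * n, 0.0), OQ((size_t) n * n, 0.0);
#define QX(i, j) Q[(size_t)(i) * n + (j)]
#define OX(i, j) OQ[(size_t)(i) * n + (j)]
  // inside; Q(i,j) for empty/short regions is 1 (handled via accessor)
  for (int j = 0; j < n; ++j) {
    for (int i = j; i >= 0; --i) {
      double z = (j > i) ? QX(i, j - 1) : 1.0;
      for (int k = i; k <= j - mh - 1; ++k) {
        if (!can_pair(M, s[k], s[j])) continue;
        double left = (k > i) ? QX(i, k - 1) : 1.0;
        double in = (j - 1 >= k + 1) ? QX(k + 1, j - 1) : 1.0;
        z += left * q * in;
      }
      QX(i, j) = z;
    }
  }
  Z = QX(0, n - 1);
  if (!R_finite(Z)) stop("partition function overflow");
  // outside, spans decreasing
  OX(0, n - 1) = 1.0;
  for (int d = n - 1; d >= 0; --d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      double o = OX(i, j);
      if (o == 0.0) continue;
      if (j - 1 >= i) OX(i, j - 1) += o;
      for (int k = i; k <= j - mh - 1; ++k) {
        if (!can_pair(M, s[k], s[j])) continue;
        double left = (k > i) ? QX(i, k - 1) : 1.0;
        double in = (j - 1 >= k + 1) ? QX(k + 1, j - 1) : 1.0;
        if (k > i) OX(i, k - 1) += o * q * in;
        if (j - 1 >= k + 1) OX(k + 1, j - 1) += o * q * left;
        P(k, j) += o * left * q * in / Z;
      }
    }
  }
#undef QX
#undef OX
}

static void traceback_maxpair(const Model& M, const std::vector<int>& s,
                              const std::vector<int>& D, std::string& db) {
  int n = (int) s.size();
  db.assign(n, '.');
  std::vector<std::pair<int,int> > st;
  st.push_back(std::make_pair(0, n - 1));
  while (!st.empty()) {
    int i = st.back().first, j = st.back().second;
    st.pop_back();
    while (j > i) {
      int dij = D[(size_t) i * n + j];
      if (dij == 0) break;
      if (dij == D[(size_t) i * n + (j - 1)]) { --j; continue; } // prefer unpaired
      int found = -1;
      for (int k = i; k <= j - M.min_hairpin - 1; ++k) {
        if (!can_pair(M, s[k], s[j])) continue;
        int v = 1 + D[(size_t) (k + 1) * n + (j - 1)];
        if (k > i) v += D[(size_t) i * n + (k - 1)];
        if (v == dij) { found = k; break; } // smallest k on ties
      }
      db[found] = '('; db[j] = ')';
      st.push_back(std::make_pair(found + 1, j - 1));
      j = found - 1;
    }
  }
}

// ------------------------------------------------------------- exports ----

static std::vector<int> as_seq(const IntegerVector& x) {
  std::vector<int> s(x.size());
  for (int i = 0; i < x.size(); ++i) {
    s[i] = x[i];
    if (s[i] < 0 || s[i] > 4) stop("invalid sequence code");
  }
  return s;
}

// [[Rcpp::export]]
List cpp_mfe(IntegerVector seq, List model, bool fast_path, bool want_structure) {
  std::vector<int> s = as_seq(seq);
  Model M = build_model(model);
  int n = (int) s.size();
  std::string db(n, '.');
  double energy = 0.0;
  if (fast_path) {
    std::vector<int> D;
    fill_maxpair(M, s, D);
    int npairs = (n > 1) ? D[(size_t) 0 * n + (n - 1)] : 0;
    // uniform per-pair energy: take it from the first allowed pair
    double pe = 0.0;
    for (int a = 0; a < 5 && pe == 0.0; ++a)
      for (int b = 0; b < 5; ++b)
        if (can_pair(M, a, b)) { pe = M.pairE[a][b]; break; }
    energy = pe * npairs;
    if (want_structure && npairs > 0) traceback_maxpair(M, s, D, db);
  } else {
    MfeTables T;
    fill_mfe(M, s, T);
    energy = (n > 1) ? T.W[n] : 0.0;
    if (energy > 0) energy = 0.0; // empty structure always admissible
    if (want_structure && energy < 0) traceback_mfe(M, s, T, db);
  }
  return List::create(_["energy"] = energy, _["structure"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_mfe_batch(List seqs, List model, bool fast_path) {
  Model M = build_model(model);
  int m = seqs.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    std::vector<int> s = as_seq(seqs[q]);
    int n = (int) s.size();
    if (fast_path) {
      std::vector<int> D;
      fill_maxpair(M, s, D);
      int npairs = (n > 1) ? D[(size_t) 0 * n + (n - 1)] : 0;
      double pe = 0.0;
      for (int a = 0; a < 5 && pe == 0.0; ++a)
        for (int b = 0; b < 5; ++b)
          if (can_pair(M, a, b)) { pe = M.pairE[a][b]; break; }
      out[q] = pe * npairs;
    } else {
      MfeTables T;
      fill_mfe(M, s, T);
      double e = (n > 1) ? T.W[n] : 0.0;
      out[q] = (e > 0) ? 0.0 : e;
    }
  }
  return out;
}

// McCaskill-style inside/outside.  Returns Z, ensemble free energy and the
// base-pair probability matrix.  fast_path selects the uniform-model
// recursion (maximum-pairing energy semantics, no internal-loop cap).
// [[Rcpp::export]]
List cpp_partition(IntegerVector seq, List model, bool fast_path) {
  std::vector<int> s = as_seq(seq);
  Model M = build_model(model);
  int n = (int) s.size();
  double RT = M.RT;
  if (fast_path) {
    double pe = 0.0;
    bool found = false;
    for (int a = 0; a < 5 && !found; ++a)
      for (int b = 0; b < 5; ++b)
        if (can_pair(M, a, b)) { pe = M.pairE[a][b]; found = true; break; }
    double Zu = 1.0;
    NumericMatrix Pu(n, n);
    if (n > 1) partition_uniform(M, s, std::exp(-pe / RT), Zu, Pu);
    return List::create(_["Z"] = Zu, _["G"] = -RT * std::log(Zu),
                        _["pair_prob"] = Pu);
  }
  const double eb = std::exp(-M.ml_b / RT);
  const double ec = std::exp(-M.ml_c / RT);
  const double eab = std::exp(-(M.ml_a + M.ml_b) / RT);

  std::vector<double> QV((size_t) n * n, 0.0), QM((size_t) n * n, 0.0),
      QM1((size_t) n * n, 0.0);
#define IX(i, j) ((size_t)(i) * n + (j))
  for (int d = 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      if (can_pair(M, s[i], s[j]) && d - 1 >= M.min_hairpin) {
        double q = std::exp(-hairpin_E(M, i, j) / RT);
        int cap = M.max_internal;
        for (int n1 = 0; n1 <= cap; ++n1) {
          int k = i + 1 + n1;
          if (k >= j) break;
          for (int n2 = 0; n2 <= cap - n1; ++n2) {
            int l = j - 1 - n2;
            if (l <= k) break;
            if (QV[IX(k, l)] == 0.0) continue;
            q += std::exp(-interior_E(M, s, i, j, k, l) / RT) * QV[IX(k, l)];
          }
        }
        double qm = 0.0;
        for (int m = i + 2; m <= j - 2; ++m)
          qm += QM[IX(i + 1, m - 1)] * QM1[IX(m, j - 1)];
        q += eab * qm;
        QV[IX(i, j)] = std::exp(-M.pairE[s[i]][s[j]] / RT) * q;
      }
      QM1[IX(i, j)] = QV[IX(i, j)] * eb +
                      (d >= 1 ? QM1[IX(i, j - 1)] * ec : 0.0);
      double qm = 0.0;
      for (int k = i; k <= j; ++k) {
        if (QM1[IX(k, j)] == 0.0) continue;
        double pre = std::pow(ec, (double)(k - i));
        if (k > i) pre += QM[IX(i, k - 1)];
        qm += pre * QM1[IX(k, j)];
      }
      QM[IX(i, j)] = qm;
    }
  }
  // external prefix / suffix
  std::vector<double> Qe(n + 1, 1.0), Qs(n + 1, 1.0);
  for (int j = 0; j < n; ++j) {
    double z = Qe[j];
    for (int i = 0; i <= j; ++i)
      if (QV[IX(i, j)] != 0.0) z += Qe[i] * QV[IX(i, j)];
    Qe[j + 1] = z;
  }
  for (int i = n - 1; i >= 0; --i) {
    double z = Qs[i + 1];
    for (int j = i; j < n; ++j)
      if (QV[IX(i, j)] != 0.0) z += QV[IX(i, j)] * Qs[j + 1];
    Qs[i] = z;
  }
  double Z = Qe[n];
  if (!R_finite(Z)) stop("partition function overflow");

  // outside pass, spans decreasing
  std::vector<double> OV((size_t) n * n, 0.0), OM((size_t) n * n, 0.0),
      OM1((size_t) n * n, 0.0);
  NumericMatrix P(n, n);
  for (int d = n - 1; d >= 1; --d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // pushes from QM(i,j) (complete by now)
      double om = OM[IX(i, j)];
      if (om != 0.0) {
        for (int k = i; k <= j; ++k) {
          if (QM1[IX(k, j)] == 0.0 && k != i) continue;
          double pre = std::pow(ec, (double)(k - i));
          if (k > i) pre += QM[IX(i, k - 1)];
          OM1[IX(k, j)] += pre * om;
          if (k > i && QM1[IX(k, j)] != 0.0)
            OM[IX(i, k - 1)] += QM1[IX(k, j)] * om;
        }
      }
      // pushes from QM1(i,j)
      double om1 = OM1[IX(i, j)];
      if (om1 != 0.0) {
        OV[IX(i, j)] += eb * om1;
        if (d >= 1) OM1[IX(i, j - 1)] += ec * om1;
      }
      if (QV[IX(i, j)] == 0.0) continue;
      // finalize OV with the external context
      OV[IX(i, j)] += Qe[i] * Qs[j + 1];
      double p = QV[IX(i, j)] * OV[IX(i, j)] / Z;
      P(i, j) = p;
      // pushes from QV(i,j): enclosing-pair contexts for inner pairs,
      // multiloop contents
      double ov = OV[IX(i, j)] * std::exp(-M.pairE[s[i]][s[j]] / RT);
      int cap = M.max_internal;
      for (int n1 = 0; n1 <= cap; ++n1) {
        int k = i + 1 + n1;
        if (k >= j) break;
        for (int n2 = 0; n2 <= cap - n1; ++n2) {
          int l = j - 1 - n2;
          if (l <= k) break;
          if (QV[IX(k, l)] == 0.0) continue;
          OV[IX(k, l)] += std::exp(-interior_E(M, s, i, j, k, l) / RT) * ov;
        }
      }
      for (int m = i + 2; m <= j - 2; ++m) {
        double left = QM[IX(i + 1, m - 1)], right = QM1[IX(m, j - 1)];
        if (right != 0.0) OM[IX(i + 1, m - 1)] += eab * right * ov;
        if (left != 0.0)  OM1[IX(m, j - 1)] += eab * left * ov;
      }
    }
  }
#undef IX
  double G = -RT * std::log(Z);
  return List::create(_["Z"] = Z, _["G"] = G, _["pair_prob"] = P);
}
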