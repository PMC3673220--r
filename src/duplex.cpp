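#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular RNA:RNA duplex minimum free energy.
//
// Bases are encoded A=0, C=1, G=2, U=3. A structure is an ordered set of base
// pairs (i1<i2<...<ik on the probe, j1>j2>...>jk on the target; antiparallel
// strands). Consecutive pairs are joined by a stack (no unpaired bases), a
// bulge (unpaired bases on one strand only) or an internal loop (both
// strands). Energy = duplex initiation + sum of stack increments and loop
// penalties. A structure qualifies if it contains a contiguous helix of at
// least `min_helix` stacked pairs; the reported value is the minimum over
// qualifying structures, capped at the 0.0 "no binding" sentinel.
//
// Pair codes follow the order CG, GC, GU, UG, AU, UA (first base on the
// probe/top strand read 5'->3'). stack(p, q) is the increment for pair q
// stacked directly 3' of pair p on the probe strand.

static inline int pair_code(int a, int b) {
  if (a == 1 && b == 2) return 0;  // C:G
  if (a == 2 && b == 1) return 1;  // G:C
  if (a == 2 && b == 3) return 2;  // G:U
  if (a == 3 && b == 2) return 3;  // U:G
  if (a == 0 && b == 3) return 4;  // A:U
  if (a == 3 && b == 0) return 5;  // U:A
  return -1;
}

struct DuplexParams {
  NumericMatrix stack;   // 6 x 6
  NumericVector bulge;   // bulge[len - 1], len = 1..max_loop
  NumericVector iloop;   // iloop[size - 2], size = 2..max_loop
  double init;
  int max_loop;
  int min_helix;
};

static DuplexParams unpack(List par) {
  DuplexParams p;
  p.stack = as<NumericMatrix>(par["stack"]);
  p.bulge = as<NumericVector>(par["bulge"]);
  p.iloop = as<NumericVector>(par["iloop"]);
  p.init = as<double>(par["init"]);
  p.max_loop = as<int>(par["max_loop"]);
  p.min_helix = as<int>(par["min_helix"]);
  return p;
}

// transition energy between consecutive pairs with ga unpaired probe bases
// and gb unpaired target bases in between; returns NA for inadmissible gaps
static inline double trans_energy(const DuplexParams& p, int pc1, int pc2,
                                  int ga, int gb, bool& is_stack) {
  is_stack = false;
  if (ga == 0 && gb == 0) {
    is_stack = true;
    return p.stack(pc1, pc2);
  }
  if (gb == 0) {  // bulge on probe
    if (ga > p.max_loop) return NA_REAL;
    return p.bulge[ga - 1];
  }
  if (ga == 0) {  // bulge on target
    if (gb > p.max_loop) return NA_REAL;
    return p.bulge[gb - 1];
  }
  int sz = ga + gb;  // internal loop, total unpaired length
  if (sz > p.max_loop) return NA_REAL;
  return p.iloop[sz - 2];
}

// ---- dynamic programme ----------------------------------------------------

static double duplex_mfe_core(const IntegerVector& a, const IntegerVector& b,
                              const DuplexParams& p) {
  const int m = a.size(), n = b.size();
  const int R = p.min_helix;  // run lengths tracked as 1..R (capped)
  const double INF = 1e9;
  // best[i][j][r][f]: min energy (loop/stack terms only) of a structure whose
  // 3'-most pair is (i, j), current stacked-run length min(run, R), f = helix
  // of length >= R seen anywhere
  std::vector<double> best(static_cast<size_t>(m) * n * R * 2, INF);
  auto idx = [&](int i, int j, int r, int f) {
    return ((static_cast<size_t>(i) * n + j) * R + (r - 1)) * 2 + f;
  };
  double ans = INF;
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      int pc = pair_code(a[i], b[j]);
      if (pc < 0) continue;
      {  // structure starting at this pair
        int f0 = (R <= 1) ? 1 : 0;
        double& slot = best[idx(i, j, 1, f0)];
        if (0.0 < slot) slot = 0.0;
      }
      // extend from previous pair (i2 < i on probe, j2 > j on target)
      for (int i2 = std::max(0, i - 1 - p.max_loop); i2 <= i - 1; ++i2) {
        for (int j2 = j + 1; j2 <= std::min(n - 1, j + 1 + p.max_loop); ++j2) {
          int pc2 = pair_code(a[i2], b[j2]);
          if (pc2 < 0) continue;
          bool is_stack;
          double te = trans_energy(p, pc2, pc, i - i2 - 1, j2 - j - 1, is_stack);
          if (ISNA(te)) continue;
          for (int r2 = 1; r2 <= R; ++r2) {
            for (int f2 = 0; f2 <= 1; ++f2) {
              double prev = best[idx(i2, j2, r2, f2)];
              if (prev >= INF) continue;
              int r = is_stack ? std::min(r2 + 1, R) : 1;
              int f = (f2 == 1 || r >= R) ? 1 : 0;
              double e = prev + te;
              double& slot = best[idx(i, j, r, f)];
              if (e < slot) slot = e;
            }
          }
        }
      }
      for (int r = 1; r <= R; ++r) {
        double e = best[idx(i, j, r, 1)];
        if (e < ans) ans = e;
      }
    }
  }
  if (ans >= INF) return 0.0;
  double g = p.init + ans;
  return g < 0.0 ? g : 0.0;
}

// ---- exhaustive enumeration (independent oracle) --------------------------

struct EnumState {
  const IntegerVector* a;
  const IntegerVector* b;
  const DuplexParams* p;
  double best;
};

static void enum_extend(EnumState& st, int i, int j, int run, int maxrun,
                        double energy) {
  const DuplexParams& p = *st.p;
  if (maxrun >= p.min_helix && energy < st.best) st.best = energy;
  const int m = st.a->size(), n = st.b->size();
  int pc1 = pair_code((*st.a)[i], (*st.b)[j]);
  for (int i2 = i + 1; i2 <= std::min(m - 1, i + 1 + p.max_loop); ++i2) {
    for (int j2 = std::max(0, j - 1 - p.max_loop); j2 <= j - 1; ++j2) {
      int pc2 = pair_code((*st.a)[i2], (*st.b)[j2]);
      if (pc2 < 0) continue;
      bool is_stack;
      double te = trans_energy(p, pc1, pc2, i2 - i - 1, j - j2 - 1, is_stack);
      if (ISNA(te)) continue;
      int run2 = is_stack ? run + 1 : 1;
      enum_extend(st, i2, j2, run2, std::max(maxrun, run2), energy + te);
    }
  }
}

static double duplex_enum_core(const IntegerVector& a, const IntegerVector& b,
                               const DuplexParams& p) {
  EnumState st{&a, &b, &p, 1e9};
  const int m = a.size(), n = b.size();
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j)
      if (pair_code(a[i], b[j]) >= 0)
        enum_extend(st, i, j, 1, 1, 0.0);
  if (st.best >= 1e9) return 0.0;
  double g = p.init + st.best;
  return g < 0.0 ? g : 0.0;
}

// [[Rcpp::export(name = ".cpp_duplex_mfe")]]
double cpp_duplex_mfe(IntegerVector probe, IntegerVector target, List par) {
  DuplexParams p = unpack(par);
  return duplex_mfe_core(probe, target, p);
}

// [[Rcpp::export(name = ".cpp_duplex_enum")]]
double cpp_duplex_enum(IntegerVector probe, IntegerVector target, List par) {
  DuplexParams p = unpack(par);
  return duplex_enum_core(probe, target, p);
}

// Energies for all 4^k probes of length k against `target`, in base-4
// lexicographic order of the probe (A=0 < C=1 < G=2 < U=3).
// [[Rcpp::export(name = ".cpp_all_kmer_energies")]]
NumericVector cpp_all_kmer_energies(int k, IntegerVector target, List par,
                                    bool use_enum) {
  DuplexParams p = unpack(par);
  R_xlen_t nk = 1;
  for (int i = 0; i < k; ++i) nk *= 4;
  NumericVector out(nk);
  IntegerVector probe(k);
  for (R_xlen_t code = 0; code < nk; ++code) {
    R_xlen_t c = code;
    for (int i = k - 1; i >= 0; --i) {
      probe[i] = c % 4;
      c /= 4;
    }
    out[code] = use_enum ? duplex_enum_core(probe, target, p)
                         : duplex_mfe_core(probe, target, p);
    if (code % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Sliding-window minimum: out[i] = min(x[i], ..., x[i + w - 1]),
// length(out) = length(x) - w + 1.
// [[Rcpp::export(name = ".cpp_sliding_min")]]
NumericVector cpp_sliding_min(NumericVector x, int w) {
  const R_xlen_t n = x.size();
  if (w < 1 || n < w) return NumericVector(0);
  R_xlen_t m = n - w + 1;
  NumericVector out(m);
  std::deque<R_xlen_t> dq;  // indices, values increasing
  for (R_xlen_t i = 0; i < n; ++i) {
    while (!dq.empty() && x[dq.back()] >= x[i]) dq.pop_back();
    dq.push_back(i);
    if (dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1) out[i - w + 1] = x[dq.front()];
  }
  return out;
}
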