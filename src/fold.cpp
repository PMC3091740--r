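#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA sequence under a simplified
// nearest-neighbour model: stacking energies for adjacent pairs, tabulated
// hairpin/bulge/internal-loop penalties, linear multiloop model
// (a + b per branch incl. the closing pair + c per unpaired base).
// Nested structures only (no pseudoknots); lonely pairs allowed; GU wobble
// allowed; minimum hairpin loop length and maximum bulge/internal-loop size
// are passed in. Traceback is deterministic: interior extensions are tried
// with smallest k (then largest l) first, then the hairpin, then multiloop
// bifurcations with the smallest split point.

static const double INF = std::numeric_limits<double>::infinity();

// bases: A=1, C=2, G=3, U=4 ; pair codes 1..6 = AU UA GC CG GU UG, 0 = none
static inline int pair_code(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

struct FoldCtx {
  int n;
  std::vector<int> code;           // base codes, 0-based
  std::vector<double> V, WM;       // n*n, row-major [i*n+j]
  std::vector<double> W;           // exterior, size n+1, W[j+1] = best for 0..j
  const double *stack;             // 6x6 column-major from R
  const double *hp, *bu, *il;      // penalty tables, 1-based size -> [size-1]
  double a, b, c;
  int minh, maxil;

  double stackE(int pout, int pin) const { return stack[(pin - 1) * 6 + (pout - 1)]; }
  int pc(int i, int j) const { return pair_code(code[i], code[j]); }
};

static double getV(FoldCtx &C, int i, int j) { return C.V[(size_t)i * C.n + j]; }
static double getWM(FoldCtx &C, int i, int j) {
  if (j - i + 1 < C.minh + 2) return INF;
  return C.WM[(size_t)i * C.n + j];
}

static void fill_tables(FoldCtx &C) {
  int n = C.n;
  C.V.assign((size_t)n * n, INF);
  C.WM.assign((size_t)n * n, INF);
  for (int span = C.minh + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      // --- V(i,j)
      double v = INF;
      if (C.pc(i, j) > 0 && j - i - 1 >= C.minh) {
        v = C.hp[j - i - 1 - 1];                       // hairpin
        // interior loop / stack / bulge
        for (int k = i + 1; k <= j - 2; ++k) {
          int s1 = k - i - 1;
          if (s1 > C.maxil) break;
          for (int l = j - 1; l > k; --l) {
            int s2 = j - l - 1;
            if (s1 + s2 > C.maxil) break;
            double inner = getV(C, k, l);
            if (!std::isfinite(inner)) continue;
            double loop;
            if (s1 == 0 && s2 == 0) loop = C.stackE(C.pc(i, j), C.pc(k, l));
            else if (s1 == 0 || s2 == 0) loop = C.bu[s1 + s2 - 1];
            else loop = C.il[s1 + s2 - 1];
            if (inner + loop < v) v = inner + loop;
          }
        }
        // multiloop: a + b (closing) + WM(i+1,u) + WM(u+1,j-1)
        for (int u = i + 1; u <= j - 2; ++u) {
          double lhs = getWM(C, i + 1, u);
          if (!std::isfinite(lhs)) continue;
          double rhs = getWM(C, u + 1, j - 1);
          if (!std::isfinite(rhs)) continue;
          double cand = C.a + C.b + lhs + rhs;
          if (cand < v) v = cand;
        }
      }
      C.V[(size_t)i * n + j] = v;
      // --- WM(i,j): >=1 branch
      double wm = INF;
      if (std::isfinite(v)) wm = v + C.b;
      double t = getWM(C, i + 1, j);
      if (std::isfinite(t) && t + C.c < wm) wm = t + C.c;
      t = getWM(C, i, j - 1);
      if (std::isfinite(t) && t + C.c < wm) wm = t + C.c;
      for (int u = i; u < j; ++u) {
        double lhs = getWM(C, i, u), rhs = getWM(C, u + 1, j);
        if (std::isfinite(lhs) && std::isfinite(rhs) && lhs + rhs < wm)
          wm = lhs + rhs;
      }
      C.WM[(size_t)i * n + j] = wm;
    }
  }
  // exterior
  C.W.assign(n + 1, 0.0);
  for (int j = 0; j < n; ++j) {
    double w = C.W[j];                                 // j unpaired
    for (int i = 0; i <= j; ++i) {
      double v = getV(C, i, j);
      if (std::isfinite(v) && C.W[i] + v < w) w = C.W[i] + v;
    }
    C.W[j + 1] = w;
  }
}

static const double EPS = 1e-9;

static void trace_V(FoldCtx &C, int i, int j, std::vector<int> &partner);

static void trace_WM(FoldCtx &C, int i, int j, std::vector<int> &partner) {
  double wm = getWM(C, i, j);
  double v = getV(C, i, j);
  if (std::isfinite(v) && std::fabs(v + C.b - wm) < EPS) {
    trace_V(C, i, j, partner); return;
  }
  double t = getWM(C, i, j - 1);
  if (std::isfinite(t) && std::fabs(t + C.c - wm) < EPS) {
    trace_WM(C, i, j - 1, partner); return;
  }
  t = getWM(C, i + 1, j);
  if (std::isfinite(t) && std::fabs(t + C.c - wm) < EPS) {
    trace_WM(C, i + 1, j, partner); return;
  }
  for (int u = i; u < j; ++u) {
    double lhs = getWM(C, i, u), rhs = getWM(C, u + 1, j);
    if (std::isfinite(lhs) && std::isfinite(rhs) &&
        std::fabs(lhs + rhs - wm) < EPS) {
      trace_WM(C, i, u, partner);
      trace_WM(C, u + 1, j, partner);
      return;
    }
  }
  stop("internal traceback failure (WM)");
}

static void trace_V(FoldCtx &C, int i, int j, std::vector<int> &partner) {
  partner[i] = j; partner[j] = i;
  double v = getV(C, i, j);
  // interior extensions first (prefer continued pairing on ties)
  for (int k = i + 1; k <= j - 2; ++k) {
    int s1 = k - i - 1;
    if (s1 > C.maxil) break;
    for (int l = j - 1; l > k; --l) {
      int s2 = j - l - 1;
      if (s1 + s2 > C.maxil) break;
      double inner = getV(C, k, l);
      if (!std::isfinite(inner)) continue;
      double loop;
      if (s1 == 0 && s2 == 0) loop = C.stackE(C.pc(i, j), C.pc(k, l));
      else if (s1 == 0 || s2 == 0) loop = C.bu[s1 + s2 - 1];
      else loop = C.il[s1 + s2 - 1];
      if (std::fabs(inner + loop - v) < EPS) {
        trace_V(C, k, l, partner);
        return;
      }
    }
  }
  if (std::fabs(C.hp[j - i - 1 - 1] - v) < EPS) return;   // hairpin
  for (int u = i + 1; u <= j - 2; ++u) {
    double lhs = getWM(C, i + 1, u), rhs = getWM(C, u + 1, j - 1);
    if (std::isfinite(lhs) && std::isfinite(rhs) &&
        std::fabs(C.a + C.b + lhs + rhs - v) < EPS) {
      trace_WM(C, i + 1, u, partner);
      trace_WM(C, u + 1, j - 1, partner);
      return;
    }
  }
  stop("internal traceback failure (V)");
}

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(IntegerVector codes, NumericMatrix stack,
              NumericVector hairpin, NumericVector bulge,
              NumericVector internal, double ml_close, double ml_branch,
              double ml_unpaired, int min_hairpin, int max_internal) {
  FoldCtx C;
  C.n = codes.size();
  C.code.assign(codes.begin(), codes.end());
  C.stack = stack.begin();
  C.hp = hairpin.begin(); C.bu = bulge.begin(); C.il = internal.begin();
  C.a = ml_close; C.b = ml_branch; C.c = ml_unpaired;
  C.minh = min_hairpin; C.maxil = max_internal;
  fill_tables(C);
  double dG = C.W[C.n];
  // exterior traceback: leave j unpaired on exact ties, else smallest i pairs
  std::vector<int> partner(C.n, -1);
  int j = C.n - 1;
  while (j >= 0) {
    double w = C.W[j + 1];
    if (std::fabs(C.W[j] - w) < EPS) { j -= 1; continue; }
    bool done = false;
    for (int i = 0; i <= j && !done; ++i) {
      double v = getV(C, i, j);
      if (std::isfinite(v) && std::fabs(C.W[i] + v - w) < EPS) {
        trace_V(C, i, j, partner);
        j = i - 1;
        done = true;
      }
    }
    if (!done) stop("internal traceback failure (W)");
  }
  IntegerVector p(C.n);
  for (int i = 0; i < C.n; ++i) p[i] = partner[i] + 1;  // 1-based, 0 = unpaired
  return List::create(_["partner"] = p, _["dG"] = dG);
}
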