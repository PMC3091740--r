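#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Brute-force minimum-free-energy oracle: depth-first enumeration of every
// nested structure (minimum hairpin loop, canonical + GU pairs), scoring
// each *complete* structure by explicit loop decomposition. Shares only the
// parameter tables with the dynamic programme in fold.cpp, not its
// recursions; intended for cross-validation on short sequences.

static inline int pc2(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

namespace {

struct OracleCtx {
  int n, minh;
  std::vector<int> code;
  const double *stack, *hp, *bu, *il;
  double a, b, c;
  std::vector<int> partner;
  double best;
  std::vector<int> best_partner;
  double n_structures;
};

// score a complete structure by loop decomposition (independent of the DP)
double score_structure(const OracleCtx &C) {
  double total = 0.0;
  for (int i = 0; i < C.n; ++i) {
    int j = C.partner[i];
    if (j <= i) continue;
    int nchild = 0, unpaired = 0, k = i + 1;
    int ck = -1, cl = -1;
    while (k < j) {
      if (C.partner[k] > k) {
        if (nchild == 0) { ck = k; cl = C.partner[k]; }
        ++nchild;
        k = C.partner[k] + 1;
      } else { ++unpaired; ++k; }
    }
    if (nchild == 0) {
      total += C.hp[j - i - 1 - 1];
    } else if (nchild == 1) {
      int s1 = ck - i - 1, s2 = j - cl - 1;
      if (s1 == 0 && s2 == 0)
        total += C.stack[(pc2(C.code[ck], C.code[cl]) - 1) * 6 +
                         (pc2(C.code[i], C.code[j]) - 1)];
      else if (s1 == 0 || s2 == 0) total += C.bu[s1 + s2 - 1];
      else total += C.il[s1 + s2 - 1];
    } else {
      total += C.a + C.b * (nchild + 1) + C.c * unpaired;
    }
  }
  return total;
}

// enumerate over region list expressed as a work stack of (lo, hi) intervals;
// the stack is restored to its entry state before returning
void enumerate(OracleCtx &C, std::vector<std::pair<int,int> > &regions) {
  // set aside exhausted regions to find the first non-empty one
  std::vector<std::pair<int,int> > saved;
  while (!regions.empty() && regions.back().first > regions.back().second) {
    saved.push_back(regions.back());
    regions.pop_back();
  }
  if (regions.empty()) {
    C.n_structures += 1;
    double e = score_structure(C);
    if (e < C.best - 1e-12) { C.best = e; C.best_partner = C.partner; }
  } else {
    std::pair<int,int> reg = regions.back();
    regions.pop_back();
    int i = reg.first, hi = reg.second;
    // option 1: i unpaired
    regions.push_back(std::make_pair(i + 1, hi));
    enumerate(C, regions);
    regions.pop_back();
    // option 2: i paired with k
    for (int k = i + C.minh + 1; k <= hi; ++k) {
      if (pc2(C.code[i], C.code[k]) == 0) continue;
      C.partner[i] = k; C.partner[k] = i;
      regions.push_back(std::make_pair(k + 1, hi));
      regions.push_back(std::make_pair(i + 1, k - 1));
      enumerate(C, regions);
      regions.pop_back();
      regions.pop_back();
      C.partner[i] = -1; C.partner[k] = -1;
    }
    regions.push_back(reg);
  }
  for (std::vector<std::pair<int,int> >::reverse_iterator it = saved.rbegin();
       it != saved.rend(); ++it)
    regions.push_back(*it);
}

} // namespace

// [[Rcpp::export(name = ".enum_mfe_cpp")]]
List enum_mfe_cpp(IntegerVector codes, NumericMatrix stack,
                  NumericVector hairpin, NumericVector bulge,
                  NumericVector internal, double ml_close, double ml_branch,
                  double ml_unpaired, int min_hairpin) {
  OracleCtx C;
  C.n = codes.size();
  C.minh = min_hairpin;
  C.code.assign(codes.begin(), codes.end());
  C.stack = stack.begin();
  C.hp = hairpin.begin(); C.bu = bulge.begin(); C.il = internal.begin();
  C.a = ml_close; C.b = ml_branch; C.c = ml_unpaired;
  C.partner.assign(C.n, -1);
  C.best = 0.0;
  C.best_partner.assign(C.n, -1);
  C.n_structures = 0.0;
  std::vector<std::pair<int,int> > regions;
  regions.push_back(std::make_pair(0, C.n - 1));
  enumerate(C, regions);
  IntegerVector p(C.n);
  for (int i = 0; i < C.n; ++i) p[i] = C.best_partner[i] + 1;
  return List::create(_["dG"] = C.best, _["partner"] = p,
                      _["n_structures"] = C.n_structures);
}
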