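// Zuker-style dynamic programming over the hybrid (thermodynamic +
// network) loop-decomposable score, with optional per-pair bonuses for
// loss-augmented inference.  Indices are 0-based internally; the R
// surface is 1-based.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e30;

// base codes: A=1, C=2, G=3, U=4, N=5
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 1;  // AU
  if (a == 4 && b == 1) return 2;  // UA
  if (a == 2 && b == 3) return 3;  // CG
  if (a == 3 && b == 2) return 4;  // GC
  if (a == 3 && b == 4) return 5;  // GU
  if (a == 4 && b == 3) return 6;  // UG
  return 0;
}
static inline bool is_augu(int pt) {
  return pt == 1 || pt == 2 || pt == 5 || pt == 6;
}

struct Thermo {
  bool use;
  std::vector<double> stack;     // 6x6 column-major
  std::vector<double> hairpin, bulge, internal_;  // index len-1, length 30
  std::vector<double> tm;        // 6x4x4 column-major [pt, a, b]
  double mb_a, mb_b, mb_c, au, extrap;

  double st(int po, int pi) const { return stack[(po - 1) + 6 * (pi - 1)]; }
  double mis(int pt, int a, int b) const {
    if (a == 5 || b == 5) return 0.0;
    return tm[(pt - 1) + 6 * (a - 1) + 24 * (b - 1)];
  }
  double aupen(int pt) const { return is_augu(pt) ? au : 0.0; }
  double len_init(const std::vector<double>& tab, int len, int mn) const {
    if (len < mn) len = mn;
    int mx = (int)tab.size();
    if (len <= mx) return tab[len - 1];
    return tab[mx - 1] + extrap * std::log((double)len / mx);
  }
};

struct DP {
  int L, min_hairpin, max_span;
  bool allow_lonely;
  std::vector<int> code, ptype;  // ptype cached per (i,j)
  const NumericMatrix &Ss, &So, &Sc, &Su, &bonus;
  Thermo th;
  std::vector<double> Vp, Vnp, MB, MB2, W, cuv, cupre;
  std::vector<std::pair<int, int>> out;

  DP(const IntegerVector& codes, const NumericMatrix& s, const NumericMatrix& o,
     const NumericMatrix& c, const NumericMatrix& u, const NumericMatrix& b,
     Thermo t, int mh, int ms, bool lonely)
      : L(codes.size()), min_hairpin(mh), max_span(ms), allow_lonely(lonely),
        Ss(s), So(o), Sc(c), Su(u), bonus(b), th(t) {
    code.resize(L);
    for (int i = 0; i < L; ++i) code[i] = codes[i];
    ptype.assign((size_t)L * L, 0);
    for (int i = 0; i < L; ++i)
      for (int j = i + 1; j < L; ++j)
        ptype[i + (size_t)L * j] = pair_type(code[i], code[j]);
    Vp.assign((size_t)L * L, NEG);
    Vnp.assign((size_t)L * L, NEG);
    MB.assign((size_t)L * L, NEG);
    MB2.assign((size_t)L * L, NEG);
    W.assign(L + 1, 0.0);
    cuv.resize(L);
    cupre.resize(L + 1);
    cupre[0] = 0.0;
    for (int t2 = 0; t2 < L; ++t2) {
      cuv[t2] = Su(t2, t2) - (th.use ? th.mb_c : 0.0);
      cupre[t2 + 1] = cupre[t2] + cuv[t2];
    }
  }

  inline double& at(std::vector<double>& M, int i, int j) {
    return M[i + (size_t)L * j];
  }
  inline double rd(const std::vector<double>& M, int i, int j) const {
    return M[i + (size_t)L * j];
  }
  inline int pt(int i, int j) const { return ptype[i + (size_t)L * j]; }
  inline bool pairable(int i, int j) const {
    return pt(i, j) > 0 && j - i - 1 >= min_hairpin;
  }
  // sum of multibranch unpaired terms over positions a..b inclusive
  inline double cusum(int a, int b) const {
    if (b < a) return 0.0;
    return cupre[b + 1] - cupre[a];
  }
  inline double vin(int i, int j) const {   // inner of a stacked pair
    double a = rd(Vp, i, j), b = rd(Vnp, i, j);
    return a > b ? a : b;
  }
  inline double vatt(int i, int j) const {  // helix attach point
    if (!allow_lonely) return rd(Vp, i, j);
    return vin(i, j);
  }

  double hairpin_term(int i, int j) const {
    double v = Sc(i, j);
    int len = j - i - 1;
    if (len >= 1) v += Su(i + 1, j - 1);
    if (th.use) {
      int p = pt(i, j);
      double e = th.len_init(th.hairpin, len, 3) + th.aupen(p);
      if (len >= 1) e += th.mis(p, code[i + 1], code[j - 1]);
      v -= e;
    }
    return v;
  }
  double stack_term(int i, int j) const {
    double v = Ss(i, j);
    if (th.use) v -= th.st(pt(i, j), pt(i + 1, j - 1));
    return v;
  }
  // two-sided loop between closing (i,j) and inner (k,l); not a stack
  double int_term(int i, int j, int k, int l) const {
    int n1 = k - i - 1, n2 = j - l - 1;
    double v = Sc(i, j) + So(k - 1, l + 1);
    if (n1 > 0) v += Su(i + 1, k - 1);
    if (n2 > 0) v += Su(l + 1, j - 1);
    if (th.use) {
      int pc = pt(i, j), pi = pt(k, l);
      double e;
      if (n1 == 0 || n2 == 0) {
        e = th.len_init(th.bulge, n1 + n2, 1);
      } else {
        e = th.len_init(th.internal_, n1 + n2, 2) +
            th.mis(pc, code[i + 1], code[j - 1]) +
            th.mis(pair_type(code[l], code[k]), code[l + 1], code[k - 1]);
      }
      e += th.aupen(pc) + th.aupen(pi);
      v -= e;
    }
    return v;
  }
  double mb_close(int i, int j) const {
    double v = Sc(i, j);
    if (th.use) v -= th.mb_a + th.mb_b + th.aupen(pt(i, j));
    return v;
  }
  // branch (k,l) inside a multibranch loop
  double branch(int k, int l) const {
    double v = vatt(k, l) + So(k > 0 ? k - 1 : 0, l < L - 1 ? l + 1 : L - 1);
    if (th.use) v -= th.mb_b + th.aupen(pt(k, l));
    return v;
  }
  // branch (k,l) in the external loop
  double branch_ext(int k, int l) const {
    double v = vatt(k, l) + So(k > 0 ? k - 1 : 0, l < L - 1 ? l + 1 : L - 1);
    if (th.use) v -= th.aupen(pt(k, l));
    return v;
  }

  void fill() {
    for (int span = 1; span < L; ++span) {
      for (int i = 0; i + span < L; ++i) {
        int j = i + span;
        if (pairable(i, j)) {
          double b = bonus(i, j);
          double best = hairpin_term(i, j);
          for (int k = i + 1; k < j; ++k) {
            int n1 = k - i - 1;
            if (n1 > max_span) break;
            for (int l = j - 1; l > k; --l) {
              int n2 = j - l - 1;
              if (n1 + n2 > max_span) break;
              if (n1 == 0 && n2 == 0) continue;  // stack handled in Vp
              double va = vatt(k, l);
              if (va <= NEG / 2) continue;
              double cand = int_term(i, j, k, l) + va;
              if (cand > best) best = cand;
            }
          }
          if (j - i >= 2 && rd(MB2, i + 1, j - 1) > NEG / 2) {
            double cand = mb_close(i, j) + rd(MB2, i + 1, j - 1);
            if (cand > best) best = cand;
          }
          at(Vnp, i, j) = best + b;
          if (j - i >= 2) {
            double vi = vin(i + 1, j - 1);
            if (vi > NEG / 2) at(Vp, i, j) = stack_term(i, j) + vi + b;
          }
        }
        // multibranch segment accumulators over [i, j]
        {
          double best = NEG, best2 = NEG;
          if (j > i) {
            if (rd(MB, i, j - 1) > NEG / 2) best = rd(MB, i, j - 1) + cuv[j];
            if (rd(MB2, i, j - 1) > NEG / 2) best2 = rd(MB2, i, j - 1) + cuv[j];
          }
          for (int k = i; k <= j - min_hairpin - 1; ++k) {
            if (!pairable(k, j)) continue;
            double va = vatt(k, j);
            if (va <= NEG / 2) continue;
            double br = branch(k, j);
            double cand = cusum(i, k - 1) + br;  // everything left unpaired
            if (cand > best) best = cand;
            if (k > i && rd(MB, i, k - 1) > NEG / 2) {
              double c2 = rd(MB, i, k - 1) + br;
              if (c2 > best) best = c2;
              if (c2 > best2) best2 = c2;
            }
          }
          at(MB, i, j) = best;
          at(MB2, i, j) = best2;
        }
      }
    }
    // external loop, W[j] = best score of prefix 1..j (1-based)
    W[0] = 0.0;
    for (int j = 1; j <= L; ++j) {
      double best = W[j - 1] + Su(j - 1, j - 1);
      for (int k = 1; k <= j; ++k) {
        double va = vatt(k - 1, j - 1);
        if (va <= NEG / 2) continue;
        double cand = W[k - 1] + branch_ext(k - 1, j - 1);
        if (cand > best) best = cand;
      }
      W[j] = best;
    }
  }

  // ---- traceback; candidates re-evaluated with identical expressions so
  // exact floating-point equality identifies the chosen branch.  Pairing
  // is preferred over leaving a base unpaired; among pairs, smaller i
  // then smaller j wins.
  void trace_W(int j) {
    if (j == 0) return;
    for (int k = 1; k <= j; ++k) {
      if (vatt(k - 1, j - 1) <= NEG / 2) continue;
      if (W[k - 1] + branch_ext(k - 1, j - 1) == W[j]) {
        trace_W(k - 1);
        trace_V(k - 1, j - 1, false);
        return;
      }
    }
    trace_W(j - 1);
  }

  void trace_V(int i, int j, bool inner_of_stack) {
    out.push_back(std::make_pair(i, j));
    double vp = rd(Vp, i, j), vnp = rd(Vnp, i, j);
    double target;
    if (inner_of_stack || allow_lonely) {
      target = vp > vnp ? vp : vnp;
    } else {
      target = vp;
    }
    if (vp > NEG / 2 && vp == target) {  // prefer helix continuation
      trace_V(i + 1, j - 1, true);
      return;
    }
    double b = bonus(i, j);
    // internal / bulge loops
    for (int k = i + 1; k < j; ++k) {
      int n1 = k - i - 1;
      if (n1 > max_span) break;
      for (int l = j - 1; l > k; --l) {
        int n2 = j - l - 1;
        if (n1 + n2 > max_span) break;
        if (n1 == 0 && n2 == 0) continue;
        double va = vatt(k, l);
        if (va <= NEG / 2) continue;
        if (int_term(i, j, k, l) + va + b == vnp) {
          trace_V(k, l, false);
          return;
        }
      }
    }
    if (j - i >= 2 && rd(MB2, i + 1, j - 1) > NEG / 2 &&
        mb_close(i, j) + rd(MB2, i + 1, j - 1) + b == vnp) {
      trace_MB(i + 1, j - 1, true);
      return;
    }
    // hairpin: nothing further to trace
  }

  void trace_MB(int i, int j, bool need2) {
    double target = need2 ? rd(MB2, i, j) : rd(MB, i, j);
    for (int k = i; k <= j - min_hairpin - 1; ++k) {
      if (!pairable(k, j)) continue;
      double va = vatt(k, j);
      if (va <= NEG / 2) continue;
      double br = branch(k, j);
      if (!need2 && cusum(i, k - 1) + br == target) {
        trace_V(k, j, false);
        return;
      }
      if (k > i && rd(MB, i, k - 1) > NEG / 2 &&
          rd(MB, i, k - 1) + br == target) {
        trace_MB(i, k - 1, false);
        trace_V(k, j, false);
        return;
      }
    }
    if (j > i) {
      double prev = need2 ? rd(MB2, i, j - 1) : rd(MB, i, j - 1);
      if (prev > NEG / 2 && prev + cuv[j] == target) {
        trace_MB(i, j - 1, need2);
        return;
      }
    }
    stop("multibranch traceback failed");  // should be unreachable
  }
};

static Thermo make_thermo(List th, bool use) {
  Thermo t;
  t.use = use;
  if (use) {
    t.stack = as<std::vector<double>>(th["stack"]);
    t.hairpin = as<std::vector<double>>(th["hairpin"]);
    t.bulge = as<std::vector<double>>(th["bulge"]);
    t.internal_ = as<std::vector<double>>(th["internal"]);
    t.tm = as<std::vector<double>>(th["tm"]);
    t.mb_a = as<double>(th["mb_a"]);
    t.mb_b = as<double>(th["mb_b"]);
    t.mb_c = as<double>(th["mb_c"]);
    t.au = as<double>(th["au"]);
    t.extrap = as<double>(th["extrap"]);
  } else {
    t.mb_a = t.mb_b = t.mb_c = t.au = t.extrap = 0.0;
  }
  return t;
}

// [[Rcpp::export]]
List dp_fold_cpp(IntegerVector codes, NumericMatrix s, NumericMatrix o,
                 NumericMatrix c, NumericMatrix u, NumericMatrix bonus,
                 bool use_thermo, List thermo, int min_hairpin,
                 int max_internal_span, bool allow_lonely) {
  DP dp(codes, s, o, c, u, bonus, make_thermo(thermo, use_thermo),
        min_hairpin, max_internal_span, allow_lonely);
  dp.fill();
  dp.trace_W(dp.L);
  int n = dp.out.size();
  IntegerMatrix pairs(n, 2);
  for (int r = 0; r < n; ++r) {
    pairs(r, 0) = dp.out[r].first + 1;
    pairs(r, 1) = dp.out[r].second + 1;
  }
  return List::create(_["pairs"] = pairs, _["score"] = dp.W[dp.L]);
}
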