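// Sequence-to-contact-score network: embedding -> N1 residual 1D-conv
// blocks (kernels 5, 3) -> N2 BiLSTM layers -> pairwise concatenation to
// an L x L x d tensor -> N3 residual 2D-conv blocks (kernels 5x5, 3x3)
// -> shared 3-layer MLP emitting the four folding scores (s, o, c, u)
// per position pair.  Layer normalization sits after each conv/recurrent
// layer, before the CELU activation; dropout is inverted (eval mode is
// the identity).  Hand-written backward pass for max-margin training;
// dropout masks are drawn from R's RNG so runs are reproducible under
// set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

static const double LN_EPS = 1e-5;

struct Cfg {
  int d, N1, N2, N3, h, H;
  double dropout;
  Cfg(List cfg) {
    d = as<int>(cfg["d"]);
    N1 = as<int>(cfg["N1"]);
    N2 = as<int>(cfg["N2"]);
    N3 = as<int>(cfg["N3"]);
    h = as<int>(cfg["h"]);
    dropout = as<double>(cfg["dropout"]);
    if (d < 2 || d % 2 != 0) stop("d must be even and >= 2");
    if (N1 < 0 || N2 < 0 || N3 < 0 || h < 1) stop("bad network config");
    H = d / 2;
  }
};

// sequential reader over the flat weight vector; order must match
// weight_layout() on the R side
struct Cursor {
  const double* p;
  size_t left;
  Cursor(const NumericVector& w) : p(REAL(w)), left(w.size()) {}
  mat m(int r, int c) {
    size_t n = (size_t)r * c;
    if (n > left) stop("weight vector too short");
    mat out(p, r, c);  // copy
    p += n;
    left -= n;
    return out;
  }
  vec v(int n) {
    if ((size_t)n > left) stop("weight vector too short");
    vec out(p, n);
    p += n;
    left -= (size_t)n;
    return out;
  }
};
// sequential writer used to flatten gradients in the same order
struct Writer {
  double* p;
  size_t left;
  Writer(NumericVector& w) : p(REAL(w)), left(w.size()) {}
  void put(const mat& m) {
    if (m.n_elem > left) stop("gradient layout overflow");
    std::copy(m.memptr(), m.memptr() + m.n_elem, p);
    p += m.n_elem;
    left -= m.n_elem;
  }
  void put(const vec& v) {
    if (v.n_elem > left) stop("gradient layout overflow");
    std::copy(v.memptr(), v.memptr() + v.n_elem, p);
    p += v.n_elem;
    left -= v.n_elem;
  }
};

static inline mat celu(const mat& x) {
  mat out(x.n_rows, x.n_cols);
  for (size_t k = 0; k < x.n_elem; ++k)
    out(k) = x(k) > 0 ? x(k) : std::expm1(x(k));
  return out;
}
static inline mat celu_grad(const mat& x) {
  mat g(x.n_rows, x.n_cols);
  for (size_t k = 0; k < x.n_elem; ++k) g(k) = x(k) > 0 ? 1.0 : std::exp(x(k));
  return g;
}

// row-wise layer normalization over the channel dimension
static mat ln_forward(const mat& z, const vec& g, const vec& b) {
  mat out(z.n_rows, z.n_cols);
  for (size_t t = 0; t < z.n_rows; ++t) {
    rowvec r = z.row(t);
    double mu = arma::mean(r);
    double sd = std::sqrt(arma::mean(arma::square(r - mu)) + LN_EPS);
    out.row(t) = ((r - mu) / sd) % g.t() + b.t();
  }
  return out;
}
static mat ln_backward(const mat& z, const vec& g, const mat& gy,
                       vec& gGain, vec& gBias) {
  mat gx(z.n_rows, z.n_cols);
  for (size_t t = 0; t < z.n_rows; ++t) {
    rowvec r = z.row(t);
    double mu = arma::mean(r);
    double sd = std::sqrt(arma::mean(arma::square(r - mu)) + LN_EPS);
    rowvec xhat = (r - mu) / sd;
    rowvec gyr = gy.row(t);
    rowvec gxh = gyr % g.t();
    double m1 = arma::mean(gxh);
    double m2 = arma::mean(gxh % xhat);
    gx.row(t) = (gxh - m1 - xhat * m2) / sd;
    gGain += (gyr % xhat).t();
    gBias += gyr.t();
  }
  return gx;
}

static mat dropout_mask(int r, int c, double p, bool training) {
  mat m(r, c, arma::fill::ones);
  if (training && p > 0) {
    double keep = 1.0 - p;
    for (size_t k = 0; k < m.n_elem; ++k)
      m(k) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  }
  return m;
}

// 1D im2col with zero padding: (L, K*d), patch feature (k*d + c)
static mat im2col1(const mat& x, int K) {
  int L = x.n_rows, d = x.n_cols, P = (K - 1) / 2;
  mat A(L, K * d, arma::fill::zeros);
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < K; ++k) {
      int src = t + k - P;
      if (src < 0 || src >= L) continue;
      A(t, arma::span((size_t)k * d, (size_t)k * d + d - 1)) = x.row(src);
    }
  return A;
}
static void col2im1(const mat& G, int K, mat& gx) {
  int L = gx.n_rows, d = gx.n_cols, P = (K - 1) / 2;
  for (int t = 0; t < L; ++t)
    for (int k = 0; k < K; ++k) {
      int src = t + k - P;
      if (src < 0 || src >= L) continue;
      gx.row(src) += G(t, arma::span((size_t)k * d, (size_t)k * d + d - 1));
    }
}
// 2D im2col over the (i, j) grid flattened column-major as r = i + j * L
static mat im2col2(const mat& x, int L, int K) {
  int d = x.n_cols, P = (K - 1) / 2;
  mat A((size_t)L * L, (size_t)K * K * d, arma::fill::zeros);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      size_t r = i + (size_t)j * L;
      for (int ki = 0; ki < K; ++ki) {
        int si = i + ki - P;
        if (si < 0 || si >= L) continue;
        for (int kj = 0; kj < K; ++kj) {
          int sj = j + kj - P;
          if (sj < 0 || sj >= L) continue;
          size_t f = (size_t)(ki * K + kj) * d;
          A(r, arma::span(f, f + d - 1)) = x.row(si + (size_t)sj * L);
        }
      }
    }
  return A;
}
static void col2im2(const mat& G, int L, int K, mat& gx) {
  int d = gx.n_cols, P = (K - 1) / 2;
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      size_t r = i + (size_t)j * L;
      for (int ki = 0; ki < K; ++ki) {
        int si = i + ki - P;
        if (si < 0 || si >= L) continue;
        for (int kj = 0; kj < K; ++kj) {
          int sj = j + kj - P;
          if (sj < 0 || sj >= L) continue;
          size_t f = (size_t)(ki * K + kj) * d;
          gx.row(si + (size_t)sj * L) += G(r, arma::span(f, f + d - 1));
        }
      }
    }
}

struct LstmCache { mat ig, fg, gg, og, cc, hh; };

static mat lstm_dir(const mat& x, const mat& Wx, const mat& Wh, const vec& b,
                    bool reverse, LstmCache& cc) {
  int L = x.n_rows, H = Wh.n_cols;
  cc.ig.set_size(L, H); cc.fg.set_size(L, H); cc.gg.set_size(L, H);
  cc.og.set_size(L, H); cc.cc.set_size(L, H); cc.hh.set_size(L, H);
  vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (int s = 0; s < L; ++s) {
    int t = reverse ? L - 1 - s : s;
    vec z = Wx * x.row(t).t() + Wh * h + b;
    vec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + arma::exp(-z.subvec(H, 2 * H - 1)));
    vec g = arma::tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + arma::exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    cc.ig.row(t) = i.t(); cc.fg.row(t) = f.t(); cc.gg.row(t) = g.t();
    cc.og.row(t) = o.t(); cc.cc.row(t) = c.t(); cc.hh.row(t) = h.t();
  }
  return cc.hh;
}

static mat lstm_dir_backward(const mat& x, const mat& Wx, const mat& Wh,
                             bool reverse, const LstmCache& cc,
                             const mat& gh_in, mat& gWx, mat& gWh, vec& gb) {
  int L = x.n_rows, H = Wh.n_cols;
  mat gx(L, x.n_cols, arma::fill::zeros);
  vec gh_next(H, arma::fill::zeros), gc_next(H, arma::fill::zeros);
  for (int s = L - 1; s >= 0; --s) {
    int t = reverse ? L - 1 - s : s;
    int tprev = reverse ? t + 1 : t - 1;
    bool has_prev = reverse ? (t + 1 < L) : (t - 1 >= 0);
    vec i = cc.ig.row(t).t(), f = cc.fg.row(t).t(), g = cc.gg.row(t).t(),
        o = cc.og.row(t).t(), c = cc.cc.row(t).t();
    vec cprev = has_prev ? vec(cc.cc.row(tprev).t()) : vec(H, arma::fill::zeros);
    vec hprev = has_prev ? vec(cc.hh.row(tprev).t()) : vec(H, arma::fill::zeros);
    vec gh = gh_in.row(t).t() + gh_next;
    vec tc = arma::tanh(c);
    vec gcv = gh % o % (1.0 - arma::square(tc)) + gc_next;
    vec gz(4 * H);
    gz.subvec(0, H - 1) = (gcv % g) % i % (1.0 - i);
    gz.subvec(H, 2 * H - 1) = (gcv % cprev) % f % (1.0 - f);
    gz.subvec(2 * H, 3 * H - 1) = (gcv % i) % (1.0 - arma::square(g));
    gz.subvec(3 * H, 4 * H - 1) = (gh % tc) % o % (1.0 - o);
    gWx += gz * x.row(t);
    gWh += gz * hprev.t();
    gb += gz;
    gx.row(t) += (Wx.t() * gz).t();
    gh_next = Wh.t() * gz;
    gc_next = gcv % f;
  }
  return gx;
}

struct ConvCache { mat in, z, a, mask; };

// residual conv layer: out = in + dropout(celu(ln(conv(in))))
static mat conv_layer_fwd(const mat& x, int L, bool two_d, int K,
                          const mat& W, const vec& b, const vec& lg,
                          const vec& lb, double p, bool training,
                          ConvCache& cache) {
  mat A = two_d ? im2col2(x, L, K) : im2col1(x, K);
  mat z = A * W;
  z.each_row() += b.t();
  mat a = ln_forward(z, lg, lb);
  mat mask = dropout_mask(a.n_rows, a.n_cols, p, training);
  cache.in = x; cache.z = z; cache.a = a; cache.mask = mask;
  return x + celu(a) % mask;
}
static mat conv_layer_bwd(const ConvCache& cc, int L, bool two_d, int K,
                          const mat& W, const mat& gout, mat& gW, vec& gb,
                          vec& glg, vec& glb, const vec& lg) {
  mat g1 = gout % cc.mask % celu_grad(cc.a);
  mat gz = ln_backward(cc.z, lg, g1, glg, glb);
  mat A = two_d ? im2col2(cc.in, L, K) : im2col1(cc.in, K);
  gW += A.t() * gz;
  gb += arma::sum(gz, 0).t();
  mat Gcol = gz * W.t();
  mat gin(cc.in.n_rows, cc.in.n_cols, arma::fill::zeros);
  if (two_d) col2im2(Gcol, L, K, gin); else col2im1(Gcol, K, gin);
  return gout + gin;  // residual skip + conv path
}

// [[Rcpp::export]]
double nn_param_count_cpp(List cfg_) {
  Cfg c(cfg_);
  double n = 0;
  n += 6.0 * c.d;  // embedding over {A, C, G, U, N, PAD}
  for (int b = 0; b < c.N1; ++b) {
    n += 5.0 * c.d * c.d + c.d + 2.0 * c.d;
    n += 3.0 * c.d * c.d + c.d + 2.0 * c.d;
  }
  for (int b = 0; b < c.N2; ++b)
    n += 2.0 * (4.0 * c.H * (c.d + c.H + 1)) + 2.0 * c.d;
  for (int b = 0; b < c.N3; ++b) {
    n += 25.0 * c.d * c.d + c.d + 2.0 * c.d;
    n += 9.0 * c.d * c.d + c.d + 2.0 * c.d;
  }
  n += 1.0 * c.d * c.h + c.h + 1.0 * c.h * c.h + c.h + 4.0 * c.h + 4;
  return n;
}

struct Net {
  Cfg cfg;
  mat E;
  std::vector<mat> c1W; std::vector<vec> c1b, c1lg, c1lb;
  std::vector<mat> lWx, lWh; std::vector<vec> lbias;
  std::vector<vec> l2lg, l2lb;
  std::vector<mat> c2W; std::vector<vec> c2b, c2lg, c2lb;
  mat W1, W2, W3; vec b1, b2, b3;

  Net(List cfg_, const NumericVector& w) : cfg(cfg_) {
    if ((double)w.size() != nn_param_count_cpp(cfg_))
      stop("weight vector length does not match config");
    Cursor cur(w);
    int d = cfg.d, H = cfg.H;
    E = cur.m(6, d);
    for (int b = 0; b < cfg.N1; ++b)
      for (int K : {5, 3}) {
        c1W.push_back(cur.m(K * d, d));
        c1b.push_back(cur.v(d));
        c1lg.push_back(cur.v(d));
        c1lb.push_back(cur.v(d));
      }
    for (int b = 0; b < cfg.N2; ++b) {
      for (int dir = 0; dir < 2; ++dir) {
        lWx.push_back(cur.m(4 * H, d));
        lWh.push_back(cur.m(4 * H, H));
        lbias.push_back(cur.v(4 * H));
      }
      l2lg.push_back(cur.v(d));
      l2lb.push_back(cur.v(d));
    }
    for (int b = 0; b < cfg.N3; ++b)
      for (int K : {5, 3}) {
        c2W.push_back(cur.m(K * K * d, d));
        c2b.push_back(cur.v(d));
        c2lg.push_back(cur.v(d));
        c2lb.push_back(cur.v(d));
      }
    W1 = cur.m(d, cfg.h); b1 = cur.v(cfg.h);
    W2 = cur.m(cfg.h, cfg.h); b2 = cur.v(cfg.h);
    W3 = cur.m(cfg.h, 4); b3 = cur.v(4);
    if (cur.left != 0) stop("weight vector has trailing elements");
  }
};

struct FwdState {
  std::vector<ConvCache> cc1, cc2;
  std::vector<mat> lstm_in, lstm_z, lstm_a, lstm_mask;
  std::vector<LstmCache> lcF, lcB;
  mat Y, F, z1, h1, z2, h2, outm;
};

static void forward(const Net& net, const IntegerVector& codes, bool training,
                    FwdState& st) {
  const Cfg& cfg = net.cfg;
  int L = codes.size(), d = cfg.d, H = cfg.H;
  mat x(L, d);
  for (int t = 0; t < L; ++t) {
    int code = codes[t];
    if (code < 1 || code > 5) stop("bad residue code");
    x.row(t) = net.E.row(code - 1);
  }
  int li = 0;
  st.cc1.resize(2 * cfg.N1);
  for (int b = 0; b < cfg.N1; ++b)
    for (int K : {5, 3}) {
      x = conv_layer_fwd(x, L, false, K, net.c1W[li], net.c1b[li],
                         net.c1lg[li], net.c1lb[li], cfg.dropout, training,
                         st.cc1[li]);
      ++li;
    }
  st.lstm_in.resize(cfg.N2); st.lcF.resize(cfg.N2); st.lcB.resize(cfg.N2);
  st.lstm_z.resize(cfg.N2); st.lstm_a.resize(cfg.N2);
  st.lstm_mask.resize(cfg.N2);
  for (int b = 0; b < cfg.N2; ++b) {
    st.lstm_in[b] = x;
    mat hf = lstm_dir(x, net.lWx[2 * b], net.lWh[2 * b], net.lbias[2 * b],
                      false, st.lcF[b]);
    mat hb = lstm_dir(x, net.lWx[2 * b + 1], net.lWh[2 * b + 1],
                      net.lbias[2 * b + 1], true, st.lcB[b]);
    mat z = arma::join_rows(hf, hb);
    st.lstm_z[b] = z;
    mat a = ln_forward(z, net.l2lg[b], net.l2lb[b]);
    st.lstm_a[b] = a;
    mat mask = dropout_mask(L, d, cfg.dropout, training);
    st.lstm_mask[b] = mask;
    x = celu(a) % mask;
  }
  st.Y = x;
  // Concat 2D: row r = i + j * L holds [half1 of position i, half2 of j]
  mat P((size_t)L * L, d);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      size_t r = i + (size_t)j * L;
      P(r, arma::span(0, H - 1)) = x(i, arma::span(0, H - 1));
      P(r, arma::span(H, d - 1)) = x(j, arma::span(H, d - 1));
    }
  li = 0;
  st.cc2.resize(2 * cfg.N3);
  mat q = P;
  for (int b = 0; b < cfg.N3; ++b)
    for (int K : {5, 3}) {
      q = conv_layer_fwd(q, L, true, K, net.c2W[li], net.c2b[li],
                         net.c2lg[li], net.c2lb[li], cfg.dropout, training,
                         st.cc2[li]);
      ++li;
    }
  st.F = q;
  st.z1 = q * net.W1; st.z1.each_row() += net.b1.t();
  st.h1 = celu(st.z1);
  st.z2 = st.h1 * net.W2; st.z2.each_row() += net.b2.t();
  st.h2 = celu(st.z2);
  st.outm = st.h2 * net.W3; st.outm.each_row() += net.b3.t();
}

static List scores_to_list(const mat& outm, int L) {
  NumericMatrix s(L, L), o(L, L), c(L, L), u(L, L);
  size_t n = (size_t)L * L;
  std::copy(outm.colptr(0), outm.colptr(0) + n, s.begin());
  std::copy(outm.colptr(1), outm.colptr(1) + n, o.begin());
  std::copy(outm.colptr(2), outm.colptr(2) + n, c.begin());
  std::copy(outm.colptr(3), outm.colptr(3) + n, u.begin());
  return List::create(_["s"] = s, _["o"] = o, _["c"] = c, _["u"] = u);
}

// [[Rcpp::export]]
List nn_forward_cpp(IntegerVector codes, List cfg_, NumericVector w,
                    bool training) {
  if (codes.size() < 1) stop("L must be >= 1");
  for (double x : w)
    if (!std::isfinite(x)) stop("non-finite network weight");
  Net net(cfg_, w);
  FwdState st;
  forward(net, codes, training, st);
  return scores_to_list(st.outm, codes.size());
}

// forward pass that additionally returns an opaque cache (the layer
// activations and the dropout masks actually drawn), so that a later
// backward pass replays exactly the same stochastic network
// [[Rcpp::export]]
List nn_forward_cache_cpp(IntegerVector codes, List cfg_, NumericVector w,
                          bool training) {
  if (codes.size() < 1) stop("L must be >= 1");
  for (double x : w)
    if (!std::isfinite(x)) stop("non-finite network weight");
  Net net(cfg_, w);
  XPtr<FwdState> ptr(new FwdState(), true);
  forward(net, codes, training, *ptr);
  List out = scores_to_list(ptr->outm, codes.size());
  out["state"] = ptr;
  return out;
}

// d(sum of g* % scores)/d(weights), flattened in layout order, using the
// cached forward state
// [[Rcpp::export]]
NumericVector nn_backward_cpp(IntegerVector codes, List cfg_, NumericVector w,
                              SEXP state, NumericMatrix gs, NumericMatrix go,
                              NumericMatrix gc, NumericMatrix gu) {
  Net net(cfg_, w);
  const Cfg& cfg = net.cfg;
  int L = codes.size(), d = cfg.d, H = cfg.H;
  XPtr<FwdState> sp(state);
  FwdState& st = *sp;
  if (st.outm.n_rows != (size_t)L * L) stop("cache does not match input");

  // owned zero gradients, parallel to Net
  mat gE(6, d, arma::fill::zeros);
  std::vector<mat> gc1W; std::vector<vec> gc1b, gc1lg, gc1lb;
  for (int b = 0; b < cfg.N1; ++b)
    for (int K : {5, 3}) {
      gc1W.push_back(mat(K * d, d, arma::fill::zeros));
      gc1b.push_back(vec(d, arma::fill::zeros));
      gc1lg.push_back(vec(d, arma::fill::zeros));
      gc1lb.push_back(vec(d, arma::fill::zeros));
    }
  std::vector<mat> glWx, glWh; std::vector<vec> glb, gl2lg, gl2lb;
  for (int b = 0; b < cfg.N2; ++b) {
    for (int dir = 0; dir < 2; ++dir) {
      glWx.push_back(mat(4 * H, d, arma::fill::zeros));
      glWh.push_back(mat(4 * H, H, arma::fill::zeros));
      glb.push_back(vec(4 * H, arma::fill::zeros));
    }
    gl2lg.push_back(vec(d, arma::fill::zeros));
    gl2lb.push_back(vec(d, arma::fill::zeros));
  }
  std::vector<mat> gc2W; std::vector<vec> gc2b, gc2lg, gc2lb;
  for (int b = 0; b < cfg.N3; ++b)
    for (int K : {5, 3}) {
      gc2W.push_back(mat(K * K * d, d, arma::fill::zeros));
      gc2b.push_back(vec(d, arma::fill::zeros));
      gc2lg.push_back(vec(d, arma::fill::zeros));
      gc2lb.push_back(vec(d, arma::fill::zeros));
    }
  mat gW1(d, cfg.h, arma::fill::zeros), gW2(cfg.h, cfg.h, arma::fill::zeros),
      gW3(cfg.h, 4, arma::fill::zeros);
  vec gb1(cfg.h, arma::fill::zeros), gb2(cfg.h, arma::fill::zeros),
      gb3(4, arma::fill::zeros);

  mat gout((size_t)L * L, 4);
  std::copy(gs.begin(), gs.end(), gout.colptr(0));
  std::copy(go.begin(), go.end(), gout.colptr(1));
  std::copy(gc.begin(), gc.end(), gout.colptr(2));
  std::copy(gu.begin(), gu.end(), gout.colptr(3));

  // MLP backward
  gW3 += st.h2.t() * gout;
  gb3 += arma::sum(gout, 0).t();
  mat gz2 = (gout * net.W3.t()) % celu_grad(st.z2);
  gW2 += st.h1.t() * gz2;
  gb2 += arma::sum(gz2, 0).t();
  mat gz1 = (gz2 * net.W2.t()) % celu_grad(st.z1);
  gW1 += st.F.t() * gz1;
  gb1 += arma::sum(gz1, 0).t();
  mat gq = gz1 * net.W1.t();

  // Block 3 backward
  for (int li = 2 * cfg.N3 - 1; li >= 0; --li) {
    int K = (li % 2 == 0) ? 5 : 3;
    gq = conv_layer_bwd(st.cc2[li], L, true, K, net.c2W[li], gq, gc2W[li],
                        gc2b[li], gc2lg[li], gc2lb[li], net.c2lg[li]);
  }
  // pair-concat backward: scatter L^2 x d grads to the two halves
  mat gY(L, d, arma::fill::zeros);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < L; ++i) {
      size_t r = i + (size_t)j * L;
      gY(i, arma::span(0, H - 1)) += gq(r, arma::span(0, H - 1));
      gY(j, arma::span(H, d - 1)) += gq(r, arma::span(H, d - 1));
    }
  // Block 2 backward
  mat gx = gY;
  for (int b = cfg.N2 - 1; b >= 0; --b) {
    mat g1 = gx % st.lstm_mask[b] % celu_grad(st.lstm_a[b]);
    mat gz = ln_backward(st.lstm_z[b], net.l2lg[b], g1, gl2lg[b], gl2lb[b]);
    mat ghf = gz.cols(0, H - 1);
    mat ghb = gz.cols(H, d - 1);
    mat gin_f = lstm_dir_backward(st.lstm_in[b], net.lWx[2 * b],
                                  net.lWh[2 * b], false, st.lcF[b], ghf,
                                  glWx[2 * b], glWh[2 * b], glb[2 * b]);
    mat gin_b = lstm_dir_backward(st.lstm_in[b], net.lWx[2 * b + 1],
                                  net.lWh[2 * b + 1], true, st.lcB[b], ghb,
                                  glWx[2 * b + 1], glWh[2 * b + 1],
                                  glb[2 * b + 1]);
    gx = gin_f + gin_b;
  }
  // Block 1 backward
  for (int li = 2 * cfg.N1 - 1; li >= 0; --li) {
    int K = (li % 2 == 0) ? 5 : 3;
    gx = conv_layer_bwd(st.cc1[li], L, false, K, net.c1W[li], gx, gc1W[li],
                        gc1b[li], gc1lg[li], gc1lb[li], net.c1lg[li]);
  }
  // embedding backward
  for (int t = 0; t < L; ++t) gE.row(codes[t] - 1) += gx.row(t);

  NumericVector grad(w.size());
  Writer wr(grad);
  wr.put(gE);
  int li1 = 0;
  for (int b = 0; b < cfg.N1; ++b)
    for (int K : {5, 3}) {
      (void)K;
      wr.put(gc1W[li1]); wr.put(gc1b[li1]); wr.put(gc1lg[li1]);
      wr.put(gc1lb[li1]);
      ++li1;
    }
  for (int b = 0; b < cfg.N2; ++b) {
    for (int dir = 0; dir < 2; ++dir) {
      wr.put(glWx[2 * b + dir]); wr.put(glWh[2 * b + dir]);
      wr.put(glb[2 * b + dir]);
    }
    wr.put(gl2lg[b]); wr.put(gl2lb[b]);
  }
  int li2 = 0;
  for (int b = 0; b < cfg.N3; ++b)
    for (int K : {5, 3}) {
      (void)K;
      wr.put(gc2W[li2]); wr.put(gc2b[li2]); wr.put(gc2lg[li2]);
      wr.put(gc2lb[li2]);
      ++li2;
    }
  wr.put(gW1); wr.put(gb1); wr.put(gW2); wr.put(gb2); wr.put(gW3); wr.put(gb3);
  if (wr.left != 0) stop("gradient layout underflow");
  return grad;
}
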