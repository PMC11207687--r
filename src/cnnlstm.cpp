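// CNN-LSTM classifier for connectivity-matrix inputs.
//
// Architecture: two conv blocks (conv 3x3 / stride 1 / pad 1 -> batch norm
// -> ReLU -> 2x2 max pool -> dropout), the second block's C2 x 13 x 13
// output read as a 13-step row sequence of C2*13 features, two stacked
// LSTM layers, and a linear softmax head.  Implemented as im2col + GEMM so
// the heavy lifting lands in BLAS; training is plain backprop-through-time
// with Adam.  All randomness (dropout masks) is drawn from R's RNG so runs
// are reproducible from set.seed().
//
// The engine is templated on the element type: single precision is the
// default for training throughput, double precision is kept for the
// finite-difference gradient checks in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

enum ParId { W1, B1, G1, BE1, W2, B2, G2, BE2,
             WX1, WH1, BZ1, WX2, WH2, BZ2, WFC, BFC, NPAR };

const char* par_names[NPAR] = {
  "conv1_w", "conv1_b", "bn1_gamma", "bn1_beta",
  "conv2_w", "conv2_b", "bn2_gamma", "bn2_beta",
  "lstm1_wx", "lstm1_wh", "lstm1_b",
  "lstm2_wx", "lstm2_wh", "lstm2_b",
  "fc_w", "fc_b"};

struct NetBase {
  virtual ~NetBase() {}
  virtual void set_weights(const Rcpp::List& w) = 0;
  virtual Rcpp::List get_weights() const = 0;
  virtual Rcpp::List get_grads() const = 0;
  virtual Rcpp::List train_epoch(const cube& x, const ivec& y,
                                 const ivec& order, int batch_size,
                                 double lr, bool use_dropout) = 0;
  virtual mat predict_probs(const cube& x, int batch_size) = 0;
  virtual double loss_grad(const cube& x, const ivec& y) = 0;
  virtual double loss_only(const cube& x, const ivec& y) = 0;
  virtual Rcpp::List forward_debug(const mat& x) = 0;
  virtual Rcpp::IntegerVector geometry() const = 0;
};

template <typename T>
struct Net : public NetBase {
  typedef Mat<T> MT;
  typedef Col<T> VT;

  int side, c1, c2, h1, h2, ncls;
  int s1, s2, f_in;
  T p1, p2;
  T bn_eps = (T)1e-5, bn_mom = (T)0.1;

  std::vector<MT> par, grad, am, av;
  long astep = 0;
  VT rm1, rv1, rm2, rv2;

  // caches for backward
  MT col1, z1n, relu1, drop1m, col2, z2n, relu2, pool2o, drop2m;
  VT istd1, istd2;
  umat argm1, argm2;
  struct LstmCache {
    std::vector<MT> gates, c, tc, h;
    const std::vector<MT>* x;
  } l1, l2;
  std::vector<MT> seq1;
  MT probs, hlast;
  ivec ybatch;

  Net(int side_, int c1_, int c2_, int h1_, int h2_, int ncls_, double p1_,
      double p2_)
      : side(side_), c1(c1_), c2(c2_), h1(h1_), h2(h2_), ncls(ncls_),
        p1((T)p1_), p2((T)p2_) {
    s1 = side / 2;
    s2 = s1 / 2;
    f_in = c2 * s2;
    par.resize(NPAR);
    par[W1].zeros(c1, 9);
    par[B1].zeros(c1, 1);
    par[G1].ones(c1, 1);
    par[BE1].zeros(c1, 1);
    par[W2].zeros(c2, c1 * 9);
    par[B2].zeros(c2, 1);
    par[G2].ones(c2, 1);
    par[BE2].zeros(c2, 1);
    par[WX1].zeros(4 * h1, f_in);
    par[WH1].zeros(4 * h1, h1);
    par[BZ1].zeros(4 * h1, 1);
    par[WX2].zeros(4 * h2, h1);
    par[WH2].zeros(4 * h2, h2);
    par[BZ2].zeros(4 * h2, 1);
    par[WFC].zeros(ncls, h2);
    par[BFC].zeros(ncls, 1);
    rm1.zeros(c1); rv1.ones(c1);
    rm2.zeros(c2); rv2.ones(c2);
    grad.resize(NPAR);
    am.resize(NPAR);
    av.resize(NPAR);
    for (int i = 0; i < NPAR; ++i) {
      am[i].zeros(par[i].n_rows, par[i].n_cols);
      av[i].zeros(par[i].n_rows, par[i].n_cols);
    }
  }

  // ---- building blocks ----

  // im2col for 3x3 / pad 1 / stride 1; x: C x (S*S*B), column index
  // (b*S + xcol)*S + yrow; offset block o = dy*3+dx at rows [o*C, o*C+C)
  MT im2col3(const MT& x, int C, int S, int B) const {
    MT out(C * 9, x.n_cols, fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int xc = 0; xc < S; ++xc) {
        const int colbase = (b * S + xc) * S;
        for (int dx = 0; dx < 3; ++dx) {
          const int sx = xc + dx - 1;
          if (sx < 0 || sx >= S) continue;
          const int srcbase = (b * S + sx) * S;
          for (int dy = 0; dy < 3; ++dy) {
            const int o = dy * 3 + dx;
            const int y0 = std::max(0, 1 - dy);
            const int y1 = std::min(S - 1, S - dy);
            out.submat(o * C, colbase + y0, o * C + C - 1, colbase + y1) =
                x.cols(srcbase + y0 + dy - 1, srcbase + y1 + dy - 1);
          }
        }
      }
    }
    return out;
  }

  MT col2im3(const MT& dcol, int C, int S, int B) const {
    MT dx(C, dcol.n_cols, fill::zeros);
    for (int b = 0; b < B; ++b) {
      for (int xc = 0; xc < S; ++xc) {
        const int colbase = (b * S + xc) * S;
        for (int dxo = 0; dxo < 3; ++dxo) {
          const int sx = xc + dxo - 1;
          if (sx < 0 || sx >= S) continue;
          const int srcbase = (b * S + sx) * S;
          for (int dy = 0; dy < 3; ++dy) {
            const int o = dy * 3 + dxo;
            const int y0 = std::max(0, 1 - dy);
            const int y1 = std::min(S - 1, S - dy);
            dx.cols(srcbase + y0 + dy - 1, srcbase + y1 + dy - 1) +=
                dcol.submat(o * C, colbase + y0, o * C + C - 1,
                            colbase + y1);
          }
        }
      }
    }
    return dx;
  }

  MT maxpool2(const MT& x, int C, int S, int B, umat& argm) const {
    const int So = S / 2;
    MT out(C, So * So * B);
    argm.set_size(C, So * So * B);
    for (int b = 0; b < B; ++b) {
      for (int xo = 0; xo < So; ++xo) {
        for (int yo = 0; yo < So; ++yo) {
          const uword oc = (uword)(b * So + xo) * So + yo;
          const uword i00 = (uword)(b * S + 2 * xo) * S + 2 * yo;
          const uword i10 = (uword)(b * S + 2 * xo + 1) * S + 2 * yo;
          for (int c = 0; c < C; ++c) {
            T v = x(c, i00); uword best = i00;
            if (x(c, i00 + 1) > v) { v = x(c, i00 + 1); best = i00 + 1; }
            if (x(c, i10) > v) { v = x(c, i10); best = i10; }
            if (x(c, i10 + 1) > v) { v = x(c, i10 + 1); best = i10 + 1; }
            out(c, oc) = v;
            argm(c, oc) = best;
          }
        }
      }
    }
    return out;
  }

  MT maxpool2_back(const MT& dout, const umat& argm, int C,
                   uword n_in_cols) const {
    MT dx(C, n_in_cols, fill::zeros);
    for (uword j = 0; j < dout.n_cols; ++j) {
      for (int c = 0; c < C; ++c) dx(c, argm(c, j)) += dout(c, j);
    }
    return dx;
  }

  MT bn_train(const MT& z, ParId g, ParId be, VT& rmean, VT& rvar, MT& znorm,
              VT& istd) {
    const T n = (T)z.n_cols;
    VT mu = mean(z, 1);
    VT va = var(z, 1, 1);
    istd = (T)1 / sqrt(va + bn_eps);
    znorm = z;
    znorm.each_col() -= mu;
    znorm.each_col() %= istd;
    rmean = (1 - bn_mom) * rmean + bn_mom * mu;
    rvar = (1 - bn_mom) * rvar +
           bn_mom * va * (n / std::max(n - (T)1, (T)1));
    MT out = znorm;
    out.each_col() %= par[g].col(0);
    out.each_col() += par[be].col(0);
    return out;
  }

  MT bn_eval(const MT& z, ParId g, ParId be, const VT& rmean,
             const VT& rvar) const {
    VT istd = (T)1 / sqrt(rvar + bn_eps);
    MT out = z;
    out.each_col() -= rmean;
    out.each_col() %= (istd % par[g].col(0));
    out.each_col() += par[be].col(0);
    return out;
  }

  MT bn_back(const MT& dout, const MT& znorm, const VT& istd, ParId g,
             MT& dg, MT& dbe) const {
    dg = sum(dout % znorm, 1);
    dbe = sum(dout, 1);
    MT dz = dout;
    VT m1 = mean(dout, 1);
    VT m2 = mean(dout % znorm, 1);
    dz.each_col() -= m1;
    MT corr = znorm;
    corr.each_col() %= m2;
    dz -= corr;
    dz.each_col() %= (par[g].col(0) % istd);
    return dz;
  }

  static MT relu_mask(const MT& z) {
    MT m(z.n_rows, z.n_cols);
    const T* zs = z.memptr();
    T* ms = m.memptr();
    for (uword i = 0; i < z.n_elem; ++i) ms[i] = zs[i] > 0 ? (T)1 : (T)0;
    return m;
  }

  MT dropout_mask(uword r, uword c, T p) const {
    MT m(r, c);
    T* ms = m.memptr();
    const T scale = (T)1 / ((T)1 - p);
    for (uword i = 0; i < m.n_elem; ++i) {
      ms[i] = (R::unif_rand() < (double)p) ? (T)0 : scale;
    }
    return m;
  }

  static MT sigm(const MT& x) { return (T)1 / ((T)1 + exp(-x)); }

  void lstm_fwd(ParId wx, ParId wh, ParId bz, int H,
                const std::vector<MT>& xs, LstmCache& cc) {
    const int Tn = (int)xs.size();
    const int B = (int)xs[0].n_cols;
    cc.gates.assign(Tn, MT());
    cc.c.assign(Tn, MT());
    cc.tc.assign(Tn, MT());
    cc.h.assign(Tn, MT());
    cc.x = &xs;
    MT hprev(H, B, fill::zeros), cprev(H, B, fill::zeros);
    for (int t = 0; t < Tn; ++t) {
      MT z = par[wx] * xs[t] + par[wh] * hprev;
      z.each_col() += par[bz].col(0);
      z.rows(0, 3 * H - 1) = sigm(z.rows(0, 3 * H - 1));
      z.rows(3 * H, 4 * H - 1) = tanh(z.rows(3 * H, 4 * H - 1));
      MT c = z.rows(0, H - 1) % cprev +
             z.rows(H, 2 * H - 1) % z.rows(3 * H, 4 * H - 1);
      MT tc = tanh(c);
      MT h = z.rows(2 * H, 3 * H - 1) % tc;
      cc.gates[t] = z;
      cc.c[t] = c;
      cc.tc[t] = tc;
      cc.h[t] = h;
      hprev = h;
      cprev = c;
    }
  }

  std::vector<MT> lstm_bwd(ParId wx, ParId wh, int H, const LstmCache& cc,
                           const std::vector<MT>& dh_ext, MT& dwx, MT& dwh,
                           MT& dbz) const {
    const int Tn = (int)cc.h.size();
    const int B = (int)cc.h[0].n_cols;
    dwx.zeros(par[wx].n_rows, par[wx].n_cols);
    dwh.zeros(par[wh].n_rows, par[wh].n_cols);
    dbz.zeros(par[wx].n_rows, 1);
    std::vector<MT> dx(Tn);
    MT dh(H, B, fill::zeros), dc(H, B, fill::zeros);
    for (int t = Tn - 1; t >= 0; --t) {
      dh += dh_ext[t];
      const MT f = cc.gates[t].rows(0, H - 1);
      const MT i = cc.gates[t].rows(H, 2 * H - 1);
      const MT o = cc.gates[t].rows(2 * H, 3 * H - 1);
      const MT g = cc.gates[t].rows(3 * H, 4 * H - 1);
      dc += dh % o % (1 - square(cc.tc[t]));
      MT dz(4 * H, B);
      // forget, input, output, candidate blocks
      if (t == 0) {
        dz.rows(0, H - 1).zeros();          // c_prev is the zero state
      } else {
        dz.rows(0, H - 1) = dc % cc.c[t - 1] % f % (1 - f);
      }
      dz.rows(H, 2 * H - 1) = dc % g % i % (1 - i);
      dz.rows(2 * H, 3 * H - 1) = dh % cc.tc[t] % o % (1 - o);
      dz.rows(3 * H, 4 * H - 1) = dc % i % (1 - square(g));
      dwx += dz * (*cc.x)[t].t();
      if (t > 0) dwh += dz * cc.h[t - 1].t();
      dbz += sum(dz, 1);
      dx[t] = par[wx].t() * dz;
      dh = par[wh].t() * dz;
      dc = dc % f;
    }
    return dx;
  }

  MT forward(const Cube<T>& xb, bool train, bool use_dropout) {
    const int B = (int)xb.n_slices;
    const int S = side;
    MT x0(1, S * S * B);
    for (int b = 0; b < B; ++b) {
      x0.cols(b * S * S, (b + 1) * S * S - 1) =
          reshape(xb.slice(b), 1, S * S);
    }
    col1 = im2col3(x0, 1, S, B);
    MT z1 = par[W1] * col1;
    z1.each_col() += par[B1].col(0);
    MT a1 = train ? bn_train(z1, G1, BE1, rm1, rv1, z1n, istd1)
                  : bn_eval(z1, G1, BE1, rm1, rv1);
    relu1 = relu_mask(a1);
    a1 %= relu1;
    MT p1m = maxpool2(a1, c1, S, B, argm1);
    if (train && use_dropout && p1 > 0) {
      drop1m = dropout_mask(p1m.n_rows, p1m.n_cols, p1);
      p1m %= drop1m;
    } else {
      drop1m.reset();
    }

    col2 = im2col3(p1m, c1, s1, B);
    MT z2 = par[W2] * col2;
    z2.each_col() += par[B2].col(0);
    MT a2 = train ? bn_train(z2, G2, BE2, rm2, rv2, z2n, istd2)
                  : bn_eval(z2, G2, BE2, rm2, rv2);
    relu2 = relu_mask(a2);
    a2 %= relu2;
    MT p2m = maxpool2(a2, c2, s1, B, argm2);
    if (train && use_dropout && p2 > 0) {
      drop2m = dropout_mask(p2m.n_rows, p2m.n_cols, p2);
      p2m %= drop2m;
    } else {
      drop2m.reset();
    }
    pool2o = p2m;

    // row-sequence: step t gathers all channels x columns at row t
    const int Tn = s2;
    seq1.assign(Tn, MT(f_in, B));
    for (int t = 0; t < Tn; ++t) {
      MT& xt = seq1[t];
      for (int b = 0; b < B; ++b) {
        for (int xc = 0; xc < s2; ++xc) {
          xt.submat(xc * c2, b, (xc + 1) * c2 - 1, b) =
              p2m.col((uword)(b * s2 + xc) * s2 + t);
        }
      }
    }
    lstm_fwd(WX1, WH1, BZ1, h1, seq1, l1);
    lstm_fwd(WX2, WH2, BZ2, h2, l1.h, l2);
    hlast = l2.h[Tn - 1];
    MT logits = par[WFC] * hlast;
    logits.each_col() += par[BFC].col(0);
    logits.each_row() -= max(logits, 0);
    MT ex = exp(logits);
    probs = ex;
    probs.each_row() /= sum(ex, 0);
    return probs;
  }

  void backward() {
    const int B = (int)probs.n_cols;
    const int Tn = s2;
    MT dlogits = probs;
    for (int b = 0; b < B; ++b) dlogits(ybatch[b], b) -= (T)1;
    dlogits /= (T)B;

    grad[WFC] = dlogits * hlast.t();
    grad[BFC] = sum(dlogits, 1);
    std::vector<MT> dh2(Tn, MT(h2, B, fill::zeros));
    dh2[Tn - 1] = par[WFC].t() * dlogits;
    std::vector<MT> dh1 = lstm_bwd(WX2, WH2, h2, l2, dh2, grad[WX2],
                                   grad[WH2], grad[BZ2]);
    std::vector<MT> dxs = lstm_bwd(WX1, WH1, h1, l1, dh1, grad[WX1],
                                   grad[WH1], grad[BZ1]);

    MT dp2(c2, pool2o.n_cols, fill::zeros);
    for (int t = 0; t < Tn; ++t) {
      for (int b = 0; b < B; ++b) {
        for (int xc = 0; xc < s2; ++xc) {
          dp2.col((uword)(b * s2 + xc) * s2 + t) +=
              dxs[t].submat(xc * c2, b, (xc + 1) * c2 - 1, b);
        }
      }
    }
    if (!drop2m.is_empty()) dp2 %= drop2m;
    MT da2 = maxpool2_back(dp2, argm2, c2, relu2.n_cols);
    da2 %= relu2;
    MT dz2 = bn_back(da2, z2n, istd2, G2, grad[G2], grad[BE2]);
    grad[W2] = dz2 * col2.t();
    grad[B2] = sum(dz2, 1);
    MT dcol2 = par[W2].t() * dz2;
    MT dp1 = col2im3(dcol2, c1, s1, B);
    if (!drop1m.is_empty()) dp1 %= drop1m;
    MT da1 = maxpool2_back(dp1, argm1, c1, relu1.n_cols);
    da1 %= relu1;
    MT dz1 = bn_back(da1, z1n, istd1, G1, grad[G1], grad[BE1]);
    grad[W1] = dz1 * col1.t();
    grad[B1] = sum(dz1, 1);
  }

  double ce(const MT& p, const ivec& y) const {
    double loss = 0;
    for (uword b = 0; b < p.n_cols; ++b) {
      loss -= std::log(std::max((double)p(y[b], b), 1e-12));
    }
    return loss / (double)p.n_cols;
  }

  void adam(double lr, double b1 = 0.9, double b2 = 0.999,
            double eps = 1e-8) {
    astep += 1;
    const T bc1 = (T)(1.0 - std::pow(b1, (double)astep));
    const T bc2 = (T)(1.0 - std::pow(b2, (double)astep));
    for (int i = 0; i < NPAR; ++i) {
      am[i] = (T)b1 * am[i] + (T)(1 - b1) * grad[i];
      av[i] = (T)b2 * av[i] + (T)(1 - b2) * square(grad[i]);
      par[i] -= (T)lr * (am[i] / bc1) / (sqrt(av[i] / bc2) + (T)eps);
    }
  }

  // ---- NetBase interface ----

  void set_weights(const Rcpp::List& w) override {
    for (int i = 0; i < NPAR; ++i) {
      mat m = Rcpp::as<mat>(w[par_names[i]]);
      if (m.n_rows != par[i].n_rows || m.n_cols != par[i].n_cols) {
        Rcpp::stop("weight '%s' has shape %dx%d, expected %dx%d",
                   par_names[i], (int)m.n_rows, (int)m.n_cols,
                   (int)par[i].n_rows, (int)par[i].n_cols);
      }
      par[i] = conv_to<MT>::from(m);
    }
    if (w.containsElementNamed("bn1_mean")) {
      rm1 = conv_to<VT>::from(Rcpp::as<vec>(w["bn1_mean"]));
      rv1 = conv_to<VT>::from(Rcpp::as<vec>(w["bn1_var"]));
      rm2 = conv_to<VT>::from(Rcpp::as<vec>(w["bn2_mean"]));
      rv2 = conv_to<VT>::from(Rcpp::as<vec>(w["bn2_var"]));
    }
  }

  Rcpp::List get_weights() const override {
    Rcpp::List out;
    for (int i = 0; i < NPAR; ++i) {
      out[par_names[i]] = conv_to<mat>::from(par[i]);
    }
    out["bn1_mean"] = conv_to<vec>::from(rm1);
    out["bn1_var"] = conv_to<vec>::from(rv1);
    out["bn2_mean"] = conv_to<vec>::from(rm2);
    out["bn2_var"] = conv_to<vec>::from(rv2);
    return out;
  }

  Rcpp::List get_grads() const override {
    Rcpp::List out;
    for (int i = 0; i < NPAR; ++i) {
      out[par_names[i]] = conv_to<mat>::from(grad[i]);
    }
    return out;
  }

  Rcpp::List train_epoch(const cube& x, const ivec& y, const ivec& order,
                         int batch_size, double lr,
                         bool use_dropout) override {
    const int n = (int)x.n_slices;
    double loss_sum = 0;
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n) - 1;
      const int B = stop - start + 1;
      Cube<T> xb(side, side, B);
      ivec yb(B);
      for (int b = 0; b < B; ++b) {
        xb.slice(b) = conv_to<MT>::from(x.slice(order[start + b]));
        yb[b] = y[order[start + b]];
      }
      ybatch = yb;
      MT p = forward(xb, true, use_dropout);
      loss_sum += ce(p, yb) * B;
      for (int b = 0; b < B; ++b) {
        if ((int)p.col(b).index_max() == yb[b]) ++correct;
      }
      backward();
      adam(lr);
    }
    return Rcpp::List::create(Rcpp::Named("loss") = loss_sum / n,
                              Rcpp::Named("accuracy") = (double)correct / n);
  }

  mat predict_probs(const cube& x, int batch_size) override {
    const int n = (int)x.n_slices;
    MT out(ncls, n);
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n) - 1;
      Cube<T> xb = conv_to<Cube<T>>::from(x.slices(start, stop));
      out.cols(start, stop) = forward(xb, false, false);
    }
    return conv_to<mat>::from(out.t());
  }

  double loss_grad(const cube& x, const ivec& y) override {
    ybatch = y;
    Cube<T> xb = conv_to<Cube<T>>::from(x);
    MT p = forward(xb, true, false);
    backward();
    return ce(p, y);
  }

  double loss_only(const cube& x, const ivec& y) override {
    Cube<T> xb = conv_to<Cube<T>>::from(x);
    MT p = forward(xb, true, false);
    return ce(p, y);
  }

  Rcpp::List forward_debug(const mat& x) override {
    Cube<T> xb(side, side, 1);
    xb.slice(0) = conv_to<MT>::from(x);
    MT p = forward(xb, false, false);
    return Rcpp::List::create(
        Rcpp::Named("block1_shape") =
            Rcpp::IntegerVector::create(c1, s1, s1),
        Rcpp::Named("block2_shape") =
            Rcpp::IntegerVector::create(c2, s2, s2),
        Rcpp::Named("lstm_steps") = s2,
        Rcpp::Named("lstm_features") = f_in,
        Rcpp::Named("probs") = conv_to<vec>::from(p.col(0)));
  }

  Rcpp::IntegerVector geometry() const override {
    return Rcpp::IntegerVector::create(
        Rcpp::Named("side") = side, Rcpp::Named("n_classes") = ncls);
  }
};

}  // namespace

typedef Rcpp::XPtr<NetBase> NetPtr;

// [[Rcpp::export]]
SEXP cnn_new(int side, int conv1_channels, int conv2_channels,
             int lstm1_hidden, int lstm2_hidden, int n_classes,
             double dropout1, double dropout2,
             bool double_precision = false) {
  if (side % 4 != 0) Rcpp::stop("input side must be divisible by 4");
  NetBase* net;
  if (double_precision) {
    net = new Net<double>(side, conv1_channels, conv2_channels, lstm1_hidden,
                          lstm2_hidden, n_classes, dropout1, dropout2);
  } else {
    net = new Net<float>(side, conv1_channels, conv2_channels, lstm1_hidden,
                         lstm2_hidden, n_classes, dropout1, dropout2);
  }
  return NetPtr(net, true);
}

// [[Rcpp::export]]
Rcpp::List cnn_get_weights(SEXP ptr) { return NetPtr(ptr)->get_weights(); }

// [[Rcpp::export]]
void cnn_set_weights(SEXP ptr, Rcpp::List w) { NetPtr(ptr)->set_weights(w); }

// [[Rcpp::export]]
Rcpp::List cnn_get_grads(SEXP ptr) { return NetPtr(ptr)->get_grads(); }

// [[Rcpp::export]]
Rcpp::List cnn_train_epoch(SEXP ptr, const arma::cube& x,
                           const arma::ivec& y, const arma::ivec& order,
                           int batch_size, double lr,
                           bool use_dropout = true) {
  return NetPtr(ptr)->train_epoch(x, y, order, batch_size, lr, use_dropout);
}

// [[Rcpp::export]]
double cnn_loss_grad(SEXP ptr, const arma::cube& x, const arma::ivec& y) {
  return NetPtr(ptr)->loss_grad(x, y);
}

// [[Rcpp::export]]
double cnn_loss_only(SEXP ptr, const arma::cube& x, const arma::ivec& y) {
  return NetPtr(ptr)->loss_only(x, y);
}

// [[Rcpp::export]]
arma::mat cnn_predict_probs(SEXP ptr, const arma::cube& x,
                            int batch_size = 64) {
  return NetPtr(ptr)->predict_probs(x, batch_size);
}

// [[Rcpp::export]]
Rcpp::List cnn_eval(SEXP ptr, const arma::cube& x, const arma::ivec& y,
                    int batch_size = 64) {
  arma::mat probs = NetPtr(ptr)->predict_probs(x, batch_size);
  double loss = 0;
  int correct = 0;
  for (arma::uword b = 0; b < probs.n_rows; ++b) {
    loss -= std::log(std::max(probs(b, y[b]), 1e-12));
    if ((int)probs.row(b).index_max() == y[b]) ++correct;
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss / probs.n_rows,
      Rcpp::Named("accuracy") = (double)correct / probs.n_rows);
}

// [[Rcpp::export]]
Rcpp::List cnn_forward_debug(SEXP ptr, const arma::mat& x) {
  return NetPtr(ptr)->forward_debug(x);
}
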