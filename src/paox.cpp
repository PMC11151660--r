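// Core numerics: counter-based RNG streams, the wavelength-masked LSTM
// regressor (forward/backward/Adam), and the fixed-wavelength feedforward
// baseline. Single precision: the regression target lives in [0,1] and the
// MAE gradients are bounded, so float accumulation is ample while halving
// the memory bandwidth of the dense algebra.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#include <cmath>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define PAOX_HAS_MXCSR 1
#endif

// Saturated gates produce subnormal float products in the backward pass;
// on x86 those run orders of magnitude slower than normal arithmetic.
// Flushing them to zero is numerically irrelevant here (they are far below
// the gradient scale) and keeps epoch times flat. RAII so the caller's FP
// environment is restored.
struct FlushDenormals {
#ifdef PAOX_HAS_MXCSR
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(saved); }
#endif
};

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uvec;

// ---------------------------------------------------------------------------
// splitmix64 counter RNG: every consumer of randomness in the package draws
// from an explicit (seed, stream) pair so results do not depend on the
// platform RNG state and early draws are invariant to the total draw count.
// ---------------------------------------------------------------------------

static inline uint64_t sm64_next(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_init(uint64_t seed, uint64_t stream) {
  uint64_t s = (seed + 0x9E3779B97F4A7C15ULL) * 0xBF58476D1CE4E5B9ULL;
  s ^= (stream + 0xD1B54A32D192ED03ULL) * 0x94D049BB133111EBULL;
  // burn two outputs to decorrelate nearby (seed, stream) pairs
  sm64_next(s);
  sm64_next(s);
  return s;
}

static inline double runif53(uint64_t& s) {
  return (sm64_next(s) >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

//' @noRd
// [[Rcpp::export]]
NumericVector pa_runif_stream(double seed, double stream, int n) {
  if (n < 0) stop("n must be non-negative");
  uint64_t s = stream_init((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = runif53(s);
  return out;
}

// k draws per stream, streams 0..n_streams-1, returned as k x n_streams
//' @noRd
// [[Rcpp::export]]
NumericMatrix pa_runif_streams(double seed, int n_streams, int k) {
  NumericMatrix out(k, n_streams);
  for (int j = 0; j < n_streams; ++j) {
    uint64_t s = stream_init((uint64_t)seed, (uint64_t)j);
    for (int i = 0; i < k; ++i) out(i, j) = runif53(s);
  }
  return out;
}

// ---------------------------------------------------------------------------
// shared pieces
// ---------------------------------------------------------------------------

static inline fmat sigmoid_f(const fmat& x) { return 1.0f / (1.0f + arma::exp(-x)); }

// Branchless exp approximation (relative error ~2e-6, monotone) so the
// activation loops auto-vectorize; libm exp/tanh dominate the epoch time
// otherwise because the toolchain has no vector math library.
static inline float fast_exp(float x) {
  float t = x * 1.44269504088896341f; // x * log2(e)
  t = t > 126.0f ? 126.0f : t;
  t = t < -126.0f ? -126.0f : t;
  const float n = std::floor(t);
  const float f = t - n;
  // Taylor of 2^f = exp(f ln2) on [0,1)
  float p = 1.53853985e-4f;
  p = p * f + 1.33335581e-3f;
  p = p * f + 9.61812911e-3f;
  p = p * f + 5.55041087e-2f;
  p = p * f + 2.40226507e-1f;
  p = p * f + 6.93147181e-1f;
  p = p * f + 1.0f;
  union { uint32_t u; float s; } bits;
  bits.u = (uint32_t)((int32_t)n + 127) << 23;
  return p * bits.s;
}

static inline void sigmoid_inplace(float* p, size_t n) {
  for (size_t i = 0; i < n; ++i) p[i] = 1.0f / (1.0f + fast_exp(-p[i]));
}

static inline void tanh_inplace(float* p, size_t n) {
  for (size_t i = 0; i < n; ++i) p[i] = 2.0f / (1.0f + fast_exp(-2.0f * p[i])) - 1.0f;
}

static const float LRELU_ALPHA = 0.3f; // Keras LeakyReLU default

static inline fmat lrelu(const fmat& x) {
  return arma::max(x, LRELU_ALPHA * x);
}
static inline fmat lrelu_grad(const fmat& x) {
  fmat g(arma::size(x));
  g.fill(LRELU_ALPHA);
  g.elem(arma::find(x > 0.0f)).fill(1.0f);
  return g;
}

static fmat glorot(uint64_t& s, int nr, int nc) {
  const float lim = std::sqrt(6.0f / (float)(nr + nc));
  fmat w(nr, nc);
  for (arma::uword j = 0; j < w.n_cols; ++j)
    for (arma::uword i = 0; i < w.n_rows; ++i)
      w(i, j) = (float)((2.0 * runif53(s) - 1.0) * lim);
  return w;
}

struct Adam {
  std::vector<fmat*> p, g;
  std::vector<fmat> m, v;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;
  void add(fmat* par, fmat* grad) {
    p.push_back(par);
    g.push_back(grad);
    m.push_back(arma::zeros<fmat>(arma::size(*par)));
    v.push_back(arma::zeros<fmat>(arma::size(*par)));
  }
  void step(float lr) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t k = 0; k < p.size(); ++k) {
      m[k] = b1 * m[k] + (1.0f - b1) * (*g[k]);
      v[k] = b2 * v[k] + (1.0f - b2) * arma::square(*g[k]);
      *p[k] -= lr * (m[k] / c1) / (arma::sqrt(v[k] / c2) + eps);
    }
  }
};

// Fisher-Yates permutation of 0..n-1 from a counter stream
static uvec perm_from_stream(uint64_t& s, arma::uword n) {
  uvec idx = arma::regspace<uvec>(0, n - 1);
  for (arma::uword i = n - 1; i > 0; --i) {
    arma::uword j = (arma::uword)(runif53(s) * (double)(i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// ---------------------------------------------------------------------------
// masked LSTM forward (shared by training and inference)
//
// Masking contract: at a masked step the cell/hidden state pass through
// unchanged and the emitted hidden vector repeats the previous one; steps
// before the first present wavelength emit zeros. Stored amplitude values at
// masked slots therefore never influence the output.
// ---------------------------------------------------------------------------

struct LstmWts {
  fmat wx;  // 1 x 4H
  fmat wh;  // H x 4H
  fmat b;   // 1 x 4H
  fmat W1;  // (T*H) x F
  fmat b1;  // 1 x F
  fmat w2;  // F x 1
  fmat b2;  // 1 x 1
};

// forward pass over one batch; optionally keeps intermediates for backprop
struct LstmCache {
  fmat E;      // B x T*H   emitted hidden vectors (the flattened encoding)
  fmat CS;     // B x T*H   cell states after mask blending
  fmat GATES;  // B x 4H*T  post-activation gates
  fmat A1;     // B x F     pre-activation of the FC hidden layer
  fmat Z1;     // B x F
  fvec out;    // B
};

static void lstm_forward(const LstmWts& W, const fmat& Xb, const fmat& Mb,
                         int H, LstmCache& cc, bool keep) {
  const int B = Xb.n_rows, T = Xb.n_cols;
  cc.E.zeros(B, T * H);
  if (keep) {
    cc.CS.zeros(B, T * H);
    cc.GATES.set_size(B, 4 * H * T);
  }
  fmat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  fmat gpre, hn, cn, tc;
  for (int t = 0; t < T; ++t) {
    const fvec xt = Xb.col(t);
    const fvec mt = Mb.col(t);
    gpre = h * W.wh;
    gpre += xt * W.wx;
    gpre.each_row() += W.b.row(0);
    // activations in place: blocks [i f | g | o]
    sigmoid_inplace(gpre.colptr(0), (size_t)B * 2 * H);
    tanh_inplace(gpre.colptr(2 * H), (size_t)B * H);
    sigmoid_inplace(gpre.colptr(3 * H), (size_t)B * H);
    cn = gpre.cols(H, 2 * H - 1) % c + gpre.cols(0, H - 1) % gpre.cols(2 * H, 3 * H - 1);
    fmat tcn = cn;
    tanh_inplace(tcn.memptr(), tcn.n_elem);
    hn = gpre.cols(3 * H, 4 * H - 1) % tcn;
    // blend by mask: masked rows keep previous state
    const fvec im = 1.0f - mt;
    cn.each_col() %= mt;
    hn.each_col() %= mt;
    c.each_col() %= im;
    h.each_col() %= im;
    c += cn;
    h += hn;
    cc.E.cols(t * H, (t + 1) * H - 1) = h;
    if (keep) {
      cc.CS.cols(t * H, (t + 1) * H - 1) = c;
      cc.GATES.cols(4 * H * t, 4 * H * (t + 1) - 1) = gpre;
    }
  }
  cc.A1 = cc.E * W.W1;
  cc.A1.each_row() += W.b1.row(0);
  cc.Z1 = lrelu(cc.A1);
  cc.out = sigmoid_f(fmat(cc.Z1 * W.w2 + W.b2(0, 0)));
  if (!keep) { cc.A1.reset(); cc.Z1.reset(); }
}

static double lstm_backward(const LstmWts& W, const fmat& Xb, const fmat& Mb,
                            const fvec& yb, int H, LstmCache& cc, LstmWts& G) {
  const int B = Xb.n_rows, T = Xb.n_cols;
  const fvec r = cc.out - yb;
  const double loss = arma::mean(arma::abs(arma::conv_to<arma::vec>::from(r)));
  fvec dout = arma::sign(r) / (float)B;
  fvec dz2 = dout % cc.out % (1.0f - cc.out);
  G.w2 = cc.Z1.t() * dz2;
  G.b2(0, 0) = arma::accu(dz2);
  fmat dz1 = dz2 * W.w2.t();
  fmat da1 = dz1 % lrelu_grad(cc.A1);
  G.W1 = cc.E.t() * da1;
  G.b1 = arma::sum(da1, 0);
  fmat dE = da1 * W.W1.t();

  G.wx.zeros(1, 4 * H);
  G.wh.zeros(H, 4 * H);
  G.b.zeros(1, 4 * H);
  fmat dH(B, H, arma::fill::zeros), dC(B, H, arma::fill::zeros);
  fmat dP(B, 4 * H);
  for (int t = T - 1; t >= 0; --t) {
    const fvec xt = Xb.col(t);
    const fvec mt = Mb.col(t);
    const fmat gi = cc.GATES.cols(4 * H * t, 4 * H * t + H - 1);
    const fmat gf = cc.GATES.cols(4 * H * t + H, 4 * H * t + 2 * H - 1);
    const fmat gg = cc.GATES.cols(4 * H * t + 2 * H, 4 * H * t + 3 * H - 1);
    const fmat go = cc.GATES.cols(4 * H * t + 3 * H, 4 * H * t + 4 * H - 1);
    const fmat ct = cc.CS.cols(t * H, (t + 1) * H - 1);
    fmat cprev = (t == 0) ? fmat(B, H, arma::fill::zeros)
                          : fmat(cc.CS.cols((t - 1) * H, t * H - 1));
    fmat hprev = (t == 0) ? fmat(B, H, arma::fill::zeros)
                          : fmat(cc.E.cols((t - 1) * H, t * H - 1));
    fmat dht = dE.cols(t * H, (t + 1) * H - 1) + dH;
    fmat tc = ct;
    tanh_inplace(tc.memptr(), tc.n_elem);
    fmat dc_tot = dC + dht % go % (1.0f - tc % tc);
    dP.cols(0, H - 1)         = (dc_tot % gg) % gi % (1.0f - gi);
    dP.cols(H, 2 * H - 1)     = (dc_tot % cprev) % gf % (1.0f - gf);
    dP.cols(2 * H, 3 * H - 1) = (dc_tot % gi) % (1.0f - gg % gg);
    dP.cols(3 * H, 4 * H - 1) = (dht % tc) % go % (1.0f - go);
    dP.each_col() %= mt; // masked steps contribute no gate gradient
    G.wh += hprev.t() * dP;
    G.wx += xt.t() * dP;
    G.b += arma::sum(dP, 0);
    const fvec im = 1.0f - mt;
    fmat dh_pass = dht;
    dh_pass.each_col() %= im;
    dH = dP * W.wh.t() + dh_pass;
    fmat dc_new = dc_tot % gf;
    dc_new.each_col() %= mt;
    dC.each_col() %= im;
    dC += dc_new;
  }
  return loss;
}

static double mae_eval(const LstmWts& W, const fmat& X, const fmat& M,
                       const fvec& y, int H, int batch) {
  const int n = X.n_rows;
  double acc = 0.0;
  LstmCache cc;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch) - 1;
    lstm_forward(W, X.rows(s, e), M.rows(s, e), H, cc, false);
    acc += arma::accu(arma::abs(arma::conv_to<arma::vec>::from(cc.out - y.subvec(s, e))));
  }
  return acc / n;
}

static List wts_to_list(const LstmWts& W) {
  return List::create(
    _["wx"] = wrap(arma::conv_to<arma::mat>::from(W.wx)),
    _["wh"] = wrap(arma::conv_to<arma::mat>::from(W.wh)),
    _["b"]  = wrap(arma::conv_to<arma::mat>::from(W.b)),
    _["W1"] = wrap(arma::conv_to<arma::mat>::from(W.W1)),
    _["b1"] = wrap(arma::conv_to<arma::mat>::from(W.b1)),
    _["w2"] = wrap(arma::conv_to<arma::mat>::from(W.w2)),
    _["b2"] = wrap(arma::conv_to<arma::mat>::from(W.b2)));
}

static LstmWts wts_from_list(const List& L) {
  LstmWts W;
  W.wx = arma::conv_to<fmat>::from(as<arma::mat>(L["wx"]));
  W.wh = arma::conv_to<fmat>::from(as<arma::mat>(L["wh"]));
  W.b  = arma::conv_to<fmat>::from(as<arma::mat>(L["b"]));
  W.W1 = arma::conv_to<fmat>::from(as<arma::mat>(L["W1"]));
  W.b1 = arma::conv_to<fmat>::from(as<arma::mat>(L["b1"]));
  W.w2 = arma::conv_to<fmat>::from(as<arma::mat>(L["w2"]));
  W.b2 = arma::conv_to<fmat>::from(as<arma::mat>(L["b2"]));
  return W;
}

//' @noRd
// [[Rcpp::export]]
List lstm_train_cpp(NumericMatrix X_, LogicalMatrix M_, NumericVector y_,
                    int hidden, int fc_hidden, int epochs, double lr0,
                    double lr_factor, int lr_patience, double lr_min,
                    int batch, double val_fraction, double seed,
                    bool verbose) {
  FlushDenormals ftz;
  const int n = X_.nrow(), T = X_.ncol(), H = hidden, F = fc_hidden;
  fmat X = arma::conv_to<fmat>::from(as<arma::mat>(X_));
  fmat M(n, T);
  for (int j = 0; j < T; ++j)
    for (int i = 0; i < n; ++i) M(i, j) = M_(i, j) ? 1.0f : 0.0f;
  fvec y = arma::conv_to<fvec>::from(as<arma::vec>(y_));

  // deterministic validation split + weight init from named streams
  uint64_t s_split = stream_init((uint64_t)seed, 101);
  uint64_t s_init  = stream_init((uint64_t)seed, 102);
  uint64_t s_shuf  = stream_init((uint64_t)seed, 103);
  uvec prm = perm_from_stream(s_split, n);
  int n_val = (int)std::floor(val_fraction * n + 0.5);
  if (n_val < 0) n_val = 0;
  if (n_val > n - 1) n_val = n - 1;
  uvec vi = (n_val > 0) ? uvec(prm.head(n_val)) : uvec();
  uvec ti = prm.tail(n - n_val);
  fmat Xt = X.rows(ti), Mt = M.rows(ti);
  fvec yt = y(ti);
  fmat Xv, Mv; fvec yv;
  if (n_val > 0) { Xv = X.rows(vi); Mv = M.rows(vi); yv = y(vi); }

  LstmWts W;
  W.wx = glorot(s_init, 1, 4 * H);
  W.wh = glorot(s_init, H, 4 * H);
  W.b  = arma::zeros<fmat>(1, 4 * H);
  W.b.cols(H, 2 * H - 1).fill(1.0f); // unit forget-gate bias
  W.W1 = glorot(s_init, T * H, F);
  W.b1 = arma::zeros<fmat>(1, F);
  W.w2 = glorot(s_init, F, 1);
  W.b2 = arma::zeros<fmat>(1, 1);

  LstmWts G = W; // gradient buffers (same shapes)
  Adam opt;
  opt.add(&W.wx, &G.wx); opt.add(&W.wh, &G.wh); opt.add(&W.b, &G.b);
  opt.add(&W.W1, &G.W1); opt.add(&W.b1, &G.b1); opt.add(&W.w2, &G.w2);
  opt.add(&W.b2, &G.b2);

  const int ntr = Xt.n_rows;
  float lr = (float)lr0;
  double best = R_PosInf;
  int wait = 0;
  NumericVector tr_log(epochs), va_log(epochs), lr_log(epochs);
  LstmCache cc;
  for (int ep = 0; ep < epochs; ++ep) {
    uvec ord = perm_from_stream(s_shuf, ntr);
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < ntr; s += batch) {
      int e = std::min(ntr, s + batch) - 1;
      uvec ids = ord.subvec(s, e);
      fmat Xb = Xt.rows(ids), Mb = Mt.rows(ids);
      fvec yb = yt(ids);
      lstm_forward(W, Xb, Mb, H, cc, true);
      ep_loss += lstm_backward(W, Xb, Mb, yb, H, cc, G);
      opt.step(lr);
      ++nb;
    }
    tr_log[ep] = ep_loss / nb;
    double vl = (n_val > 0) ? mae_eval(W, Xv, Mv, yv, H, batch) : tr_log[ep];
    va_log[ep] = vl;
    lr_log[ep] = lr;
    if (vl < best) { best = vl; wait = 0; } else if (++wait >= lr_patience) {
      lr = std::max((float)lr_min, lr * (float)lr_factor);
      wait = 0;
    }
    if (verbose)
      Rcout << "epoch " << (ep + 1) << "  train " << tr_log[ep]
            << "  val " << vl << "  lr " << lr << "\n";
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = wts_to_list(W),
                      _["train_loss"] = tr_log, _["val_loss"] = va_log,
                      _["lr"] = lr_log);
}

//' @noRd
// [[Rcpp::export]]
NumericVector lstm_predict_cpp(List weights, NumericMatrix X_,
                               LogicalMatrix M_, int hidden, int batch) {
  FlushDenormals ftz;
  LstmWts W = wts_from_list(weights);
  const int n = X_.nrow(), T = X_.ncol();
  fmat X = arma::conv_to<fmat>::from(as<arma::mat>(X_));
  fmat M(n, T);
  for (int j = 0; j < T; ++j)
    for (int i = 0; i < n; ++i) M(i, j) = M_(i, j) ? 1.0f : 0.0f;
  NumericVector out(n);
  LstmCache cc;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch) - 1;
    lstm_forward(W, X.rows(s, e), M.rows(s, e), hidden, cc, false);
    for (int i = s; i <= e; ++i) out[i] = (double)cc.out[i - s];
  }
  return out;
}

// ---------------------------------------------------------------------------
// feedforward baseline (learned spectral decoloring): fixed full wavelength
// set, 41 -> h1 -> h2 -> 1 with leaky ReLU and sigmoid output, same
// optimizer and schedule as the recurrent model.
// ---------------------------------------------------------------------------

struct MlpWts { fmat W1, b1, W2, b2, w3, b3; };

static fvec mlp_forward(const MlpWts& W, const fmat& Xb,
                        fmat& a1, fmat& z1, fmat& a2, fmat& z2) {
  a1 = Xb * W.W1; a1.each_row() += W.b1.row(0);
  z1 = lrelu(a1);
  a2 = z1 * W.W2; a2.each_row() += W.b2.row(0);
  z2 = lrelu(a2);
  return sigmoid_f(fmat(z2 * W.w3 + W.b3(0, 0)));
}

//' @noRd
// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X_, NumericVector y_, int h1, int h2,
                   int epochs, double lr0, double lr_factor, int lr_patience,
                   double lr_min, int batch, double val_fraction, double seed,
                   bool verbose) {
  FlushDenormals ftz;
  const int n = X_.nrow(), D = X_.ncol();
  fmat X = arma::conv_to<fmat>::from(as<arma::mat>(X_));
  fvec y = arma::conv_to<fvec>::from(as<arma::vec>(y_));
  uint64_t s_split = stream_init((uint64_t)seed, 201);
  uint64_t s_init  = stream_init((uint64_t)seed, 202);
  uint64_t s_shuf  = stream_init((uint64_t)seed, 203);
  uvec prm = perm_from_stream(s_split, n);
  int n_val = (int)std::floor(val_fraction * n + 0.5);
  if (n_val < 0) n_val = 0;
  if (n_val > n - 1) n_val = n - 1;
  uvec vi = (n_val > 0) ? uvec(prm.head(n_val)) : uvec();
  uvec ti = prm.tail(n - n_val);
  fmat Xt = X.rows(ti); fvec yt = y(ti);
  fmat Xv; fvec yv;
  if (n_val > 0) { Xv = X.rows(vi); yv = y(vi); }

  MlpWts W;
  W.W1 = glorot(s_init, D, h1);  W.b1 = arma::zeros<fmat>(1, h1);
  W.W2 = glorot(s_init, h1, h2); W.b2 = arma::zeros<fmat>(1, h2);
  W.w3 = glorot(s_init, h2, 1);  W.b3 = arma::zeros<fmat>(1, 1);
  MlpWts G = W;
  Adam opt;
  opt.add(&W.W1, &G.W1); opt.add(&W.b1, &G.b1);
  opt.add(&W.W2, &G.W2); opt.add(&W.b2, &G.b2);
  opt.add(&W.w3, &G.w3); opt.add(&W.b3, &G.b3);

  const int ntr = Xt.n_rows;
  float lr = (float)lr0;
  double best = R_PosInf;
  int wait = 0;
  NumericVector tr_log(epochs), va_log(epochs), lr_log(epochs);
  fmat a1, z1, a2, z2;
  for (int ep = 0; ep < epochs; ++ep) {
    uvec ord = perm_from_stream(s_shuf, ntr);
    double ep_loss = 0.0;
    int nb = 0;
    for (int s = 0; s < ntr; s += batch) {
      int e = std::min(ntr, s + batch) - 1;
      uvec ids = ord.subvec(s, e);
      fmat Xb = Xt.rows(ids);
      fvec yb = yt(ids);
      const int B = Xb.n_rows;
      fvec out = mlp_forward(W, Xb, a1, z1, a2, z2);
      fvec r = out - yb;
      ep_loss += arma::mean(arma::abs(arma::conv_to<arma::vec>::from(r)));
      fvec dz3 = (arma::sign(r) / (float)B) % out % (1.0f - out);
      G.w3 = z2.t() * dz3; G.b3(0, 0) = arma::accu(dz3);
      fmat da2 = (dz3 * W.w3.t()) % lrelu_grad(a2);
      G.W2 = z1.t() * da2; G.b2 = arma::sum(da2, 0);
      fmat da1 = (da2 * W.W2.t()) % lrelu_grad(a1);
      G.W1 = Xb.t() * da1; G.b1 = arma::sum(da1, 0);
      opt.step(lr);
      ++nb;
    }
    tr_log[ep] = ep_loss / nb;
    double vl;
    if (n_val > 0) {
      fvec ov = mlp_forward(W, Xv, a1, z1, a2, z2);
      vl = arma::mean(arma::abs(arma::conv_to<arma::vec>::from(ov - yv)));
    } else vl = tr_log[ep];
    va_log[ep] = vl;
    lr_log[ep] = lr;
    if (vl < best) { best = vl; wait = 0; } else if (++wait >= lr_patience) {
      lr = std::max((float)lr_min, lr * (float)lr_factor);
      wait = 0;
    }
    if (verbose)
      Rcout << "epoch " << (ep + 1) << "  train " << tr_log[ep]
            << "  val " << vl << "  lr " << lr << "\n";
    Rcpp::checkUserInterrupt();
  }
  List wl = List::create(
    _["W1"] = wrap(arma::conv_to<arma::mat>::from(W.W1)),
    _["b1"] = wrap(arma::conv_to<arma::mat>::from(W.b1)),
    _["W2"] = wrap(arma::conv_to<arma::mat>::from(W.W2)),
    _["b2"] = wrap(arma::conv_to<arma::mat>::from(W.b2)),
    _["w3"] = wrap(arma::conv_to<arma::mat>::from(W.w3)),
    _["b3"] = wrap(arma::conv_to<arma::mat>::from(W.b3)));
  return List::create(_["weights"] = wl, _["train_loss"] = tr_log,
                      _["val_loss"] = va_log, _["lr"] = lr_log);
}

//' @noRd
// [[Rcpp::export]]
NumericVector mlp_predict_cpp(List weights, NumericMatrix X_, int batch) {
  FlushDenormals ftz;
  MlpWts W;
  W.W1 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W1"]));
  W.b1 = arma::conv_to<fmat>::from(as<arma::mat>(weights["b1"]));
  W.W2 = arma::conv_to<fmat>::from(as<arma::mat>(weights["W2"]));
  W.b2 = arma::conv_to<fmat>::from(as<arma::mat>(weights["b2"]));
  W.w3 = arma::conv_to<fmat>::from(as<arma::mat>(weights["w3"]));
  W.b3 = arma::conv_to<fmat>::from(as<arma::mat>(weights["b3"]));
  const int n = X_.nrow();
  fmat X = arma::conv_to<fmat>::from(as<arma::mat>(X_));
  NumericVector out(n);
  fmat a1, z1, a2, z2;
  for (int s = 0; s < n; s += batch) {
    int e = std::min(n, s + batch) - 1;
    fvec o = mlp_forward(W, X.rows(s, e), a1, z1, a2, z2);
    for (int i = s; i <= e; ++i) out[i] = (double)o[i - s];
  }
  return out;
}
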