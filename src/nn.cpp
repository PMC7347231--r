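// Minimal feed-forward network engine: 2-D / 1-D convolutional streams with
// TensorFlow-style "same" padding, batch normalization on every hidden layer,
// ReLU activations, dropout on the fully connected stack, sigmoid / softmax
// heads with class-weighted cross-entropy, and Adam updates with Xavier
// (Glorot-uniform) initialization.  All randomness is drawn from R's RNG so
// set.seed() on the R side makes initialization, shuffling, dropout and any
// augmentation callback reproducible.
//
// Activation layout: one matrix per layer with rows indexed (sample-major,
// then spatial position) and one column per channel.  A conv layer maps a
// (N*H*W) x C_in matrix to a (N*oH*oW) x C_out matrix via im2col + GEMM.

#include <RcppArmadillo.h>
#include <cstring>
#if defined(__GLIBC__)
#include <malloc.h>
// the training loop cycles large im2col buffers every minibatch; keeping
// freed blocks on the heap (instead of mmap/munmap round trips) roughly
// halves the wall time of a training epoch
struct MallocTuner {
  MallocTuner() {
    mallopt(M_MMAP_MAX, 0);
    mallopt(M_TRIM_THRESHOLD, 64 * 1024 * 1024);
  }
};
static MallocTuner malloc_tuner;
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
typedef arma::fmat emat;       // engine (training/inference) precision
typedef arma::fvec evec;
typedef arma::frowvec erowvec;

namespace {

struct ConvGeom {
  int kh, kw, stride, units;
  int H, W, C;        // input geometry
  int oH, oW;         // output geometry
  int padT, padL;
};

// "same" padding as in TensorFlow: output ceil(in/stride), leading pad floor(total/2)
ConvGeom make_geom(int kh, int kw, int stride, int units, int H, int W, int C) {
  ConvGeom g;
  g.kh = kh; g.kw = kw; g.stride = stride; g.units = units;
  g.H = H; g.W = W; g.C = C;
  g.oH = (H + stride - 1) / stride;
  g.oW = (W + stride - 1) / stride;
  int padH = std::max(0, (g.oH - 1) * stride + kh - H);
  int padW = std::max(0, (g.oW - 1) * stride + kw - W);
  g.padT = padH / 2;
  g.padL = padW / 2;
  return g;
}

// X: (N*H*W) x C, sample-major rows; returns (N*oH*oW) x (kh*kw*C).
// Loop order keeps each destination column (one (ky, kx, c) triple)
// contiguous in the inner loops.
template <typename M>
M im2col_t(const M& X, const ConvGeom& g, int N) {
  typedef typename M::elem_type T;
  const int HW = g.H * g.W, oHW = g.oH * g.oW, K = g.kh * g.kw;
  const int s = g.stride;
  M Mx(static_cast<arma::uword>(N) * oHW, static_cast<arma::uword>(K) * g.C,
        arma::fill::zeros);
  for (int c = 0; c < g.C; ++c) {
    const T* Xc = X.colptr(c);
    for (int kx = 0; kx < g.kw; ++kx) {
      for (int ky = 0; ky < g.kh; ++ky) {
        T* Mc = Mx.colptr(ky + g.kh * kx + K * c);
        // valid oy range: 0 <= oy*s - padT + ky < H
        const int oyLo = std::max(0, (g.padT - ky + s - 1) / s);
        const int oyHi = std::min(g.oH - 1, (g.H - 1 + g.padT - ky) / s);
        if (oyHi < oyLo) continue;
        const int len = oyHi - oyLo + 1;
        for (int b = 0; b < N; ++b) {
          const T* Xb = Xc + static_cast<size_t>(b) * HW;
          T* Mb = Mc + static_cast<size_t>(b) * oHW;
          for (int ox = 0; ox < g.oW; ++ox) {
            const int x = ox * s - g.padL + kx;
            if (x < 0 || x >= g.W) continue;
            const T* src = Xb + x * g.H + (oyLo * s - g.padT + ky);
            T* dst = Mb + g.oH * ox + oyLo;
            if (s == 1) {
              std::memcpy(dst, src, len * sizeof(T));
            } else {
              for (int i = 0; i < len; ++i) dst[i] = src[i * s];
            }
          }
        }
      }
    }
  }
  return Mx;
}

// adjoint of im2col: scatter-add patches back; dM: (N*oHW) x (K*C)
template <typename M>
M col2im_t(const M& dM, const ConvGeom& g, int N) {
  typedef typename M::elem_type T;
  const int HW = g.H * g.W, oHW = g.oH * g.oW, K = g.kh * g.kw;
  const int s = g.stride;
  M dX(static_cast<arma::uword>(N) * HW, g.C, arma::fill::zeros);
  for (int c = 0; c < g.C; ++c) {
    T* Xc = dX.colptr(c);
    for (int kx = 0; kx < g.kw; ++kx) {
      for (int ky = 0; ky < g.kh; ++ky) {
        const T* Mc = dM.colptr(ky + g.kh * kx + K * c);
        const int oyLo = std::max(0, (g.padT - ky + s - 1) / s);
        const int oyHi = std::min(g.oH - 1, (g.H - 1 + g.padT - ky) / s);
        if (oyHi < oyLo) continue;
        const int len = oyHi - oyLo + 1;
        for (int b = 0; b < N; ++b) {
          T* Xb = Xc + static_cast<size_t>(b) * HW;
          const T* Mb = Mc + static_cast<size_t>(b) * oHW;
          for (int ox = 0; ox < g.oW; ++ox) {
            const int x = ox * s - g.padL + kx;
            if (x < 0 || x >= g.W) continue;
            T* dst = Xb + x * g.H + (oyLo * s - g.padT + ky);
            const T* src = Mb + g.oH * ox + oyLo;
            if (s == 1) {
              for (int i = 0; i < len; ++i) dst[i] += src[i];
            } else {
              for (int i = 0; i < len; ++i) dst[i * s] += src[i];
            }
          }
        }
      }
    }
  }
  return dX;
}

struct StreamGeom {
  int H, W, C;
  std::vector<ConvGeom> layers;
  int out_dim;  // flattened dimension after the conv stack
};

struct NetGeom {
  std::vector<StreamGeom> streams;
  int scalar_dim;
  std::vector<int> fc_units;
  int out_dim;
  bool softmax;
};

NetGeom parse_cfg(const List& cfg) {
  NetGeom net;
  List streams = cfg["streams"];
  for (int s = 0; s < streams.size(); ++s) {
    List st = streams[s];
    IntegerVector shape = st["shape"];  // H, W, C
    StreamGeom sg;
    sg.H = shape[0]; sg.W = shape[1]; sg.C = shape[2];
    int H = sg.H, W = sg.W, C = sg.C;
    List layers = st["layers"];
    for (int l = 0; l < layers.size(); ++l) {
      List ly = layers[l];
      IntegerVector k = ly["kernel"];
      ConvGeom g = make_geom(k[0], k[1], as<int>(ly["stride"]),
                             as<int>(ly["units"]), H, W, C);
      sg.layers.push_back(g);
      H = g.oH; W = g.oW; C = g.units;
    }
    sg.out_dim = H * W * C;
    net.streams.push_back(sg);
  }
  net.scalar_dim = as<int>(cfg["scalar_dim"]);
  net.fc_units = as<std::vector<int>>(cfg["fc_units"]);
  net.out_dim = as<int>(cfg["out_dim"]);
  net.softmax = as<std::string>(cfg["out_activation"]) == "softmax";
  return net;
}

double runif_pm(double a) { return (2.0 * unif_rand() - 1.0) * a; }

emat glorot(int n_in, int n_out, int fan_in, int fan_out) {
  double a = std::sqrt(6.0 / (fan_in + fan_out));
  emat W(n_in, n_out);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i)
      W(i, j) = runif_pm(a);
  return W;
}

struct BNParams {
  erowvec gamma, beta, rmean, rvar;
};

struct BNCache {
  emat xhat;
  erowvec invstd;
};

// Batch normalization over rows (batch x spatial), per column (channel).
emat bn_forward(const emat& X, BNParams& p, bool training, BNCache* cache,
                float momentum = 0.9f, float eps = 1e-5f) {
  erowvec mu, var;
  if (training) {
    mu = arma::mean(X, 0);
    var = arma::var(X, 1, 0);  // population variance
    p.rmean = momentum * p.rmean + (1 - momentum) * mu;
    p.rvar  = momentum * p.rvar  + (1 - momentum) * var;
  } else {
    mu = p.rmean;
    var = p.rvar;
  }
  erowvec invstd = 1.0f / arma::sqrt(var + eps);
  const arma::uword nr = X.n_rows, nc = X.n_cols;
  emat out(nr, nc);
  if (cache) cache->xhat.set_size(nr, nc);
  for (arma::uword j = 0; j < nc; ++j) {
    const float mj = mu[j], sj = invstd[j], gj = p.gamma[j], bj = p.beta[j];
    const float* xi = X.colptr(j);
    float* oi = out.colptr(j);
    if (cache) {
      float* hi = cache->xhat.colptr(j);
      for (arma::uword i = 0; i < nr; ++i) {
        const float h = (xi[i] - mj) * sj;
        hi[i] = h;
        oi[i] = h * gj + bj;
      }
    } else {
      for (arma::uword i = 0; i < nr; ++i)
        oi[i] = (xi[i] - mj) * sj * gj + bj;
    }
  }
  if (cache) cache->invstd = invstd;
  return out;
}

emat bn_backward(const emat& dY, const BNParams& p, const BNCache& c,
                 erowvec& dgamma, erowvec& dbeta) {
  const arma::uword nr = dY.n_rows, nc = dY.n_cols;
  const float m = static_cast<float>(nr);
  dgamma.set_size(nc);
  dbeta.set_size(nc);
  emat dX(nr, nc);
  for (arma::uword j = 0; j < nc; ++j) {
    const float* dy = dY.colptr(j);
    const float* xh = c.xhat.colptr(j);
    float sdy = 0, sdyxh = 0;
    for (arma::uword i = 0; i < nr; ++i) {
      sdy += dy[i];
      sdyxh += dy[i] * xh[i];
    }
    dgamma[j] = sdyxh;
    dbeta[j] = sdy;
    const float g = p.gamma[j];
    const float s1 = g * sdy, s2 = g * sdyxh;
    const float k = c.invstd[j] / m;
    float* dx = dX.colptr(j);
    for (arma::uword i = 0; i < nr; ++i)
      dx[i] = k * (m * g * dy[i] - s1 - xh[i] * s2);
  }
  return dX;
}

std::string pnm(int s, int l, const char* part) {
  std::ostringstream os;
  os << "s" << s << "_conv" << (l + 1) << "_" << part;
  return os.str();
}
std::string fnm(int l, const char* part) {
  std::ostringstream os;
  os << "fc" << (l + 1) << "_" << part;
  return os.str();
}

struct Params {
  std::map<std::string, emat> M;    // weight matrices
  std::map<std::string, BNParams> BN;
};

Params params_from_list(const List& lp, const NetGeom& net) {
  Params P;
  CharacterVector nms = lp.names();
  for (int i = 0; i < lp.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    if (nm.size() > 3 && nm.substr(nm.size() - 3) == "_bn") {
      List b = lp[i];
      BNParams bp;
      bp.gamma = arma::conv_to<erowvec>::from(as<rowvec>(b["gamma"]));
      bp.beta = arma::conv_to<erowvec>::from(as<rowvec>(b["beta"]));
      bp.rmean = arma::conv_to<erowvec>::from(as<rowvec>(b["rmean"]));
      bp.rvar = arma::conv_to<erowvec>::from(as<rowvec>(b["rvar"]));
      P.BN[nm.substr(0, nm.size() - 2)] = bp;
    } else {
      P.M[nm] = arma::conv_to<emat>::from(as<mat>(lp[i]));
    }
  }
  (void)net;
  return P;
}

List params_to_list(const Params& P) {
  List out;
  for (auto& kv : P.M) out[kv.first] = wrap(arma::conv_to<mat>::from(kv.second));
  for (auto& kv : P.BN) {
    out[kv.first + "bn"] = List::create(
        _["gamma"] = NumericVector(kv.second.gamma.begin(), kv.second.gamma.end()),
        _["beta"] = NumericVector(kv.second.beta.begin(), kv.second.beta.end()),
        _["rmean"] = NumericVector(kv.second.rmean.begin(), kv.second.rmean.end()),
        _["rvar"] = NumericVector(kv.second.rvar.begin(), kv.second.rvar.end()));
  }
  return out;
}

// reshape stream input matrix (d x n) into activation layout (n*HW) x C
emat stream_input(const emat& X, const StreamGeom& sg) {
  const int HW = sg.H * sg.W, C = sg.C, n = X.n_cols;
  emat A(static_cast<arma::uword>(n) * HW, C);
  for (int b = 0; b < n; ++b)
    for (int c = 0; c < C; ++c)
      A.submat(b * HW, c, (b + 1) * HW - 1, c) = X.submat(c * HW, b, (c + 1) * HW - 1, b);
  return A;
}

struct ForwardCache {
  // per stream, per layer
  std::vector<std::vector<emat>> cols;    // im2col matrices
  std::vector<std::vector<emat>> relu;    // post-ReLU activations
  std::vector<std::vector<BNCache>> bnc;
  emat Z0;                                 // concatenated FC input
  std::vector<emat> fc_relu;               // post-dropout activations per FC layer
  std::vector<BNCache> fc_bnc;
  std::vector<emat> drop_mask;
  emat probs;
};

emat forward_pass(const NetGeom& net, Params& P,
                  const std::vector<emat>& stream_x,
                  const emat& scalars, bool training, double dropout,
                  ForwardCache* fc) {
  int n = -1;
  std::vector<emat> flat(net.streams.size());
  if (fc) {
    fc->cols.resize(net.streams.size());
    fc->relu.resize(net.streams.size());
    fc->bnc.resize(net.streams.size());
  }
  for (size_t s = 0; s < net.streams.size(); ++s) {
    const StreamGeom& sg = net.streams[s];
    n = stream_x[s].n_cols;
    emat A = stream_input(stream_x[s], sg);
    const emat* Ap = &A;
    for (size_t l = 0; l < sg.layers.size(); ++l) {
      const ConvGeom& g = sg.layers[l];
      emat M = im2col_t(*Ap, g, n);
      emat Y = M * P.M[pnm(s, l, "W")];
      BNCache bc;
      Y = bn_forward(Y, P.BN[pnm(s, l, "")], training, fc ? &bc : nullptr);
      Y.transform([](float v) { return v > 0 ? v : 0.0f; });
      if (fc) {
        fc->cols[s].push_back(std::move(M));
        fc->relu[s].push_back(std::move(Y));
        fc->bnc[s].push_back(std::move(bc));
        Ap = &fc->relu[s].back();
      } else {
        A = std::move(Y);
        Ap = &A;
      }
    }
    // flatten: per sample, column-major over (position, channel)
    const int d = sg.out_dim;
    const int oHW = sg.layers.empty() ? sg.H * sg.W : d / sg.layers.back().units;
    const emat& Af = *Ap;
    emat F(n, d);
    for (int b = 0; b < n; ++b) {
      for (int c = 0; c < (int)Af.n_cols; ++c) {
        const float* srcp = Af.colptr(c) + static_cast<size_t>(b) * oHW;
        for (int i = 0; i < oHW; ++i) F(b, c * oHW + i) = srcp[i];
      }
    }
    flat[s] = std::move(F);
  }
  emat Z;
  if (!net.streams.empty()) {
    Z = flat[0];
    for (size_t s = 1; s < flat.size(); ++s) Z = arma::join_rows(Z, flat[s]);
  }
  if (net.scalar_dim > 0) {
    emat Sc = scalars.t();  // n x p
    n = Sc.n_rows;
    Z = Z.n_elem ? arma::join_rows(Z, Sc) : Sc;
  }
  if (fc) fc->Z0 = Z;
  // fully connected stack
  for (size_t l = 0; l < net.fc_units.size(); ++l) {
    emat Y = Z * P.M[fnm(l, "W")];
    BNCache bc;
    Y = bn_forward(Y, P.BN[fnm(l, "")], training, fc ? &bc : nullptr);
    Y.transform([](float v) { return v > 0 ? v : 0.0f; });
    emat mask;
    if (training && dropout > 0) {
      mask.set_size(Y.n_rows, Y.n_cols);
      const float keep = 1.0f - (float)dropout;
      for (arma::uword j = 0; j < Y.n_cols; ++j)
        for (arma::uword i = 0; i < Y.n_rows; ++i)
          mask(i, j) = unif_rand() >= dropout ? 1.0f / keep : 0.0f;
      Y %= mask;
    }
    if (fc) {
      fc->fc_bnc.push_back(std::move(bc));
      fc->fc_relu.push_back(std::move(Y));
      fc->drop_mask.push_back(std::move(mask));
      Z = fc->fc_relu.back();
    } else {
      Z = std::move(Y);
    }
  }
  emat logits = Z * P.M["out_W"];
  logits.each_row() += P.M["out_b"].row(0);
  emat probs;
  if (net.softmax) {
    probs = logits;
    probs.each_col() -= arma::max(logits, 1);
    probs = arma::exp(probs);
    probs.each_col() /= arma::sum(probs, 1);
  } else {
    probs = 1.0 / (1.0 + arma::exp(-logits));
  }
  if (fc) fc->probs = probs;
  return probs;
}

struct Adam {
  std::map<std::string, emat> m, v;
  std::map<std::string, erowvec> mg, vg;
  long t = 0;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;

  void step_mat(const std::string& key, emat& W, const emat& g, double lr) {
    if (!m.count(key)) { m[key] = arma::zeros<emat>(arma::size(W));
                         v[key] = arma::zeros<emat>(arma::size(W)); }
    emat& mm = m[key]; emat& vv = v[key];
    const float c1 = 1 - std::pow(b1, (float)t), c2 = 1 - std::pow(b2, (float)t);
    const float a = (float)lr, ic1 = 1.0f / c1, ic2 = 1.0f / c2;
    float* wp = W.memptr(); float* mp = mm.memptr(); float* vp = vv.memptr();
    const float* gp = g.memptr();
    const arma::uword ne = W.n_elem;
    for (arma::uword i = 0; i < ne; ++i) {
      mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
      vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
      wp[i] -= a * (mp[i] * ic1) / (std::sqrt(vp[i] * ic2) + eps);
    }
  }
  void step_row(const std::string& key, erowvec& W, const erowvec& g,
                double lr) {
    if (!mg.count(key)) { mg[key] = arma::zeros<erowvec>(W.n_elem);
                          vg[key] = arma::zeros<erowvec>(W.n_elem); }
    erowvec& mm = mg[key]; erowvec& vv = vg[key];
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    float c1 = 1 - std::pow(b1, (float)t), c2 = 1 - std::pow(b2, (float)t);
    W -= (float)lr * (mm / c1) / (arma::sqrt(vv / c2) + eps);
  }
};

}  // namespace

// [[Rcpp::export]]
List nn_init_cpp(List cfg) {
  NetGeom net = parse_cfg(cfg);
  Params P;
  for (size_t s = 0; s < net.streams.size(); ++s) {
    const StreamGeom& sg = net.streams[s];
    for (size_t l = 0; l < sg.layers.size(); ++l) {
      const ConvGeom& g = sg.layers[l];
      int K = g.kh * g.kw;
      P.M[pnm(s, l, "W")] = glorot(K * g.C, g.units, K * g.C, K * g.units);
      BNParams bp;
      bp.gamma = arma::ones<erowvec>(g.units);
      bp.beta = arma::zeros<erowvec>(g.units);
      bp.rmean = arma::zeros<erowvec>(g.units);
      bp.rvar = arma::ones<erowvec>(g.units);
      P.BN[pnm(s, l, "")] = bp;
    }
  }
  int din = net.scalar_dim;
  for (auto& sg : net.streams) din += sg.out_dim;
  for (size_t l = 0; l < net.fc_units.size(); ++l) {
    int u = net.fc_units[l];
    P.M[fnm(l, "W")] = glorot(din, u, din, u);
    BNParams bp;
    bp.gamma = arma::ones<erowvec>(u);
    bp.beta = arma::zeros<erowvec>(u);
    bp.rmean = arma::zeros<erowvec>(u);
    bp.rvar = arma::ones<erowvec>(u);
    P.BN[fnm(l, "")] = bp;
    din = u;
  }
  P.M["out_W"] = glorot(din, net.out_dim, din, net.out_dim);
  P.M["out_b"] = arma::zeros<emat>(1, net.out_dim);
  return params_to_list(P);
}

// [[Rcpp::export]]
arma::mat nn_predict_cpp(List cfg, List params, List stream_x,
                         Nullable<NumericMatrix> scalars,
                         int batch = 256) {
  NetGeom net = parse_cfg(cfg);
  Params P = params_from_list(params, net);
  std::vector<emat> SX;
  for (int s = 0; s < stream_x.size(); ++s)
    SX.push_back(arma::conv_to<emat>::from(as<mat>(stream_x[s])));
  emat SC;
  if (scalars.isNotNull()) SC = arma::conv_to<emat>::from(as<mat>(scalars.get()));
  int n = SX.empty() ? SC.n_cols : SX[0].n_cols;
  mat out(n, net.out_dim);
  for (int i0 = 0; i0 < n; i0 += batch) {
    int i1 = std::min(n, i0 + batch) - 1;
    std::vector<emat> bx;
    for (auto& X : SX) bx.push_back(X.cols(i0, i1));
    emat bs;
    if (SC.n_elem) bs = SC.cols(i0, i1);
    out.rows(i0, i1) = arma::conv_to<mat>::from(
        forward_pass(net, P, bx, bs, false, 0.0, nullptr));
  }
  return out;
}

// [[Rcpp::export]]
List nn_train_cpp(List cfg, List params, List stream_x,
                  Nullable<NumericMatrix> scalars, IntegerVector y,
                  NumericMatrix stages, int batch_size,
                  NumericVector class_weights,
                  Nullable<Function> batch_transform) {
  NetGeom net = parse_cfg(cfg);
  Params P = params_from_list(params, net);
  std::vector<emat> SX;
  for (int s = 0; s < stream_x.size(); ++s)
    SX.push_back(arma::conv_to<emat>::from(as<mat>(stream_x[s])));
  emat SC;
  if (scalars.isNotNull()) SC = arma::conv_to<emat>::from(as<mat>(scalars.get()));
  const int n = y.size();
  Adam opt;
  std::vector<double> trace;

  for (int st = 0; st < stages.nrow(); ++st) {
    const int epochs = (int)stages(st, 0);
    const double lr0 = stages(st, 1);
    const double lr1 = stages.ncol() > 3 ? stages(st, 3) : NA_REAL;
    const double dropout = stages(st, 2);
    for (int ep = 0; ep < epochs; ++ep) {
      // learning rate, optionally decaying quadratically across the stage
      double lr = lr0;
      if (R_finite(lr1) && epochs > 1) {
        double f = (double)ep / (epochs - 1);
        lr = lr0 + (lr1 - lr0) * f * f;
      }
      // shuffle with R's RNG
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(idx[i], idx[j]);
      }
      double ep_loss = 0; int nb = 0;
      for (int i0 = 0; i0 < n; i0 += batch_size) {
        int i1 = std::min(n, i0 + batch_size);
        int nbatch = i1 - i0;
        arma::uvec bidx(nbatch);
        for (int i = 0; i < nbatch; ++i) bidx[i] = idx[i0 + i];
        std::vector<emat> bx;
        for (auto& X : SX) bx.push_back(X.cols(bidx));
        emat bs;
        if (SC.n_elem) bs = SC.cols(bidx);
        if (batch_transform.isNotNull()) {
          Function f(batch_transform.get());
          List xin;
          for (size_t s = 0; s < bx.size(); ++s)
            xin.push_back(wrap(arma::conv_to<mat>::from(bx[s])));
          List xout = f(xin, bs.n_elem ?
              wrap(arma::conv_to<mat>::from(bs)) : R_NilValue);
          List nbx = xout["streams"];
          for (int s = 0; s < nbx.size(); ++s)
            bx[s] = arma::conv_to<emat>::from(as<mat>(nbx[s]));
          if (!Rf_isNull(xout["scalars"]))
            bs = arma::conv_to<emat>::from(as<mat>(xout["scalars"]));
        }
        vec by(nbatch), bw(nbatch);
        for (int i = 0; i < nbatch; ++i) {
          by[i] = y[bidx[i]];
          bw[i] = class_weights[y[bidx[i]]];
        }
        ForwardCache fc;
        forward_pass(net, P, bx, bs, true, dropout, &fc);
        // loss and output gradient
        double loss = 0;
        emat dlogits;
        if (net.softmax) {
          dlogits = fc.probs;
          for (int i = 0; i < nbatch; ++i) {
            int cls = (int)by[i];
            loss += -bw[i] * std::log(std::max((double)fc.probs(i, cls), 1e-12));
            dlogits.row(i) *= bw[i];
            dlogits(i, cls) -= bw[i];
          }
        } else {
          dlogits.set_size(nbatch, 1);
          for (int i = 0; i < nbatch; ++i) {
            double p = std::min(std::max((double)fc.probs(i, 0), 1e-12), 1 - 1e-12);
            loss += -bw[i] * (by[i] * std::log(p) + (1 - by[i]) * std::log(1 - p));
            dlogits(i, 0) = bw[i] * (fc.probs(i, 0) - by[i]);
          }
        }
        loss /= nbatch;
        dlogits /= nbatch;
        if (!std::isfinite(loss))
          stop("training diverged: non-finite loss (stage %d, epoch %d)", st + 1, ep + 1);
        ep_loss += loss; ++nb;
        opt.t += 1;

        // ---- backward ----
        const emat& Zlast = net.fc_units.empty() ? fc.Z0 : fc.fc_relu.back();
        emat d_outW = Zlast.t() * dlogits;
        erowvec d_outb = arma::sum(dlogits, 0);
        emat dZ = dlogits * P.M["out_W"].t();
        for (int l = (int)net.fc_units.size() - 1; l >= 0; --l) {
          if (fc.drop_mask[l].n_elem) dZ %= fc.drop_mask[l];
          // ReLU gate (dropout mask already folded into fc_relu)
          {
            const float* a = fc.fc_relu[l].memptr();
            float* d = dZ.memptr();
            const arma::uword ne = dZ.n_elem;
            for (arma::uword i = 0; i < ne; ++i)
              if (a[i] <= 0) d[i] = 0;
          }
          erowvec dg, db;
          emat dpre = bn_backward(dZ, P.BN[fnm(l, "")], fc.fc_bnc[l], dg, db);
          const emat& Zin = l == 0 ? fc.Z0 : fc.fc_relu[l - 1];
          emat dW = Zin.t() * dpre;
          emat dnext = dpre * P.M[fnm(l, "W")].t();
          opt.step_mat(fnm(l, "W"), P.M[fnm(l, "W")], dW, lr);
          opt.step_row(fnm(l, "g"), P.BN[fnm(l, "")].gamma, dg, lr);
          opt.step_row(fnm(l, "b"), P.BN[fnm(l, "")].beta, db, lr);
          dZ = std::move(dnext);
        }
        opt.step_mat("out_W", P.M["out_W"], d_outW, lr);
        erowvec ob = P.M["out_b"].row(0);
        opt.step_row("out_b", ob, d_outb, lr);
        P.M["out_b"].row(0) = ob;

        // split dZ back into streams (scalars occupy the trailing columns)
        int off = 0;
        for (size_t s = 0; s < net.streams.size(); ++s) {
          const StreamGeom& sg = net.streams[s];
          emat dF = dZ.cols(off, off + sg.out_dim - 1);
          off += sg.out_dim;
          const int nlay = sg.layers.size();
          const int oHW = sg.out_dim / sg.layers.back().units;
          emat dA(static_cast<arma::uword>(nbatch) * oHW, sg.layers.back().units);
          for (int b = 0; b < nbatch; ++b) {
            erowvec r = dF.row(b);
            dA.rows(b * oHW, (b + 1) * oHW - 1) =
                arma::reshape(emat(r.t()), oHW, sg.layers.back().units);
          }
          for (int l = nlay - 1; l >= 0; --l) {
            const ConvGeom& g = sg.layers[l];
            {
              const float* a = fc.relu[s][l].memptr();
              float* d = dA.memptr();
              const arma::uword ne = dA.n_elem;
              for (arma::uword i = 0; i < ne; ++i)
                if (a[i] <= 0) d[i] = 0;
            }
            erowvec dg2, db2;
            emat dpre = bn_backward(dA, P.BN[pnm(s, l, "")], fc.bnc[s][l], dg2, db2);
            emat dW = fc.cols[s][l].t() * dpre;
            opt.step_row(pnm(s, l, "g"), P.BN[pnm(s, l, "")].gamma, dg2, lr);
            opt.step_row(pnm(s, l, "b"), P.BN[pnm(s, l, "")].beta, db2, lr);
            if (l > 0) {
              emat dM = dpre * P.M[pnm(s, l, "W")].t();
              dA = col2im_t(dM, g, nbatch);
            }
            opt.step_mat(pnm(s, l, "W"), P.M[pnm(s, l, "W")], dW, lr);
          }
        }
      }
      trace.push_back(ep_loss / std::max(nb, 1));
      Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["params"] = params_to_list(P),
                      _["loss_trace"] = wrap(trace));
}

// Post-activation (eval-mode) response of every layer; one matrix (d_l x n)
// per layer, conv layers flattened per sample.
// [[Rcpp::export]]
List nn_activations_cpp(List cfg, List params, List stream_x,
                        Nullable<NumericMatrix> scalars) {
  NetGeom net = parse_cfg(cfg);
  Params P = params_from_list(params, net);
  std::vector<emat> SX;
  for (int s = 0; s < stream_x.size(); ++s)
    SX.push_back(arma::conv_to<emat>::from(as<mat>(stream_x[s])));
  emat SC;
  if (scalars.isNotNull()) SC = arma::conv_to<emat>::from(as<mat>(scalars.get()));
  ForwardCache fc;
  forward_pass(net, P, SX, SC, false, 0.0, &fc);
  List out;
  CharacterVector tags;
  for (size_t s = 0; s < net.streams.size(); ++s) {
    const StreamGeom& sg = net.streams[s];
    for (size_t l = 0; l < sg.layers.size(); ++l) {
      const emat& A = fc.relu[s][l];
      const int u = sg.layers[l].units;
      const int oHW = A.n_rows / (SX[s].n_cols);
      mat R(static_cast<arma::uword>(oHW) * u, SX[s].n_cols);
      for (arma::uword b = 0; b < SX[s].n_cols; ++b)
        R.col(b) = arma::conv_to<vec>::from(
            arma::vectorise(A.rows(b * oHW, (b + 1) * oHW - 1)));
      std::ostringstream nm;
      nm << "s" << (s + 1) << "_CV" << (l + 1);
      out.push_back(wrap(R));
      tags.push_back(nm.str());
    }
  }
  for (size_t l = 0; l < net.fc_units.size(); ++l) {
    out.push_back(wrap(arma::conv_to<mat>::from(emat(fc.fc_relu[l].t()))));
    std::ostringstream nm;
    nm << "FC" << (l + 1);
    tags.push_back(nm.str());
  }
  out.push_back(wrap(arma::conv_to<mat>::from(emat(fc.probs.t()))));
  tags.push_back("output");
  out.attr("names") = tags;
  return out;
}

// ---- double-precision conv / adjoint helpers used by the deconvolution
// analyses (single sample, one stream) ----

// [[Rcpp::export]]
arma::mat conv_apply_cpp(IntegerVector shape, List layer, arma::mat W,
                         arma::mat x) {
  // x: (H*W) x C column layout for one sample
  IntegerVector k = layer["kernel"];
  ConvGeom g = make_geom(k[0], k[1], as<int>(layer["stride"]),
                         as<int>(layer["units"]), shape[0], shape[1], shape[2]);
  mat M = im2col_t(x, g, 1);
  return M * W;  // (oH*oW) x units
}

// [[Rcpp::export]]
arma::mat conv_adjoint_cpp(IntegerVector shape, List layer, arma::mat W,
                           arma::mat gmap) {
  IntegerVector k = layer["kernel"];
  ConvGeom g = make_geom(k[0], k[1], as<int>(layer["stride"]),
                         as<int>(layer["units"]), shape[0], shape[1], shape[2]);
  mat dM = gmap * W.t();
  return col2im_t(dM, g, 1);  // (H*W) x C
}
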