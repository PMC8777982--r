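// Native arithmetic for the dual-stream segmentation networks.
//
// Activations are stored per image as an (n_pixels x n_channels) float
// matrix, pixels column-major (p = i + h*j).  Convolutions run as
// im2col + single-precision GEMM; all computation is single precision,
// single threaded, and free of any RNG, so results are reproducible
// bit-for-bit for a given input.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;
using arma::uword;

namespace {

struct Feat {
  fmat m;     // n_pixels x n_channels
  int h, w;
  int npix() const { return h * w; }
};

// ceil-mode 'same' geometry: out = ceil(n / stride); the smaller half of
// the padding goes before (top/left), the remainder after (bottom/right).
void same_geom(int n, int s, int k, int &out, int &p0) {
  out = (n + s - 1) / s;
  int tot = std::max((out - 1) * s + k - n, 0);
  p0 = tot / 2;
}

// gather patches: cols(p_out, ki + k*kj + k*k*c) = x(ii + h*jj, c).
// cols is a caller-owned reusable buffer; only out-of-range (padding)
// entries are zeroed, so no full-buffer clear is needed.
void im2col(const Feat &x, int k, int s, int ho, int wo, int pt, int pl,
            fmat &cols) {
  const int h = x.h, w = x.w, C = x.m.n_cols;
  cols.set_size(ho * (size_t)wo, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const float *xc = x.m.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        float *dst = cols.colptr((size_t)c * k * k + (size_t)kj * k + ki);
        const int oi = ki - pt, oj = kj - pl;  // ii = i*s + oi
        int i0 = oi < 0 ? (-oi + s - 1) / s : 0;
        int i1 = (h - oi) > 0 ? (h - oi + s - 1) / s : 0;  // exclusive
        if (i1 > ho) i1 = ho;
        if (i1 < i0) i1 = i0;
        int j0 = oj < 0 ? (-oj + s - 1) / s : 0;
        int j1 = (w - oj) > 0 ? (w - oj + s - 1) / s : 0;
        if (j1 > wo) j1 = wo;
        if (j1 < j0) j1 = j0;
        if (j0 > 0) std::memset(dst, 0, sizeof(float) * (size_t)j0 * ho);
        if (j1 < wo)
          std::memset(dst + (size_t)j1 * ho, 0,
                      sizeof(float) * (size_t)(wo - j1) * ho);
        for (int j = j0; j < j1; ++j) {
          const float *src = xc + (size_t)(j * s + oj) * h;
          float *d = dst + (size_t)j * ho;
          if (i0 > 0) std::memset(d, 0, sizeof(float) * i0);
          if (i1 < ho) std::memset(d + i1, 0, sizeof(float) * (ho - i1));
          if (s == 1) {
            std::memcpy(d + i0, src + (i0 + oi), sizeof(float) * (i1 - i0));
          } else {
            for (int i = i0; i < i1; ++i) d[i] = src[i * s + oi];
          }
        }
      }
    }
  }
}

// scatter-add: inverse of im2col (gradient w.r.t. the conv input)
void col2im_add(Feat &x, const fmat &cols, int k, int s, int ho, int wo,
                int pt, int pl) {
  const int h = x.h, w = x.w, C = x.m.n_cols;
  for (int c = 0; c < C; ++c) {
    float *xc = x.m.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const float *src0 =
            cols.colptr((size_t)c * k * k + (size_t)kj * k + ki);
        const int oi = ki - pt, oj = kj - pl;
        int i0 = oi < 0 ? (-oi + s - 1) / s : 0;
        int i1 = (h - oi) > 0 ? (h - oi + s - 1) / s : 0;
        if (i1 > ho) i1 = ho;
        int j0 = oj < 0 ? (-oj + s - 1) / s : 0;
        int j1 = (w - oj) > 0 ? (w - oj + s - 1) / s : 0;
        if (j1 > wo) j1 = wo;
        for (int j = j0; j < j1; ++j) {
          float *dcol = xc + (size_t)(j * s + oj) * h;
          const float *sp = src0 + (size_t)j * ho;
          for (int i = i0; i < i1; ++i) dcol[i * s + oi] += sp[i];
        }
      }
    }
  }
}

Feat to_feat(const NumericVector &a) {
  IntegerVector d = a.attr("dim");
  Feat f;
  f.h = d[0];
  f.w = d[1];
  int C = d.size() >= 3 ? d[2] : 1;
  f.m.set_size((size_t)f.h * f.w, C);
  const double *src = a.begin();
  for (size_t t = 0; t < f.m.n_elem; ++t) f.m[t] = (float)src[t];
  return f;
}

NumericVector from_mat(const fmat &m, IntegerVector dim) {
  NumericVector out(m.n_elem);
  for (size_t t = 0; t < m.n_elem; ++t) out[t] = (double)m[t];
  out.attr("dim") = dim;
  return out;
}

// reshape an R array whose last extent is nr into (prod(other dims) x nr)
fmat get_fmat(const List &lay, const char *name, int nr) {
  NumericVector v = lay[name];
  fmat m(v.size() / nr, nr);
  for (int c = 0; c < nr; ++c)
    for (size_t r = 0; r < m.n_rows; ++r)
      m(r, c) = (float)v[(size_t)c * m.n_rows + r];
  return m;
}

fvec get_fvec(const List &lay, const char *name) {
  NumericVector v = lay[name];
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

// ---------------------------------------------------------------------------
// layer objects (hold parameters, caches and gradients for one batch pass)
// ---------------------------------------------------------------------------

struct BN {
  fvec gamma, beta, rmean, rvar;
  fvec mu, istd;          // batch statistics (training pass)
  fvec dgamma, dbeta;
  float eps;
  bool train;

  // z columns are channels; apply BN (+ update batch stats on first call
  // pattern: stats are computed by the owner across the whole batch)
  void stats(const std::vector<Feat> &zs) {
    const int C = gamma.n_elem;
    mu.zeros(C);
    fvec s2(C, arma::fill::zeros);
    double n = 0;
    for (const Feat &z : zs) {
      mu += arma::sum(z.m, 0).t();
      s2 += arma::sum(arma::square(z.m), 0).t();
      n += z.npix();
    }
    mu /= (float)n;
    fvec var = s2 / (float)n - arma::square(mu);
    var.transform([](float v) { return v < 0 ? 0.0f : v; });
    istd = 1.0f / arma::sqrt(var + eps);
    rmean = 0.9f * rmean + 0.1f * mu;
    rvar = 0.9f * rvar + 0.1f * var;
  }
  // fused affine: y = a*z + b with a = gamma*istd, b = beta - mean*a
  void apply(Feat &z) const {
    const fvec &m = train ? mu : rmean;
    fvec is = train ? istd : fvec(1.0f / arma::sqrt(rvar + eps));
    for (uword c = 0; c < z.m.n_cols; ++c) {
      const float a = is[c] * gamma[c], b = beta[c] - m[c] * a;
      float *p = z.m.colptr(c);
      const size_t n = z.m.n_rows;
      for (size_t i = 0; i < n; ++i) p[i] = a * p[i] + b;
    }
  }
};

// fused ReLU-mask + BN batch-sum accumulation: zeroes dy where the
// pre-ReLU output was non-positive and accumulates S1 = sum(dy),
// S2 = sum(dy * xhat) per channel (dgamma = S2, dbeta = S1)
void bn_relu_sums(const BN &bn, const std::vector<Feat> &z,
                  std::vector<Feat> &dy, fvec &S1, fvec &S2, double &ntot) {
  const int C = bn.gamma.n_elem;
  S1.zeros(C);
  S2.zeros(C);
  ntot = 0;
  for (size_t n = 0; n < z.size(); ++n) {
    ntot += z[n].npix();
    for (int c = 0; c < C; ++c) {
      const float a = bn.gamma[c] * bn.istd[c];
      const float b = bn.beta[c] - bn.mu[c] * a;
      const float *zp = z[n].m.colptr(c);
      float *dp = dy[n].m.colptr(c);
      const size_t np = z[n].m.n_rows;
      double s1 = 0, s2 = 0;
      for (size_t i = 0; i < np; ++i) {
        if (a * zp[i] + b <= 0) {
          dp[i] = 0;
        } else {
          s1 += dp[i];
          s2 += dp[i] * ((zp[i] - bn.mu[c]) * bn.istd[c]);
        }
      }
      S1[c] += (float)s1;
      S2[c] += (float)s2;
    }
  }
}

// in-place BN backward for one image: dy (masked) -> dz,
// dz = A*dy - D*z + (D*mu - B), A = gamma*istd, B = S1*A/N, D = S2*A*istd/N
void bn_backward_inplace(const BN &bn, const Feat &z, Feat &dy,
                         const fvec &S1, const fvec &S2, double ntot) {
  const int C = bn.gamma.n_elem;
  for (int c = 0; c < C; ++c) {
    const float A = bn.gamma[c] * bn.istd[c];
    const float B = S1[c] * A / (float)ntot;
    const float D = S2[c] * A * bn.istd[c] / (float)ntot;
    const float E = D * bn.mu[c] - B;
    const float *zp = z.m.colptr(c);
    float *dp = dy.m.colptr(c);
    const size_t np = z.m.n_rows;
    for (size_t i = 0; i < np; ++i) dp[i] = A * dp[i] - D * zp[i] + E;
  }
}

struct ConvLayer {
  int k = 3, stride = 1;
  fmat W;                 // (k*k*Cin) x Cout
  fmat dW;
  BN bn;
  std::vector<Feat> in, z;  // caches (training only)
  fmat colsbuf;             // reusable im2col buffer
  bool train = false;

  std::vector<Feat> forward(std::vector<Feat> xs) {
    const int N = xs.size();
    std::vector<Feat> zs(N);
    for (int n = 0; n < N; ++n) {
      int ho, wo, pt, pl;
      same_geom(xs[n].h, stride, k, ho, pt);
      same_geom(xs[n].w, stride, k, wo, pl);
      im2col(xs[n], k, stride, ho, wo, pt, pl, colsbuf);
      zs[n].h = ho;
      zs[n].w = wo;
      zs[n].m = colsbuf * W;
    }
    if (train) {
      in = std::move(xs);
      bn.train = true;
      bn.stats(zs);
    } else {
      bn.train = false;
    }
    std::vector<Feat> out(N);
    for (int n = 0; n < N; ++n) {
      if (train) {
        out[n] = zs[n];
      } else {
        out[n] = std::move(zs[n]);
      }
      bn.apply(out[n]);
      out[n].m.transform([](float v) { return v > 0 ? v : 0.0f; });
    }
    if (train) z = std::move(zs);
    return out;
  }

  // dy: gradient at the post-ReLU output; returns gradient at the input
  std::vector<Feat> backward(std::vector<Feat> &dy) {
    const int N = dy.size();
    fvec S1, S2;
    double ntot;
    bn_relu_sums(bn, z, dy, S1, S2, ntot);
    bn.dgamma = S2;
    bn.dbeta = S1;
    dW.zeros(W.n_rows, W.n_cols);
    std::vector<Feat> dx(N);
    for (int n = 0; n < N; ++n) {
      bn_backward_inplace(bn, z[n], dy[n], S1, S2, ntot);
      const fmat &dz = dy[n].m;
      int ho = z[n].h, wo = z[n].w, pt, pl, dum;
      same_geom(in[n].h, stride, k, dum, pt);
      same_geom(in[n].w, stride, k, dum, pl);
      im2col(in[n], k, stride, ho, wo, pt, pl, colsbuf);
      dW += colsbuf.t() * dz;
      fmat dcols = dz * W.t();
      dx[n].h = in[n].h;
      dx[n].w = in[n].w;
      dx[n].m.zeros(in[n].npix(), in[n].m.n_cols);
      col2im_add(dx[n], dcols, k, stride, ho, wo, pt, pl);
    }
    return dx;
  }
};

struct PoolLayer {  // 2x2 max pool, stride 2, ceil mode
  std::vector<umat> idx;
  std::vector<int> hin, win, cin;
  std::vector<Feat> forward(const std::vector<Feat> &xs, bool train) {
    const int N = xs.size();
    std::vector<Feat> out(N);
    if (train) { idx.resize(N); hin.resize(N); win.resize(N); cin.resize(N); }
    for (int n = 0; n < N; ++n) {
      const Feat &x = xs[n];
      int ho = (x.h + 1) / 2, wo = (x.w + 1) / 2, C = x.m.n_cols;
      out[n].h = ho;
      out[n].w = wo;
      out[n].m.set_size((size_t)ho * wo, C);
      umat id;
      if (train) id.set_size((size_t)ho * wo, C);
      for (int c = 0; c < C; ++c) {
        const float *xc = x.m.colptr(c);
        for (int j = 0; j < wo; ++j)
          for (int i = 0; i < ho; ++i) {
            float best = -std::numeric_limits<float>::infinity();
            uword bp = 0;
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                int ii = 2 * i + di, jj = 2 * j + dj;
                if (ii >= x.h || jj >= x.w) continue;
                uword p = ii + (size_t)x.h * jj;
                if (xc[p] > best) { best = xc[p]; bp = p; }
              }
            out[n].m(i + (size_t)ho * j, c) = best;
            if (train) id(i + (size_t)ho * j, c) = bp;
          }
      }
      if (train) { idx[n] = id; hin[n] = x.h; win[n] = x.w; cin[n] = C; }
    }
    return out;
  }
  std::vector<Feat> backward(const std::vector<Feat> &dy) {
    const int N = dy.size();
    std::vector<Feat> dx(N);
    for (int n = 0; n < N; ++n) {
      dx[n].h = hin[n];
      dx[n].w = win[n];
      dx[n].m.zeros((size_t)hin[n] * win[n], cin[n]);
      for (int c = 0; c < cin[n]; ++c)
        for (uword p = 0; p < dy[n].m.n_rows; ++p)
          dx[n].m(idx[n](p, c), c) += dy[n].m(p, c);
    }
    return dx;
  }
};

struct TConvLayer {  // kernel 4, stride 2, pad 1: exact x2 upsampling
  static const int k = 4, stride = 2, pad = 1;
  fmat W;    // (k*k*Cout) x Cin
  fvec b;
  fmat dW;
  fvec db;
  BN bn;
  std::vector<Feat> in, z;
  bool train = false;

  std::vector<Feat> forward(std::vector<Feat> xs) {
    const int N = xs.size();
    const int Cout = b.n_elem;
    std::vector<Feat> zs(N);
    for (int n = 0; n < N; ++n) {
      const Feat &x = xs[n];
      int ho = 2 * x.h, wo = 2 * x.w;
      fmat cols = x.m * W.t();  // npix_in x (k*k*Cout)
      zs[n].h = ho;
      zs[n].w = wo;
      zs[n].m.set_size((size_t)ho * wo, Cout);
      for (int c = 0; c < Cout; ++c) zs[n].m.col(c).fill(b[c]);
      // scatter: out(2i-1+ki, 2j-1+kj) += cols(p, c*16 + kj*4 + ki)
      for (int c = 0; c < Cout; ++c) {
        float *oc = zs[n].m.colptr(c);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const float *sc = cols.colptr((size_t)c * k * k + (size_t)kj * k + ki);
            for (int j = 0; j < x.w; ++j) {
              int oj = 2 * j - pad + kj;
              if (oj < 0 || oj >= wo) continue;
              float *od = oc + (size_t)ho * oj;
              const float *sd = sc + (size_t)x.h * j;
              for (int i = 0; i < x.h; ++i) {
                int oi = 2 * i - pad + ki;
                if (oi >= 0 && oi < ho) od[oi] += sd[i];
              }
            }
          }
      }
    }
    if (train) {
      in = std::move(xs);
      bn.train = true;
      bn.stats(zs);
    } else {
      bn.train = false;
    }
    std::vector<Feat> out(N);
    for (int n = 0; n < N; ++n) {
      out[n] = zs[n];
      bn.apply(out[n]);
      out[n].m.transform([](float v) { return v > 0 ? v : 0.0f; });
    }
    if (train) z = std::move(zs);
    return out;
  }

  std::vector<Feat> backward(std::vector<Feat> &dy) {
    const int N = dy.size();
    const int C = bn.gamma.n_elem;
    fvec S1, S2;
    double ntot;
    bn_relu_sums(bn, z, dy, S1, S2, ntot);
    bn.dgamma = S2;
    bn.dbeta = S1;
    dW.zeros(W.n_rows, W.n_cols);
    db.zeros(C);
    std::vector<Feat> dx(N);
    for (int n = 0; n < N; ++n) {
      bn_backward_inplace(bn, z[n], dy[n], S1, S2, ntot);
      const fmat &dz = dy[n].m;
      for (int c = 0; c < C; ++c) db[c] += arma::accu(dz.col(c));
      const Feat &x = in[n];
      int ho = z[n].h, wo = z[n].w;
      fmat dcols((size_t)x.h * x.w, (size_t)k * k * C, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        const float *gc = dz.colptr(c);
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            float *dc = dcols.colptr((size_t)c * k * k + (size_t)kj * k + ki);
            for (int j = 0; j < x.w; ++j) {
              int oj = 2 * j - pad + kj;
              if (oj < 0 || oj >= wo) continue;
              const float *gd = gc + (size_t)ho * oj;
              float *dd = dc + (size_t)x.h * j;
              for (int i = 0; i < x.h; ++i) {
                int oi = 2 * i - pad + ki;
                if (oi >= 0 && oi < ho) dd[i] = gd[oi];
              }
            }
          }
      }
      dW += dcols.t() * x.m;
      dx[n].h = x.h;
      dx[n].w = x.w;
      dx[n].m = dcols * W;
    }
    return dx;
  }
};

struct ClsLayer {  // 1x1 convolution to n_classes, with bias, no BN/ReLU
  fmat W;  // Cin x n_classes
  fvec b;
  fmat dW;
  fvec db;
  std::vector<Feat> in;
  bool train = false;
  std::vector<Feat> forward(std::vector<Feat> xs) {
    const int N = xs.size();
    std::vector<Feat> out(N);
    for (int n = 0; n < N; ++n) {
      out[n].h = xs[n].h;
      out[n].w = xs[n].w;
      out[n].m = xs[n].m * W;
      out[n].m.each_row() += b.t();
    }
    if (train) in = std::move(xs);
    return out;
  }
  std::vector<Feat> backward(const std::vector<Feat> &dy) {
    const int N = dy.size();
    dW.zeros(W.n_rows, W.n_cols);
    db.zeros(b.n_elem);
    std::vector<Feat> dx(N);
    for (int n = 0; n < N; ++n) {
      dW += in[n].m.t() * dy[n].m;
      db += arma::sum(dy[n].m, 0).t();
      dx[n].h = in[n].h;
      dx[n].w = in[n].w;
      dx[n].m = dy[n].m * W.t();
    }
    return dx;
  }
};

// ---------------------------------------------------------------------------
// whole-network assembly
// ---------------------------------------------------------------------------

struct Net {
  std::vector<ConvLayer> trunk, strA, strB, fin;
  std::vector<int> poolAfter;  // per strB conv: 1 if a pool follows
  PoolLayer pool1, pool2;
  bool merge_cat = false;
  TConvLayer up1, up2;
  ClsLayer cls;
  float bn_eps;

  void load(const List &params, const List &plan) {
    bn_eps = as<double>(plan["bn_eps"]);
    IntegerVector stridesA = plan["strides_a"];
    IntegerVector poolB = plan["pool_b"];
    merge_cat = as<int>(plan["merge_cat"]) == 1;
    int n_in = as<int>(plan["n_input"]), nf = as<int>(plan["n_final"]);
    int li = 0;
    auto load_conv = [&](ConvLayer &L, int stride) {
      List lay = params[li++];
      NumericVector w = lay["W"];
      IntegerVector d = w.attr("dim");
      L.k = d[0];
      L.stride = stride;
      L.W = get_fmat(lay, "W", d[3]);
      L.bn.gamma = get_fvec(lay, "gamma");
      L.bn.beta = get_fvec(lay, "beta");
      L.bn.rmean = get_fvec(lay, "rmean");
      L.bn.rvar = get_fvec(lay, "rvar");
      L.bn.eps = bn_eps;
    };
    trunk.resize(n_in);
    for (int i = 0; i < n_in; ++i) load_conv(trunk[i], 1);
    strA.resize(stridesA.size());
    for (int i = 0; i < (int)strA.size(); ++i) load_conv(strA[i], stridesA[i]);
    strB.resize(poolB.size());
    poolAfter.assign(poolB.begin(), poolB.end());
    for (int i = 0; i < (int)strB.size(); ++i) load_conv(strB[i], 1);
    fin.resize(nf);
    for (int i = 0; i < nf; ++i) load_conv(fin[i], 1);
    auto load_tconv = [&](TConvLayer &L) {
      List lay = params[li++];
      NumericVector w = lay["W"];
      IntegerVector d = w.attr("dim");
      L.W = get_fmat(lay, "W", d[3]);  // (k*k*Cout) x Cin
      L.b = get_fvec(lay, "b");
      L.bn.gamma = get_fvec(lay, "gamma");
      L.bn.beta = get_fvec(lay, "beta");
      L.bn.rmean = get_fvec(lay, "rmean");
      L.bn.rvar = get_fvec(lay, "rvar");
      L.bn.eps = bn_eps;
    };
    load_tconv(up1);
    load_tconv(up2);
    List lay = params[li++];
    NumericVector w = lay["W"];
    IntegerVector d = w.attr("dim");
    cls.W = get_fmat(lay, "W", d[3]);
    cls.b = get_fvec(lay, "b");
  }

  void set_train(bool t) {
    for (auto &L : trunk) L.train = t;
    for (auto &L : strA) L.train = t;
    for (auto &L : strB) L.train = t;
    for (auto &L : fin) L.train = t;
    up1.train = t;
    up2.train = t;
    cls.train = t;
  }

  // forward to logits (uncropped, decoder resolution)
  std::vector<Feat> forward(std::vector<Feat> xs, bool train) {
    set_train(train);
    for (auto &L : trunk) xs = L.forward(std::move(xs));
    std::vector<Feat> a = xs, b = std::move(xs);  // branch point (one copy)
    for (auto &L : strA) a = L.forward(std::move(a));
    int pi = 0;
    for (size_t i = 0; i < strB.size(); ++i) {
      b = strB[i].forward(std::move(b));
      if (poolAfter[i]) {
        b = (pi == 0 ? pool1 : pool2).forward(b, train);
        ++pi;
      }
    }
    // merge
    std::vector<Feat> m(a.size());
    for (size_t n = 0; n < a.size(); ++n) {
      m[n].h = a[n].h;
      m[n].w = a[n].w;
      m[n].m = merge_cat ? arma::join_rows(a[n].m, b[n].m)
                         : fmat(a[n].m + b[n].m);
    }
    for (auto &L : fin) m = L.forward(std::move(m));
    m = up1.forward(std::move(m));
    m = up2.forward(std::move(m));
    return cls.forward(std::move(m));
  }

  // backward from logits gradient; fills layer grads
  void backward(std::vector<Feat> dlogits) {
    std::vector<Feat> d = cls.backward(dlogits);
    d = up2.backward(d);
    d = up1.backward(d);
    for (int i = fin.size() - 1; i >= 0; --i) d = fin[i].backward(d);
    const int Ca = strA.back().W.n_cols;
    std::vector<Feat> da(d.size()), db(d.size());
    for (size_t n = 0; n < d.size(); ++n) {
      da[n].h = db[n].h = d[n].h;
      da[n].w = db[n].w = d[n].w;
      if (merge_cat) {
        da[n].m = d[n].m.cols(0, Ca - 1);
        db[n].m = d[n].m.cols(Ca, d[n].m.n_cols - 1);
      } else {
        da[n].m = d[n].m;
        db[n].m = d[n].m;
      }
    }
    for (int i = strA.size() - 1; i >= 0; --i) da = strA[i].backward(da);
    int pi = 0;
    for (size_t i = 0; i < strB.size(); ++i)
      if (poolAfter[i]) ++pi;
    for (int i = strB.size() - 1; i >= 0; --i) {
      if (poolAfter[i]) db = (--pi == 0 ? pool1 : pool2).backward(db);
      db = strB[i].backward(db);
    }
    for (size_t n = 0; n < da.size(); ++n) da[n].m += db[n].m;
    for (int i = trunk.size() - 1; i >= 0; --i) da = trunk[i].backward(da);
  }

  List grads() const {
    List out;
    auto conv_grad = [](const ConvLayer &L) {
      return List::create(_["W"] = from_mat(L.dW, IntegerVector::create(
                              L.k, L.k, L.dW.n_rows / (L.k * L.k), L.dW.n_cols)),
                          _["gamma"] = from_mat(L.bn.dgamma,
                                                IntegerVector::create(L.bn.dgamma.n_elem)),
                          _["beta"] = from_mat(L.bn.dbeta,
                                               IntegerVector::create(L.bn.dbeta.n_elem)));
    };
    for (const auto &L : trunk) out.push_back(conv_grad(L));
    for (const auto &L : strA) out.push_back(conv_grad(L));
    for (const auto &L : strB) out.push_back(conv_grad(L));
    for (const auto &L : fin) out.push_back(conv_grad(L));
    auto tconv_grad = [](const TConvLayer &L) {
      int Cout = L.b.n_elem;
      return List::create(_["W"] = from_mat(L.dW, IntegerVector::create(
                              4, 4, Cout, L.dW.n_cols)),
                          _["b"] = from_mat(L.db, IntegerVector::create(Cout)),
                          _["gamma"] = from_mat(L.bn.dgamma,
                                                IntegerVector::create(Cout)),
                          _["beta"] = from_mat(L.bn.dbeta,
                                               IntegerVector::create(Cout)));
    };
    out.push_back(tconv_grad(up1));
    out.push_back(tconv_grad(up2));
    out.push_back(List::create(
        _["W"] = from_mat(cls.dW, IntegerVector::create(1, 1, cls.dW.n_rows,
                                                        cls.dW.n_cols)),
        _["b"] = from_mat(cls.db, IntegerVector::create(cls.db.n_elem))));
    return out;
  }

  List bn_state() const {
    List out;
    auto push_conv = [&](const ConvLayer &L) {
      out.push_back(List::create(
          _["rmean"] = from_mat(L.bn.rmean, IntegerVector::create(L.bn.rmean.n_elem)),
          _["rvar"] = from_mat(L.bn.rvar, IntegerVector::create(L.bn.rvar.n_elem))));
    };
    for (const auto &L : trunk) push_conv(L);
    for (const auto &L : strA) push_conv(L);
    for (const auto &L : strB) push_conv(L);
    for (const auto &L : fin) push_conv(L);
    for (const TConvLayer *L : {&up1, &up2})
      out.push_back(List::create(
          _["rmean"] = from_mat(L->bn.rmean, IntegerVector::create(L->bn.rmean.n_elem)),
          _["rvar"] = from_mat(L->bn.rvar, IntegerVector::create(L->bn.rvar.n_elem))));
    out.push_back(R_NilValue);  // classifier has no BN
    return out;
  }
};

// crop the decoder output (size 4*ceil(ceil(H/4)) >= H) centrally to H x W
void crop_to(const Feat &big, int H, int W, Feat &out) {
  int di = (big.h - H) / 2, dj = (big.w - W) / 2;
  out.h = H;
  out.w = W;
  out.m.set_size((size_t)H * W, big.m.n_cols);
  for (uword c = 0; c < big.m.n_cols; ++c) {
    const float *src = big.m.colptr(c);
    float *dst = out.m.colptr(c);
    for (int j = 0; j < W; ++j)
      std::memcpy(dst + (size_t)H * j, src + (size_t)(j + dj) * big.h + di,
                  sizeof(float) * H);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_net_predict(List params, List plan, NumericVector image) {
  Net net;
  net.load(params, plan);
  IntegerVector d = image.attr("dim");
  std::vector<Feat> xs(1);
  xs[0] = to_feat(image);
  std::vector<Feat> logits = net.forward(std::move(xs), false);
  Feat lg;
  crop_to(logits[0], d[0], d[1], lg);
  // per-pixel softmax (rows are pixels)
  fvec mx = arma::max(lg.m, 1);
  lg.m.each_col() -= mx;
  lg.m = arma::exp(lg.m);
  fvec s = arma::sum(lg.m, 1);
  lg.m.each_col() /= s;
  return List::create(
      _["prob"] = from_mat(lg.m, IntegerVector::create(d[0], d[1], lg.m.n_cols)),
      _["enc_h"] = (int)((d[0] + 1) / 2 + 1) / 2,
      _["enc_w"] = (int)((d[1] + 1) / 2 + 1) / 2);
}

// One optimisation step's worth of work for a mini-batch: forward pass,
// Generalized Dice Loss with squared-inverse class-volume weights computed
// on the batch, backward pass. Returns loss, pixel accuracy, gradients and
// updated BN running moments.
// [[Rcpp::export]]
List cpp_net_batch(List params, List plan, List images, List masks,
                   double weight_cap) {
  Net net;
  net.load(params, plan);
  const int N = images.size();
  std::vector<Feat> xs(N);
  std::vector<int> H(N), Wd(N);
  for (int n = 0; n < N; ++n) {
    NumericVector im = images[n];
    IntegerVector d = im.attr("dim");
    H[n] = d[0];
    Wd[n] = d[1];
    xs[n] = to_feat(im);
  }
  std::vector<Feat> logits = net.forward(std::move(xs), true);

  // softmax + GDL over the batch (class 0 background, class 1 vessel)
  std::vector<fmat> p(N), r(N);
  double V0 = 0, V1 = 0, P0 = 0, P1 = 0, inter0 = 0, inter1 = 0;
  double correct = 0, total = 0;
  for (int n = 0; n < N; ++n) {
    Feat lg;
    crop_to(logits[n], H[n], Wd[n], lg);
    fvec mx = arma::max(lg.m, 1);
    lg.m.each_col() -= mx;
    lg.m = arma::exp(lg.m);
    fvec s = arma::sum(lg.m, 1);
    lg.m.each_col() /= s;
    p[n] = lg.m;
    NumericVector mk = masks[n];
    fvec mv(mk.size());
    for (int i = 0; i < mk.size(); ++i) mv[i] = (float)mk[i];
    r[n] = fmat(mv.n_elem, 2);
    r[n].col(1) = mv;
    r[n].col(0) = 1.0f - mv;
    V0 += arma::accu(r[n].col(0));
    V1 += arma::accu(r[n].col(1));
    P0 += arma::accu(p[n].col(0));
    P1 += arma::accu(p[n].col(1));
    inter0 += arma::dot(r[n].col(0), p[n].col(0));
    inter1 += arma::dot(r[n].col(1), p[n].col(1));
    arma::uvec pred = arma::index_max(p[n], 1);
    correct += arma::accu((arma::conv_to<fvec>::from(pred) - mv) == 0);
    total += mv.n_elem;
  }
  double w0 = V0 > 0 ? 1.0 / (V0 * V0) : weight_cap;
  double w1 = V1 > 0 ? 1.0 / (V1 * V1) : weight_cap;
  double num = w0 * inter0 + w1 * inter1;
  double den = w0 * (V0 + P0) + w1 * (V1 + P1);
  double loss = 1.0 - 2.0 * num / den;

  // dL/dp then softmax backward; embed cropped grad into decoder grid
  std::vector<Feat> dlog(N);
  for (int n = 0; n < N; ++n) {
    fmat dp(p[n].n_rows, 2);
    dp.col(0) = arma::conv_to<fvec>::from(
        (-2.0 * w0 / den) * (arma::conv_to<arma::vec>::from(r[n].col(0)) - num / den));
    dp.col(1) = arma::conv_to<fvec>::from(
        (-2.0 * w1 / den) * (arma::conv_to<arma::vec>::from(r[n].col(1)) - num / den));
    fvec dot = arma::sum(dp % p[n], 1);
    fmat dz = p[n] % (dp.each_col() - dot);
    // uncrop
    const Feat &big = logits[n];
    dlog[n].h = big.h;
    dlog[n].w = big.w;
    dlog[n].m.zeros(big.m.n_rows, big.m.n_cols);
    int di = (big.h - H[n]) / 2, dj = (big.w - Wd[n]) / 2;
    for (uword c = 0; c < 2; ++c) {
      const float *src = dz.colptr(c);
      float *dst = dlog[n].m.colptr(c);
      for (int j = 0; j < Wd[n]; ++j)
        std::memcpy(dst + (size_t)(j + dj) * big.h + di, src + (size_t)H[n] * j,
                    sizeof(float) * H[n]);
    }
  }
  net.backward(std::move(dlog));
  return List::create(_["loss"] = loss, _["acc"] = correct / total,
                      _["grads"] = net.grads(), _["bn"] = net.bn_state());
}

// plain convolution primitive (no BN/ReLU) for cross-checking against a
// direct R oracle on small inputs
// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, int stride) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  Feat f = to_feat(x);
  int k = dw[0], Cout = dw[3];
  fmat W(w.size() / Cout, Cout);
  for (int c = 0; c < Cout; ++c)
    for (size_t r2 = 0; r2 < W.n_rows; ++r2)
      W(r2, c) = (float)w[(size_t)c * W.n_rows + r2];
  int ho, wo, pt, pl;
  same_geom(f.h, stride, k, ho, pt);
  same_geom(f.w, stride, k, wo, pl);
  fmat cols;
  im2col(f, k, stride, ho, wo, pt, pl, cols);
  fmat z = cols * W;
  return from_mat(z, IntegerVector::create(ho, wo, Cout));
}

// ceil-mode 2x2/stride-2 max pooling primitive for tests
// [[Rcpp::export]]
NumericVector cpp_maxpool2(NumericVector x) {
  Feat f = to_feat(x);
  PoolLayer pl;
  std::vector<Feat> v(1);
  v[0] = f;
  std::vector<Feat> o = pl.forward(v, false);
  return from_mat(o[0].m, IntegerVector::create(o[0].h, o[0].w, o[0].m.n_cols));
}
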