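// Core network engine: 3D spatially separable convolution blocks with
// batch normalization, ReLU, SAME max pooling, global average pooling,
// covariate fusion and a dense regression head.
//
// Activations are stored channels-first: a C x (V * B) matrix whose
// column index is voxel (column-major i, j, k) plus V * subject.  Each
// asymmetric convolution builds a shifted stack Xs ((N*C) x (V*B)) and
// performs one small-by-wide GEMM, the cache-friendly orientation for
// one-CPU BLAS.  The stacks built during the forward pass are kept and
// reused by the backward pass (which therefore must follow a forward
// call on the same batch, as the training loop guarantees).
//
// The engine is templated on the floating type: float64 for exact /
// oracle work, float32 for the large seeded training runs where memory
// bandwidth dominates.
#include <RcppArmadillo.h>
#include <cstring>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Large activation buffers are allocated and freed once per batch; keep
// them on the heap (rather than per-call mmap/munmap) so the pages stay
// warm across training steps.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    // big buffers via the heap (not per-call mmap/munmap), but let the
    // heap top shrink back so finished phases return memory to the OS
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 128 << 20);
    done = true;
  }
#endif
}

// Fill Xs rows [t*cin, (t+1)*cin) with A shifted by (t - N/2) voxels
// along `axis`, zero outside (SAME padding), per subject block.
template <typename T>
static void build_stack(const Mat<T>& A, Mat<T>& Xs, const ivec& dims, int B,
                        int axis, int N) {
  const int cin = A.n_rows, n = dims[axis];
  long stride = 1, post = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  for (int a = axis + 1; a < 3; ++a) post *= dims[a];
  post *= B;
  const uword nr = (uword)N * cin;
  if (Xs.n_rows != nr || Xs.n_cols != A.n_cols) Xs.set_size(nr, A.n_cols);
  for (int t = 0; t < N; ++t) {
    const int off = t - N / 2;
    const int x0 = std::max(0, -off), x1 = n - 1 - std::max(0, off);
    const long c0 = (long)x0 * stride;
    const long span = x1 >= x0 ? (long)(x1 - x0 + 1) * stride : 0;
    for (long r = 0; r < post; ++r) {
      const long base = r * n * stride;
      const long shift = (long)off * stride;
      // zero the padded ends, copy the valid middle
      for (long c = 0; c < c0; ++c)
        std::memset(Xs.colptr(base + c) + (uword)t * cin, 0,
                    sizeof(T) * cin);
      for (long c = c0 + span; c < (long)n * stride; ++c)
        std::memset(Xs.colptr(base + c) + (uword)t * cin, 0,
                    sizeof(T) * cin);
      for (long c = 0; c < span; ++c)
        std::memcpy(Xs.colptr(base + c0 + c) + (uword)t * cin,
                    A.colptr(base + c0 + c + shift), sizeof(T) * cin);
    }
  }
}

// Backward: scatter dXs (stacked) back into dA, reversing the shifts.
template <typename T>
static void scatter_stack(const Mat<T>& dXs, Mat<T>& dA, const ivec& dims,
                          int B, int axis, int N) {
  const int cin = dA.n_rows, n = dims[axis];
  long stride = 1, post = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  for (int a = axis + 1; a < 3; ++a) post *= dims[a];
  post *= B;
  for (int t = 0; t < N; ++t) {
    const int off = t - N / 2;
    const int x0 = std::max(0, -off), x1 = n - 1 - std::max(0, off);
    if (x1 < x0) continue;
    const long c0 = (long)x0 * stride, span = (long)(x1 - x0 + 1) * stride;
    for (long r = 0; r < post; ++r) {
      const long base = r * n * stride;
      const long shift = (long)off * stride;
      for (long c = 0; c < span; ++c) {
        T* dst = dA.colptr(base + c0 + c + shift);
        const T* src = dXs.colptr(base + c0 + c) + (uword)t * cin;
        for (int i = 0; i < cin; ++i) dst[i] += src[i];
      }
    }
  }
}

// --- SAME max pooling, window 3, stride 2 --------------------------------
static void pool_dims(const ivec& din, ivec& dout, ivec& pad) {
  dout.set_size(3); pad.set_size(3);
  for (int a = 0; a < 3; ++a) {
    dout[a] = (din[a] + 1) / 2;
    int tot = (dout[a] - 1) * 2 + 3 - din[a];
    pad[a] = tot > 0 ? tot / 2 : 0;
  }
}

template <typename T>
static void maxpool_fwd(const Mat<T>& X, const ivec& din, int B, Mat<T>& Y,
                        umat& idx, ivec& dout) {
  ivec pad;
  pool_dims(din, dout, pad);
  const long Vin = (long)din[0] * din[1] * din[2];
  const long Vout = (long)dout[0] * dout[1] * dout[2];
  const int C = X.n_rows;
  Y.set_size(C, Vout * B);
  idx.set_size(C, Vout * B);
  for (int b = 0; b < B; ++b) {
    const long ibase = (long)b * Vin, obase = (long)b * Vout;
    for (int ok = 0; ok < dout[2]; ++ok) {
      int k0 = std::max(0, 2 * ok - (int)pad[2]);
      int k1 = std::min((int)din[2] - 1, 2 * ok - (int)pad[2] + 2);
      for (int oj = 0; oj < dout[1]; ++oj) {
        int j0 = std::max(0, 2 * oj - (int)pad[1]);
        int j1 = std::min((int)din[1] - 1, 2 * oj - (int)pad[1] + 2);
        for (int oi = 0; oi < dout[0]; ++oi) {
          int i0 = std::max(0, 2 * oi - (int)pad[0]);
          int i1 = std::min((int)din[0] - 1, 2 * oi - (int)pad[0] + 2);
          long ocol = obase + oi + (long)dout[0] * (oj + (long)dout[1] * ok);
          T* yp = Y.colptr(ocol);
          uword* ip = idx.colptr(ocol);
          bool first = true;
          for (int k = k0; k <= k1; ++k)
            for (int j = j0; j <= j1; ++j)
              for (int i = i0; i <= i1; ++i) {
                long col = ibase + i + (long)din[0] * (j + (long)din[1] * k);
                const T* xp = X.colptr(col);
                if (first) {
                  for (int c = 0; c < C; ++c) { yp[c] = xp[c]; ip[c] = col; }
                  first = false;
                } else {
                  for (int c = 0; c < C; ++c)
                    if (xp[c] > yp[c]) { yp[c] = xp[c]; ip[c] = col; }
                }
              }
        }
      }
    }
  }
}

template <typename T>
static void maxpool_bwd(const Mat<T>& dY, const umat& idx, long incols,
                        Mat<T>& dX) {
  dX.zeros(dY.n_rows, incols);
  const int C = dY.n_rows;
  for (uword col = 0; col < dY.n_cols; ++col) {
    const T* dyp = dY.colptr(col);
    const uword* ip = idx.colptr(col);
    for (int c = 0; c < C; ++c) dX(c, ip[c]) += dyp[c];
  }
}

// --- network -------------------------------------------------------------
template <typename T>
struct Block {
  int N, cin, cout;
  bool pool;
  // Wcat: cout x (N*cin), columns in stack order (tap-major, cin inner);
  // the transpose of the flat ((N*cin) x cout) parameter layout.
  Mat<T> W1, W2, W3;
  Col<T> b1, b2, b3, gamma, beta, rmean, rvar;
  Mat<T> Xs1, Xs2, Xs3;           // forward shifted stacks (reused by bwd)
  Mat<T> c1, c2, xhat, act, pooled;
  Col<T> invstd;
  umat pidx;
  ivec din, dpool;
  Mat<T> dW1, dW2, dW3;
  Col<T> db1, db2, db3, dgamma, dbeta;
};

template <typename T>
class NetCtx {
public:
  ivec in_dims;
  int hidden, ncov;
  bool use_cov;
  T bn_eps, bn_mom;
  std::vector<Block<T>> blocks;
  Mat<T> Wh;          // zin x hidden (R layout)
  Col<T> bh, Wo;      // hidden
  T bo;
  Mat<T> dWh; Col<T> dbh, dWo; T dbo;
  Mat<T> X0, g, z, preh, hdrop, dmask;
  int curB = 0;
  bool training = false;
  long lastZ = 0;
  ivec last_dims;

  void set_params(const vec& p) {
    uword o = 0;
    auto getW = [&](Mat<T>& W, uword nr, uword nc) {
      // stored ((N*cin) x cout) column-major; engine wants the transpose
      W.set_size(nc, nr);
      for (uword c = 0; c < nc; ++c)
        for (uword r = 0; r < nr; ++r)
          W(c, r) = (T)p[o + c * nr + r];
      o += nr * nc;
    };
    auto getv = [&](Col<T>& v, uword n) {
      v = conv_to<Col<T>>::from(p.subvec(o, o + n - 1)); o += n;
    };
    for (auto& B : blocks) {
      getW(B.W1, (uword)B.N * B.cin, B.cout);  getv(B.b1, B.cout);
      getW(B.W2, (uword)B.N * B.cout, B.cout); getv(B.b2, B.cout);
      getW(B.W3, (uword)B.N * B.cout, B.cout); getv(B.b3, B.cout);
      getv(B.gamma, B.cout); getv(B.beta, B.cout);
    }
    int zin = blocks.back().cout + (use_cov ? ncov : 0);
    Wh.set_size(zin, hidden);
    for (uword i = 0; i < Wh.n_elem; ++i) Wh[i] = (T)p[o + i];
    o += Wh.n_elem;
    getv(bh, hidden);
    getv(Wo, hidden);
    bo = (T)p[o++];
    if (o != p.n_elem) Rcpp::stop("parameter vector length mismatch");
  }

  vec get_grad() const {
    std::vector<double> out;
    auto pushW = [&](const Mat<T>& dW) { // transpose back to flat layout
      for (uword c = 0; c < dW.n_rows; ++c)       // c indexes cout
        for (uword r = 0; r < dW.n_cols; ++r)
          out.push_back((double)dW(c, r));
    };
    auto pushv = [&](const Col<T>& v) {
      for (uword i = 0; i < v.n_elem; ++i) out.push_back((double)v[i]);
    };
    for (auto& B : blocks) {
      pushW(B.dW1); pushv(B.db1);
      pushW(B.dW2); pushv(B.db2);
      pushW(B.dW3); pushv(B.db3);
      pushv(B.dgamma); pushv(B.dbeta);
    }
    for (uword i = 0; i < dWh.n_elem; ++i) out.push_back((double)dWh[i]);
    pushv(dbh); pushv(dWo); out.push_back((double)dbo);
    return vec(out);
  }

  void set_running(const vec& r) {
    uword o = 0;
    for (auto& B : blocks) {
      B.rmean = conv_to<Col<T>>::from(r.subvec(o, o + B.cout - 1));
      o += B.cout;
      B.rvar = conv_to<Col<T>>::from(r.subvec(o, o + B.cout - 1));
      o += B.cout;
    }
    if (o != r.n_elem) Rcpp::stop("running-stat vector length mismatch");
  }

  vec get_running() const {
    std::vector<double> out;
    for (auto& B : blocks) {
      for (uword i = 0; i < B.rmean.n_elem; ++i)
        out.push_back((double)B.rmean[i]);
      for (uword i = 0; i < B.rvar.n_elem; ++i)
        out.push_back((double)B.rvar[i]);
    }
    return vec(out);
  }

  static void conv_fwd(const Mat<T>& A, const ivec& dims, int B, int axis,
                       const Mat<T>& Wcat, const Col<T>& b, int N,
                       Mat<T>& Xs, Mat<T>& out) {
    build_stack(A, Xs, dims, B, axis, N);
    out = Wcat * Xs;
    out.each_col() += b;
  }

  // Uses the cached forward stack Xs; Ain only supplies dimensions.
  static void conv_bwd(const Mat<T>& dY, const Mat<T>& Xs, uword cin,
                       const ivec& dims, int B, int axis, const Mat<T>& Wcat,
                       int N, Mat<T>& dWcat, Col<T>& db, Mat<T>& dA) {
    dWcat = dY * Xs.t();
    db = sum(dY, 1);
    Mat<T> dXs = Wcat.t() * dY;
    dA.zeros(cin, dY.n_cols);
    scatter_stack(dXs, dA, dims, B, axis, N);
  }

  // Forward one batch.  X: 1 x (V*B), cov: ncov x B,
  // dropmask: hidden x B (scaled by 1/keep; all ones in evaluation).
  Col<T> forward(const Mat<T>& X, int B, const Mat<T>& cov, bool train,
                 const Mat<T>& dropmask) {
    curB = B; training = train; X0 = X; dmask = dropmask;
    ivec dims = in_dims;
    const Mat<T>* cur = &X0;
    for (auto& Bl : blocks) {
      Bl.din = dims;
      conv_fwd(*cur, dims, B, 0, Bl.W1, Bl.b1, Bl.N, Bl.Xs1, Bl.c1);
      conv_fwd(Bl.c1, dims, B, 1, Bl.W2, Bl.b2, Bl.N, Bl.Xs2, Bl.c2);
      Mat<T> c3;
      conv_fwd(Bl.c2, dims, B, 2, Bl.W3, Bl.b3, Bl.N, Bl.Xs3, c3);
      const long ncol = c3.n_cols;
      const int C = Bl.cout;
      Col<T> m(C), v(C);
      if (train) {
        Col<T> ones_n(ncol, fill::ones);
        m = c3 * ones_n / (T)ncol;
        // two-pass variance: E[(x - m)^2], not E[x^2] - m^2 (the latter
        // cancels catastrophically in single precision when |m| >> sd)
        v.zeros(C);
        for (long col = 0; col < ncol; ++col) {
          const T* xp = c3.colptr(col);
          for (int c = 0; c < C; ++c) {
            const T d = xp[c] - m[c];
            v[c] += d * d;
          }
        }
        v /= (T)ncol;
        Bl.rmean = bn_mom * Bl.rmean + ((T)1 - bn_mom) * m;
        Bl.rvar = bn_mom * Bl.rvar + ((T)1 - bn_mom) * v;
      } else {
        m = Bl.rmean;
        v = Bl.rvar;
      }
      Bl.invstd = (T)1 / sqrt(v + bn_eps);
      // fused normalize + scale/shift + ReLU, one pass
      Bl.xhat.set_size(C, ncol);
      Bl.act.set_size(C, ncol);
      for (long col = 0; col < ncol; ++col) {
        const T* xp = c3.colptr(col);
        T* xh = Bl.xhat.colptr(col);
        T* ac = Bl.act.colptr(col);
        for (int c = 0; c < C; ++c) {
          const T h = (xp[c] - m[c]) * Bl.invstd[c];
          xh[c] = h;
          const T a = h * Bl.gamma[c] + Bl.beta[c];
          ac[c] = a > (T)0 ? a : (T)0;
        }
      }
      if (Bl.pool) {
        maxpool_fwd(Bl.act, dims, B, Bl.pooled, Bl.pidx, Bl.dpool);
        dims = Bl.dpool;
        cur = &Bl.pooled;
      } else {
        Bl.dpool = dims;
        cur = &Bl.act;
      }
    }
    last_dims = dims;
    const long Z = (long)dims[0] * dims[1] * dims[2];
    lastZ = Z;
    const int C = blocks.back().cout;
    g.set_size(C, B);
    Col<T> ones_z(Z, fill::ones);
    for (int b = 0; b < B; ++b)
      g.col(b) = cur->cols((uword)b * Z, (uword)(b + 1) * Z - 1) * ones_z /
        (T)Z;
    z = use_cov ? join_cols(g, cov) : g;
    preh = Wh.t() * z;         // hidden x B
    preh.each_col() += bh;
    hdrop = clamp(preh, (T)0, std::numeric_limits<T>::infinity());
    if (train) hdrop %= dmask;
    Col<T> y = hdrop.t() * Wo + bo;
    return y;
  }

  // Must follow a forward() call on the same batch.
  void backward(const Col<T>& dy) {
    const int B = curB, C = blocks.back().cout;
    const long Z = lastZ;
    dWo = hdrop * dy;                  // hidden
    dbo = accu(dy);
    Mat<T> dhd = Wo * dy.t();          // hidden x B
    if (training) dhd %= dmask;
    Mat<T> dpreh = dhd % conv_to<Mat<T>>::from(preh > (T)0);
    dWh = z * dpreh.t();               // zin x hidden
    dbh = sum(dpreh, 1);
    Mat<T> dz = Wh * dpreh;            // zin x B
    Mat<T> dg = dz.rows(0, C - 1);
    Mat<T> dcur(C, (uword)Z * B);
    for (int b = 0; b < B; ++b)
      dcur.cols((uword)b * Z, (uword)(b + 1) * Z - 1) =
        repmat(dg.col(b) / (T)Z, 1, Z);
    for (int bi = (int)blocks.size() - 1; bi >= 0; --bi) {
      Block<T>& Bl = blocks[bi];
      Mat<T> dact;
      if (Bl.pool) maxpool_bwd(dcur, Bl.pidx, Bl.act.n_cols, dact);
      else dact = std::move(dcur);
      const long ncol = dact.n_cols;
      const int Cb = Bl.cout;
      // fused ReLU-mask + batch-norm backward statistics, one pass
      Bl.dgamma.zeros(Cb);
      Bl.dbeta.zeros(Cb);
      Col<T> sdx(Cb, fill::zeros), sdxx(Cb, fill::zeros);
      for (long col = 0; col < ncol; ++col) {
        T* da = dact.colptr(col);
        const T* ac = Bl.act.colptr(col);
        const T* xh = Bl.xhat.colptr(col);
        for (int c = 0; c < Cb; ++c) {
          const T d = ac[c] > (T)0 ? da[c] : (T)0;
          da[c] = d;                   // masked dact in place
          Bl.dgamma[c] += d * xh[c];
          Bl.dbeta[c] += d;
          const T dxh = d * Bl.gamma[c];
          sdx[c] += dxh;
          sdxx[c] += dxh * xh[c];
        }
      }
      Mat<T> dc3(Cb, ncol);
      if (training) {
        const Col<T> mdx = sdx / (T)ncol, mdxx = sdxx / (T)ncol;
        for (long col = 0; col < ncol; ++col) {
          const T* da = dact.colptr(col);
          const T* xh = Bl.xhat.colptr(col);
          T* d3 = dc3.colptr(col);
          for (int c = 0; c < Cb; ++c)
            d3[c] = (da[c] * Bl.gamma[c] - mdx[c] - xh[c] * mdxx[c]) *
              Bl.invstd[c];
        }
      } else {
        for (long col = 0; col < ncol; ++col) {
          const T* da = dact.colptr(col);
          T* d3 = dc3.colptr(col);
          for (int c = 0; c < Cb; ++c)
            d3[c] = da[c] * Bl.gamma[c] * Bl.invstd[c];
        }
      }
      Mat<T> dc2, dc1, dx;
      conv_bwd(dc3, Bl.Xs3, Bl.cout, Bl.din, B, 2, Bl.W3, Bl.N,
               Bl.dW3, Bl.db3, dc2);
      conv_bwd(dc2, Bl.Xs2, Bl.cout, Bl.din, B, 1, Bl.W2, Bl.N,
               Bl.dW2, Bl.db2, dc1);
      conv_bwd(dc1, Bl.Xs1, Bl.cin, Bl.din, B, 0, Bl.W1, Bl.N,
               Bl.dW1, Bl.db1, dx);
      dcur = std::move(dx);
    }
  }
};

// Type-erased holder so both precisions share one external pointer API.
struct NetAny {
  virtual ~NetAny() {}
  virtual void set_params(const vec&) = 0;
  virtual void set_running(const vec&) = 0;
  virtual vec get_running() const = 0;
  virtual vec get_grad() const = 0;
  virtual vec forward(const vec& X, int B, const mat& cov, bool train,
                      const mat& dmask) = 0;
  virtual void backward(const vec& dy) = 0;
  virtual mat last_features() const = 0;
  virtual ivec last_dims() const = 0;
};

template <typename T>
struct NetImpl : NetAny {
  NetCtx<T> ctx;
  void set_params(const vec& p) override { ctx.set_params(p); }
  void set_running(const vec& r) override { ctx.set_running(r); }
  vec get_running() const override { return ctx.get_running(); }
  vec get_grad() const override { return ctx.get_grad(); }
  vec forward(const vec& X, int B, const mat& cov, bool train,
              const mat& dmask) override {
    Mat<T> Xm(1, X.n_elem);
    for (uword i = 0; i < X.n_elem; ++i) Xm[i] = (T)X[i];
    Mat<T> covm = conv_to<Mat<T>>::from(cov.t());
    Mat<T> dm = conv_to<Mat<T>>::from(dmask.t());
    Col<T> y = ctx.forward(Xm, B, covm, train, dm);
    return conv_to<vec>::from(y);
  }
  void backward(const vec& dy) override {
    ctx.backward(conv_to<Col<T>>::from(dy));
  }
  mat last_features() const override {
    const Block<T>& Bl = ctx.blocks.back();
    const Mat<T>& A = Bl.pool ? Bl.pooled : Bl.act;
    return conv_to<mat>::from(A.t());
  }
  ivec last_dims() const override { return ctx.last_dims; }
};

template <typename T>
static NetAny* make_net(Rcpp::List config, const vec& params,
                        const vec& running) {
  NetImpl<T>* net = new NetImpl<T>();
  NetCtx<T>& ctx = net->ctx;
  Rcpp::IntegerVector dims = config["input_shape"];
  ctx.in_dims = ivec({dims[0], dims[1], dims[2]});
  Rcpp::IntegerVector N = config["kernel"], cin = config["cin"],
                      cout = config["cout"];
  Rcpp::LogicalVector pool = config["pool"];
  for (int i = 0; i < N.size(); ++i) {
    Block<T> b;
    b.N = N[i]; b.cin = cin[i]; b.cout = cout[i]; b.pool = pool[i];
    ctx.blocks.push_back(std::move(b));
  }
  ctx.hidden = Rcpp::as<int>(config["hidden_units"]);
  ctx.use_cov = Rcpp::as<bool>(config["use_covariates"]);
  ctx.ncov = ctx.use_cov ? Rcpp::as<int>(config["n_covariates"]) : 0;
  ctx.bn_eps = (T)Rcpp::as<double>(config["bn_eps"]);
  ctx.bn_mom = (T)Rcpp::as<double>(config["bn_momentum"]);
  ctx.set_params(params);
  ctx.set_running(running);
  return net;
}

static NetAny* ctx_from(SEXP xp) {
  Rcpp::XPtr<NetAny> p(xp);
  return p.get();
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(Rcpp::List config, Rcpp::NumericVector params,
                Rcpp::NumericVector running, std::string precision) {
  tune_allocator();
  vec p(params.begin(), params.size()), r(running.begin(), running.size());
  NetAny* net;
  if (precision == "double") net = make_net<double>(config, p, r);
  else if (precision == "single") net = make_net<float>(config, p, r);
  else Rcpp::stop("precision must be 'double' or 'single'");
  return Rcpp::XPtr<NetAny>(net, true);
}

// X is the concatenation of B volumes (voxel-major); cov is B x ncov and
// dropmask B x hidden in R orientation (transposed internally).
// [[Rcpp::export(name = ".net_forward")]]
Rcpp::NumericVector net_forward(SEXP xp, Rcpp::NumericVector X, int B,
                                Rcpp::NumericMatrix cov, bool training,
                                Rcpp::NumericMatrix dropmask) {
  vec Xv(X.begin(), X.size(), false);
  mat covm(cov.begin(), cov.nrow(), cov.ncol(), false);
  mat dm(dropmask.begin(), dropmask.nrow(), dropmask.ncol(), false);
  vec y = ctx_from(xp)->forward(Xv, B, covm, training, dm);
  return Rcpp::NumericVector(y.begin(), y.end());
}

// [[Rcpp::export(name = ".net_backward")]]
Rcpp::NumericVector net_backward(SEXP xp, Rcpp::NumericVector dy) {
  NetAny* net = ctx_from(xp);
  net->backward(vec(dy.begin(), dy.size()));
  vec gflat = net->get_grad();
  return Rcpp::NumericVector(gflat.begin(), gflat.end());
}

// Free a context's C++ buffers immediately.  R's garbage collector does
// not account for native memory held behind an external pointer, so
// long test sessions would otherwise accumulate stale contexts; the
// finalizer then sees a cleared pointer and does nothing.
// [[Rcpp::export(name = ".net_free")]]
void net_free(SEXP xp) {
  NetAny* net = (NetAny*)R_ExternalPtrAddr(xp);
  if (net != nullptr) {
    delete net;
    R_ClearExternalPtr(xp);
  }
#ifdef __GLIBC__
  malloc_trim(0);
#endif
}

// [[Rcpp::export(name = ".net_set_params")]]
void net_set_params(SEXP xp, Rcpp::NumericVector params) {
  ctx_from(xp)->set_params(vec(params.begin(), params.size()));
}

// [[Rcpp::export(name = ".net_set_running")]]
void net_set_running(SEXP xp, Rcpp::NumericVector running) {
  ctx_from(xp)->set_running(vec(running.begin(), running.size()));
}

// [[Rcpp::export(name = ".net_get_running")]]
Rcpp::NumericVector net_get_running(SEXP xp) {
  vec r = ctx_from(xp)->get_running();
  return Rcpp::NumericVector(r.begin(), r.end());
}

// Last block's post-activation feature maps from the most recent forward
// call, as a (Z*B) x C matrix (voxel-major rows) plus the spatial dims.
// [[Rcpp::export(name = ".net_last_features")]]
Rcpp::List net_last_features(SEXP xp) {
  NetAny* net = ctx_from(xp);
  ivec d = net->last_dims();
  return Rcpp::List::create(
    Rcpp::Named("features") = Rcpp::wrap(net->last_features()),
    Rcpp::Named("dims") = Rcpp::IntegerVector(d.begin(), d.end()));
}

// Standalone SAME max pooling (window 3, stride 2) for testing.
// X is (V*B) x C voxel-major.
// [[Rcpp::export(name = ".maxpool3")]]
Rcpp::List maxpool3(Rcpp::NumericMatrix X, Rcpp::IntegerVector dims, int B) {
  mat Xm = trans(mat(X.begin(), X.nrow(), X.ncol(), false));
  ivec din({dims[0], dims[1], dims[2]}), dout;
  mat Y; umat idx;
  maxpool_fwd(Xm, din, B, Y, idx, dout);
  mat Yt = Y.t();
  return Rcpp::List::create(
    Rcpp::Named("values") = Rcpp::wrap(Yt),
    Rcpp::Named("dims") = Rcpp::IntegerVector(dout.begin(), dout.end()));
}

// Standalone separable-axis convolution for testing: X (V*B) x cin
// voxel-major; W is the flat ((N*cin) x cout) layout, rows tap-major.
// [[Rcpp::export(name = ".conv_axis")]]
Rcpp::NumericMatrix conv_axis(Rcpp::NumericMatrix X, Rcpp::IntegerVector dims,
                              int B, int axis, Rcpp::NumericMatrix W,
                              Rcpp::NumericVector b, int N) {
  mat Xm = trans(mat(X.begin(), X.nrow(), X.ncol(), false));
  mat Wflat(W.begin(), W.nrow(), W.ncol(), false);
  mat Wcat = Wflat.t();
  vec bv(b.begin(), b.size());
  ivec dv({dims[0], dims[1], dims[2]});
  mat out, Xs;
  NetCtx<double>::conv_fwd(Xm, dv, B, axis, Wcat, bv, N, Xs, out);
  mat outt = out.t();
  return Rcpp::wrap(outt);
}
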