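// Separable B-spline resampling and rigid in-plane rotation for 3D
// volumes.  Orders 0-5 are supported; orders >= 2 use the standard
// recursive prefilter (pole decomposition, mirror boundary) so that the
// interpolant passes through the original samples.
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

static void spline_poles(int order, std::vector<double>& z) {
  z.clear();
  switch (order) {
  case 2: z.push_back(std::sqrt(8.0) - 3.0); break;
  case 3: z.push_back(std::sqrt(3.0) - 2.0); break;
  case 4:
    z.push_back(-0.361341225900220177092212841325);
    z.push_back(-0.013725429297339121360331226939);
    break;
  case 5:
    z.push_back(-0.430575347099973791851434783493);
    z.push_back(-0.043096288203264653822712376822);
    break;
  default: break; // orders 0 and 1 need no prefilter
  }
}

// In-place recursive filter along a strided line (length n, step stride).
static void filter_line(double* c, int n, int stride, double zp) {
  if (n == 1) return;
  const double gain = (1.0 - zp) * (1.0 - 1.0 / zp);
  for (int i = 0; i < n; ++i) c[i * stride] *= gain;
  // causal initialization, mirror boundary
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(zp)));
  double cp;
  if (horizon < n) {
    double zn = zp;
    cp = c[0];
    for (int k = 1; k < horizon; ++k) { cp += zn * c[k * stride]; zn *= zp; }
  } else {
    double zn = zp, z2n = std::pow(zp, n - 1), iz = 1.0 / zp;
    cp = c[0] + z2n * c[(n - 1) * stride];
    z2n *= z2n * iz;
    for (int k = 1; k <= n - 2; ++k) {
      cp += (zn + z2n) * c[k * stride];
      zn *= zp; z2n *= iz;
    }
    cp /= (1.0 - std::pow(zp, 2 * n - 2));
  }
  c[0] = cp;
  for (int i = 1; i < n; ++i) c[i * stride] += zp * c[(i - 1) * stride];
  c[(n - 1) * stride] = (zp / (zp * zp - 1.0)) *
    (zp * c[(n - 2) * stride] + c[(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = zp * (c[(i + 1) * stride] - c[i * stride]);
}

// Prefilter a 3D array along one axis.
static void prefilter_axis(double* a, const int* dims, int axis, int order) {
  if (order < 2) return;
  std::vector<double> poles;
  spline_poles(order, poles);
  int stride = 1, n = dims[axis], post = 1;
  for (int i = 0; i < axis; ++i) stride *= dims[i];
  for (int i = axis + 1; i < 3; ++i) post *= dims[i];
  for (int r = 0; r < post; ++r)
    for (int p = 0; p < stride; ++p) {
      double* line = a + (long)r * n * stride + p;
      for (double zp : poles) filter_line(line, n, stride, zp);
    }
}

// Centered B-spline basis of degree n via the two-scale recursion.
static double bspline_kern(int n, double u) {
  if (n == 0) {
    if (u > -0.5 && u < 0.5) return 1.0;
    if (u == -0.5 || u == 0.5) return 0.5;
    return 0.0;
  }
  const double h = (n + 1) / 2.0;
  if (u <= -h || u >= h) return 0.0;
  return ((u + h) * bspline_kern(n - 1, u + 0.5) +
          (h - u) * bspline_kern(n - 1, u - 0.5)) / n;
}

// Tap start index and weights for evaluating at position x.
static int spline_taps(int order, double x, double* w) {
  int i0;
  if (order == 0) {
    i0 = (int)std::floor(x + 0.5);
    w[0] = 1.0;
    return i0;
  }
  if (order % 2 == 1) i0 = (int)std::floor(x) - (order - 1) / 2;
  else i0 = (int)std::floor(x + 0.5) - order / 2;
  for (int j = 0; j <= order; ++j) w[j] = bspline_kern(order, x - (i0 + j));
  return i0;
}

// Mirror (reflect about edge samples) index into [0, n-1].
static int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i = std::abs(i) % period;
  return i < n ? i : period - i;
}

// Resample one axis to a new length with endpoint-aligned coordinates:
// output index i maps to input coordinate i * (n_in-1)/(n_out-1).
static void resample_axis(const std::vector<double>& in, const int* dims,
                          int axis, int nout, int order,
                          std::vector<double>& out, int* odims) {
  int nin = dims[axis];
  odims[0] = dims[0]; odims[1] = dims[1]; odims[2] = dims[2];
  odims[axis] = nout;
  out.assign((long)odims[0] * odims[1] * odims[2], 0.0);
  if (nout == nin) { // identity on this axis (no prefilter round-trip)
    out = in;
    return;
  }
  std::vector<double> coef(in);
  prefilter_axis(coef.data(), dims, axis, order);
  int stride = 1, post = 1;
  for (int i = 0; i < axis; ++i) stride *= dims[i];
  for (int i = axis + 1; i < 3; ++i) post *= dims[i];
  double scale = nout > 1 ? (double)(nin - 1) / (nout - 1) : 0.0;
  double w[6];
  for (int x = 0; x < nout; ++x) {
    double xc = nout > 1 ? x * scale : (nin - 1) / 2.0;
    int i0 = spline_taps(order, xc, w);
    for (int r = 0; r < post; ++r) {
      const double* src = coef.data() + (long)r * nin * stride;
      double* dst = out.data() + (long)r * nout * stride + (long)x * stride;
      for (int j = 0; j <= order; ++j) {
        int si = mirror_idx(i0 + j, nin);
        const double* s = src + (long)si * stride;
        const double wj = w[j];
        if (wj == 0.0) continue;
        for (int p = 0; p < stride; ++p) dst[p] += wj * s[p];
      }
    }
  }
}

// [[Rcpp::export(name = ".resample3d")]]
Rcpp::NumericVector resample3d(Rcpp::NumericVector arr,
                               Rcpp::IntegerVector in_dims,
                               Rcpp::IntegerVector out_dims, int order) {
  int dims[3] = {in_dims[0], in_dims[1], in_dims[2]};
  std::vector<double> cur(arr.begin(), arr.end()), nxt;
  for (int axis = 0; axis < 3; ++axis) {
    int od[3];
    resample_axis(cur, dims, axis, out_dims[axis], order, nxt, od);
    cur.swap(nxt);
    dims[0] = od[0]; dims[1] = od[1]; dims[2] = od[2];
  }
  Rcpp::NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = Rcpp::IntegerVector::create(dims[0], dims[1], dims[2]);
  return out;
}

// Rigid in-plane rotation about one grid axis through the volume centre
// ((n-1)/2 per axis); zero fill outside the grid.
// [[Rcpp::export(name = ".rotate3d")]]
Rcpp::NumericVector rotate3d(Rcpp::NumericVector arr,
                             Rcpp::IntegerVector in_dims, int axis,
                             double angle_deg, int order) {
  const int dims[3] = {in_dims[0], in_dims[1], in_dims[2]};
  const long V = (long)dims[0] * dims[1] * dims[2];
  // in-plane axes (the two axes != rotation axis)
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> coef(arr.begin(), arr.end());
  prefilter_axis(coef.data(), dims, a1, order);
  prefilter_axis(coef.data(), dims, a2, order);
  std::vector<double> out(V, 0.0);
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double c1 = (dims[a1] - 1) / 2.0, c2 = (dims[a2] - 1) / 2.0;
  long strides[3] = {1, dims[0], (long)dims[0] * dims[1]};
  double w1[6], w2[6];
  int idx[3];
  for (idx[2] = 0; idx[2] < dims[2]; ++idx[2])
    for (idx[1] = 0; idx[1] < dims[1]; ++idx[1])
      for (idx[0] = 0; idx[0] < dims[0]; ++idx[0]) {
        // inverse-map the in-plane coordinates
        double u = idx[a1] - c1, v = idx[a2] - c2;
        double su = ct * u + st * v + c1;
        double sv = -st * u + ct * v + c2;
        if (su < -0.5 || su > dims[a1] - 0.5 ||
            sv < -0.5 || sv > dims[a2] - 0.5)
          continue; // outside: zero fill
        int i1 = spline_taps(order, su, w1);
        int i2 = spline_taps(order, sv, w2);
        double acc = 0.0;
        for (int j2 = 0; j2 <= order; ++j2) {
          int m2 = mirror_idx(i2 + j2, dims[a2]);
          double acc1 = 0.0;
          for (int j1 = 0; j1 <= order; ++j1) {
            int m1 = mirror_idx(i1 + j1, dims[a1]);
            long lin = (long)idx[axis] * strides[axis] +
              (long)m1 * strides[a1] + (long)m2 * strides[a2];
            acc1 += w1[j1] * coef[lin];
          }
          acc += w2[j2] * acc1;
        }
        long olin = (long)idx[0] + strides[1] * idx[1] + strides[2] * idx[2];
        out[olin] = acc;
      }
  Rcpp::NumericVector res(out.begin(), out.end());
  res.attr("dim") = in_dims;
  return res;
}
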