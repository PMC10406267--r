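// Volumetric layer primitives for the residual 3D U-Net.
// Arrays are column-major with dims (nx, ny, nz, channels), matching R.
// Convolution weights are (k^3 * cin) x cout matrices; the row index runs
// kernel-x fastest, then kernel-y, kernel-z, then input channel.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col3d(const double* x, int nx, int ny, int nz, int cin,
                          int k, int stride, int pad,
                          int onx, int ony, int onz) {
  const int k3 = k * k * k;
  const size_t novox = (size_t)onx * ony * onz;
  arma::mat cols(novox, (size_t)k3 * cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch) {
    const double* xc = x + (size_t)ch * nx * ny * nz;
    for (int c = 0; c < k; ++c)
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a) {
          const size_t col = (size_t)ch * k3 + (size_t)c * k * k + (size_t)b * k + a;
          double* dst = cols.colptr(col);
          for (int oz = 0; oz < onz; ++oz) {
            const int iz = oz * stride + c - pad;
            if (iz < 0 || iz >= nz) continue;
            for (int oy = 0; oy < ony; ++oy) {
              const int iy = oy * stride + b - pad;
              if (iy < 0 || iy >= ny) continue;
              const double* src = xc + ((size_t)iz * ny + iy) * nx;
              double* d = dst + ((size_t)oz * ony + oy) * onx;
              for (int ox = 0; ox < onx; ++ox) {
                const int ix = ox * stride + a - pad;
                if (ix < 0 || ix >= nx) continue;
                d[ox] = src[ix];
              }
            }
          }
        }
  }
  return cols;
}

static void out_shape(int n, int k, int stride, int pad, int* on) {
  *on = (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, NumericMatrix w, NumericVector b,
                            IntegerVector in_dim, int k, int stride, int pad) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], cin = in_dim[3];
  const int cout = w.ncol();
  int onx, ony, onz;
  out_shape(nx, k, stride, pad, &onx);
  out_shape(ny, k, stride, pad, &ony);
  out_shape(nz, k, stride, pad, &onz);
  arma::mat cols = im2col3d(x.begin(), nx, ny, nz, cin, k, stride, pad, onx, ony, onz);
  arma::mat W(w.begin(), w.nrow(), cout, false, true);
  arma::mat Y = cols * W;
  Y.each_row() += arma::rowvec(b.begin(), cout, false, true);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(onx, ony, onz, cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                   IntegerVector in_dim, int k, int stride, int pad) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], cin = in_dim[3];
  const int cout = w.ncol();
  int onx, ony, onz;
  out_shape(nx, k, stride, pad, &onx);
  out_shape(ny, k, stride, pad, &ony);
  out_shape(nz, k, stride, pad, &onz);
  const size_t novox = (size_t)onx * ony * onz;
  const int k3 = k * k * k;

  arma::mat cols = im2col3d(x.begin(), nx, ny, nz, cin, k, stride, pad, onx, ony, onz);
  arma::mat W(w.begin(), w.nrow(), cout, false, true);
  arma::mat dY(dy.begin(), novox, cout, false, true);

  arma::mat dW = cols.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dcols = dY * W.t();

  NumericVector dx((size_t)nx * ny * nz * cin);
  double* dxp = dx.begin();
  for (int ch = 0; ch < cin; ++ch) {
    double* xc = dxp + (size_t)ch * nx * ny * nz;
    for (int c = 0; c < k; ++c)
      for (int b2 = 0; b2 < k; ++b2)
        for (int a = 0; a < k; ++a) {
          const size_t col = (size_t)ch * k3 + (size_t)c * k * k + (size_t)b2 * k + a;
          const double* src = dcols.colptr(col);
          for (int oz = 0; oz < onz; ++oz) {
            const int iz = oz * stride + c - pad;
            if (iz < 0 || iz >= nz) continue;
            for (int oy = 0; oy < ony; ++oy) {
              const int iy = oy * stride + b2 - pad;
              if (iy < 0 || iy >= ny) continue;
              double* d = xc + ((size_t)iz * ny + iy) * nx;
              const double* s = src + ((size_t)oz * ony + oy) * onx;
              for (int ox = 0; ox < onx; ++ox) {
                const int ix = ox * stride + a - pad;
                if (ix < 0 || ix >= nx) continue;
                d[ix] += s[ox];
              }
            }
          }
        }
  }
  dx.attr("dim") = in_dim;
  NumericMatrix dWout(w.nrow(), cout);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(cout);
  std::copy(db.begin(), db.end(), dbout.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = dbout);
}

struct AxisMap {
  std::vector<int> i0, i1;
  std::vector<double> w1;
};

static AxisMap axis_map(int n) {
  AxisMap m;
  const int on = 2 * n;
  m.i0.resize(on);
  m.i1.resize(on);
  m.w1.resize(on);
  for (int o = 0; o < on; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    int i0 = (int)std::floor(s);
    if (i0 > n - 2) i0 = n - 2;
    if (i0 < 0) i0 = 0;
    double w1 = s - i0;
    if (n == 1) { i0 = 0; w1 = 0; }
    m.i0[o] = i0;
    m.i1[o] = (n == 1) ? 0 : i0 + 1;
    m.w1[o] = w1;
  }
  return m;
}

// Trilinear x2 upsampling (half-voxel aligned), and its adjoint for backprop.
// [[Rcpp::export]]
NumericVector upsample2_fw_cpp(NumericVector x, IntegerVector in_dim) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], nc = in_dim[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  AxisMap mx = axis_map(nx), my = axis_map(ny), mz = axis_map(nz);
  NumericVector out((size_t)ox * oy * oz * nc);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int ch = 0; ch < nc; ++ch) {
    const double* xc = xp + (size_t)ch * nx * ny * nz;
    double* oc = op + (size_t)ch * ox * oy * oz;
    for (int z = 0; z < oz; ++z) {
      const int z0 = mz.i0[z], z1 = mz.i1[z];
      const double wz = mz.w1[z];
      for (int y = 0; y < oy; ++y) {
        const int y0 = my.i0[y], y1 = my.i1[y];
        const double wy = my.w1[y];
        for (int xo = 0; xo < ox; ++xo) {
          const int x0 = mx.i0[xo], x1 = mx.i1[xo];
          const double wx = mx.w1[xo];
          const double v =
            (1 - wz) * ((1 - wy) * ((1 - wx) * xc[(size_t)(z0 * ny + y0) * nx + x0] +
                                    wx * xc[(size_t)(z0 * ny + y0) * nx + x1]) +
                        wy * ((1 - wx) * xc[(size_t)(z0 * ny + y1) * nx + x0] +
                              wx * xc[(size_t)(z0 * ny + y1) * nx + x1])) +
            wz * ((1 - wy) * ((1 - wx) * xc[(size_t)(z1 * ny + y0) * nx + x0] +
                              wx * xc[(size_t)(z1 * ny + y0) * nx + x1]) +
                  wy * ((1 - wx) * xc[(size_t)(z1 * ny + y1) * nx + x0] +
                        wx * xc[(size_t)(z1 * ny + y1) * nx + x1]));
          oc[((size_t)z * oy + y) * ox + xo] = v;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bw_cpp(NumericVector dy, IntegerVector in_dim) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], nc = in_dim[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  AxisMap mx = axis_map(nx), my = axis_map(ny), mz = axis_map(nz);
  NumericVector dx((size_t)nx * ny * nz * nc);
  const double* dp = dy.begin();
  double* xp = dx.begin();
  for (int ch = 0; ch < nc; ++ch) {
    double* xc = xp + (size_t)ch * nx * ny * nz;
    const double* oc = dp + (size_t)ch * ox * oy * oz;
    for (int z = 0; z < oz; ++z) {
      const int z0 = mz.i0[z], z1 = mz.i1[z];
      const double wz = mz.w1[z];
      for (int y = 0; y < oy; ++y) {
        const int y0 = my.i0[y], y1 = my.i1[y];
        const double wy = my.w1[y];
        for (int xo = 0; xo < ox; ++xo) {
          const int x0 = mx.i0[xo], x1 = mx.i1[xo];
          const double wx = mx.w1[xo];
          const double g = oc[((size_t)z * oy + y) * ox + xo];
          xc[(size_t)(z0 * ny + y0) * nx + x0] += g * (1 - wz) * (1 - wy) * (1 - wx);
          xc[(size_t)(z0 * ny + y0) * nx + x1] += g * (1 - wz) * (1 - wy) * wx;
          xc[(size_t)(z0 * ny + y1) * nx + x0] += g * (1 - wz) * wy * (1 - wx);
          xc[(size_t)(z0 * ny + y1) * nx + x1] += g * (1 - wz) * wy * wx;
          xc[(size_t)(z1 * ny + y0) * nx + x0] += g * wz * (1 - wy) * (1 - wx);
          xc[(size_t)(z1 * ny + y0) * nx + x1] += g * wz * (1 - wy) * wx;
          xc[(size_t)(z1 * ny + y1) * nx + x0] += g * wz * wy * (1 - wx);
          xc[(size_t)(z1 * ny + y1) * nx + x1] += g * wz * wy * wx;
        }
      }
    }
  }
  dx.attr("dim") = in_dim;
  return dx;
}

// Eigen-decomposition of per-voxel symmetric diffusion tensors.
// tens: nvox x 6 (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz). Returns eigenvalues in
// descending order and the principal eigenvector with sign convention
// first-nonzero-component >= 0. All-zero tensors give zero output.
// [[Rcpp::export]]
List tensor_eig_cpp(NumericMatrix tens) {
  const int n = tens.nrow();
  NumericMatrix evals(n, 3), evec1(n, 3);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (int i = 0; i < n; ++i) {
    const double xx = tens(i, 0), yy = tens(i, 1), zz = tens(i, 2);
    const double xy = tens(i, 3), xz = tens(i, 4), yz = tens(i, 5);
    if (xx == 0 && yy == 0 && zz == 0 && xy == 0 && xz == 0 && yz == 0) continue;
    D(0, 0) = xx; D(1, 1) = yy; D(2, 2) = zz;
    D(0, 1) = D(1, 0) = xy;
    D(0, 2) = D(2, 0) = xz;
    D(1, 2) = D(2, 1) = yz;
    arma::eig_sym(ev, V, D);  // ascending
    evals(i, 0) = ev(2); evals(i, 1) = ev(1); evals(i, 2) = ev(0);
    arma::vec3 v = V.col(2);
    for (int j = 0; j < 3; ++j) {
      if (std::abs(v(j)) > 1e-12) {
        if (v(j) < 0) v = -v;
        break;
      }
    }
    evec1(i, 0) = v(0); evec1(i, 1) = v(1); evec1(i, 2) = v(2);
  }
  return List::create(_["evals"] = evals, _["evec1"] = evec1);
}
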