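// Low-level numerical kernels for the segmentation network.
//
// Tensors are passed as arma::cube in (row = y, col = x, slice = channel)
// layout, matching R arrays of dim c(H, W, C).  Convolution weights arrive
// as a (k*k*Cin) x Cout matrix whose row order is the R flattening of an
// array of dim c(k, k, Cin): kernel-row fastest, then kernel-col, then
// input channel.  All kernels are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat col(static_cast<size_t>(Hout) * Wout,
                static_cast<size_t>(k) * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colidx = c * k * k + kj * k + ki;
        for (int j = 0; j < Wout; ++j) {
          const int xj = j * stride - pad + kj;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int xi = i * stride - pad + ki;
            if (xi < 0 || xi >= H) continue;
            col(i + static_cast<size_t>(Hout) * j, colidx) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".nn_conv2d_fwd")]]
arma::cube nn_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.n_cols;
  arma::mat col = im2col(x, k, stride, pad, Hout, Wout);
  arma::mat y = col * w;
  y.each_row() += b.t();
  arma::cube out(Hout, Wout, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), Hout, Wout);
  return out;
}

// [[Rcpp::export(name = ".nn_conv2d_bwd")]]
List nn_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dy, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = dy.n_rows, Wout = dy.n_cols, Cout = dy.n_slices;
  arma::mat col = im2col(x, k, stride, pad, Hout, Wout);
  arma::mat dymat(static_cast<size_t>(Hout) * Wout, Cout);
  for (int c = 0; c < Cout; ++c)
    dymat.col(c) = arma::vectorise(dy.slice(c));
  arma::mat dw = col.t() * dymat;
  arma::vec db = arma::sum(dymat, 0).t();
  arma::mat dcol = dymat * w.t();
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int colidx = c * k * k + kj * k + ki;
        for (int j = 0; j < Wout; ++j) {
          const int xj = j * stride - pad + kj;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int xi = i * stride - pad + ki;
            if (xi < 0 || xi >= H) continue;
            dx(xi, xj, c) += dcol(i + static_cast<size_t>(Hout) * j, colidx);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Nearest-neighbour 2x upsampling (FPN top-down pathway, mask head).
// [[Rcpp::export(name = ".nn_upsample2_fwd")]]
arma::cube nn_upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".nn_upsample2_bwd")]]
arma::cube nn_upsample2_bwd(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Bilinear sample of channel c at continuous (x, y); pixel (r, cc) has its
// center at (cc + 0.5, r + 0.5).  Coordinates are clamped to the border.
static inline double bilin(const arma::cube& f, double x, double y, int c,
                           double* wts = nullptr, int* idx = nullptr) {
  const int H = f.n_rows, W = f.n_cols;
  double u = x - 0.5, v = y - 0.5;
  if (u < 0) u = 0;
  if (v < 0) v = 0;
  if (u > W - 1) u = W - 1;
  if (v > H - 1) v = H - 1;
  const int j0 = std::min(static_cast<int>(std::floor(u)), W - 2 >= 0 ? W - 2 : 0);
  const int i0 = std::min(static_cast<int>(std::floor(v)), H - 2 >= 0 ? H - 2 : 0);
  const int j1 = std::min(j0 + 1, W - 1);
  const int i1 = std::min(i0 + 1, H - 1);
  const double a = u - j0, b = v - i0;
  const double w00 = (1 - a) * (1 - b), w01 = a * (1 - b);
  const double w10 = (1 - a) * b, w11 = a * b;
  if (wts) {
    wts[0] = w00; wts[1] = w01; wts[2] = w10; wts[3] = w11;
    idx[0] = i0; idx[1] = j0; idx[2] = i1; idx[3] = j1;
  }
  return w00 * f(i0, j0, c) + w01 * f(i0, j1, c) +
         w10 * f(i1, j0, c) + w11 * f(i1, j1, c);
}

// RoIAlign: average `sampling`^2 bilinear samples per output bin.  The box
// (x0, y0, w, h) is in continuous feature-map coordinates.
// [[Rcpp::export(name = ".nn_roi_align_fwd")]]
arma::cube nn_roi_align_fwd(const arma::cube& feat, double x0, double y0,
                            double w, double h, int out, int sampling) {
  const int C = feat.n_slices;
  arma::cube y(out, out, C, arma::fill::zeros);
  const double bw = w / out, bh = h / out;
  const double norm = 1.0 / (sampling * sampling);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < out; ++j)
      for (int i = 0; i < out; ++i) {
        double acc = 0;
        for (int a = 0; a < sampling; ++a)
          for (int b = 0; b < sampling; ++b) {
            const double sx = x0 + (j + (a + 0.5) / sampling) * bw;
            const double sy = y0 + (i + (b + 0.5) / sampling) * bh;
            acc += bilin(feat, sx, sy, c);
          }
        y(i, j, c) = acc * norm;
      }
  return y;
}

// Gradient of RoIAlign w.r.t. the feature map (scatter of bilinear weights).
// [[Rcpp::export(name = ".nn_roi_align_bwd")]]
arma::cube nn_roi_align_bwd(int H, int W, int C, double x0, double y0,
                            double w, double h, int out, int sampling,
                            const arma::cube& dy) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::cube probe(H, W, 1, arma::fill::zeros);  // only for bilin() geometry
  const double bw = w / out, bh = h / out;
  const double norm = 1.0 / (sampling * sampling);
  double wts[4];
  int idx[4];
  for (int j = 0; j < out; ++j)
    for (int i = 0; i < out; ++i) {
      for (int a = 0; a < sampling; ++a)
        for (int b = 0; b < sampling; ++b) {
          const double sx = x0 + (j + (a + 0.5) / sampling) * bw;
          const double sy = y0 + (i + (b + 0.5) / sampling) * bh;
          bilin(probe, sx, sy, 0, wts, idx);
          for (int c = 0; c < C; ++c) {
            const double g = dy(i, j, c) * norm;
            dx(idx[0], idx[1], c) += wts[0] * g;
            dx(idx[0], idx[3], c) += wts[1] * g;
            dx(idx[2], idx[1], c) += wts[2] * g;
            dx(idx[2], idx[3], c) += wts[3] * g;
          }
        }
    }
  return dx;
}

// Plain bilinear resize (inference-time mask upsampling; no gradient).
// [[Rcpp::export(name = ".nn_bilinear_resize")]]
arma::cube nn_bilinear_resize(const arma::cube& x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(oh, ow, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double sx = (j + 0.5) * (static_cast<double>(W) / ow);
        const double sy = (i + 0.5) * (static_cast<double>(H) / oh);
        y(i, j, c) = bilin(x, sx, sy, c);
      }
  return y;
}
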