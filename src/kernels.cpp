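// Numerical kernels for the 3D convolutional encoder and volume geometry.
//
// Activation layout: a batch is an arma::cube of shape (V, C, N) where
// V = H*W*D voxels in column-major order (h fastest, then w, then d),
// C channels, N samples. Convolutions are kernel 3, stride 1, padding 1,
// realised as im2col followed by a BLAS matrix product; weights are
// (C_out x 27*C_in) with the 27 kernel offsets fastest (dh fastest, then
// dw, then dd), matching the im2col row order.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword vox(int h, int w, int d, int H, int W) {
  return (arma::uword)h + (arma::uword)H * ((arma::uword)w + (arma::uword)W * (arma::uword)d);
}

// col matrix: (27*Cin) x V for one sample, zero padding outside the grid
static void im2col3(const arma::mat &x, int H, int W, int D, arma::mat &col) {
  const int Cin = (int)x.n_cols;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double *xc = x.colptr(c);
    int r0 = 27 * c;
    for (int dd = -1; dd <= 1; ++dd) {
      for (int dw = -1; dw <= 1; ++dw) {
        for (int dh = -1; dh <= 1; ++dh) {
          int r = r0 + (dh + 1) + 3 * ((dw + 1) + 3 * (dd + 1));
          for (int d = 0; d < D; ++d) {
            int sd = d + dd;
            if (sd < 0 || sd >= D) continue;
            for (int w = 0; w < W; ++w) {
              int sw = w + dw;
              if (sw < 0 || sw >= W) continue;
              for (int h = 0; h < H; ++h) {
                int sh = h + dh;
                if (sh < 0 || sh >= H) continue;
                col.at(r, vox(h, w, d, H, W)) = xc[vox(sh, sw, sd, H, W)];
              }
            }
          }
        }
      }
    }
  }
}

// scatter-add of a col-shaped gradient back onto the voxel grid
static void col2im3(const arma::mat &col, int H, int W, int D, arma::mat &dx) {
  const int Cin = (int)dx.n_cols;
  for (int c = 0; c < Cin; ++c) {
    double *xc = dx.colptr(c);
    int r0 = 27 * c;
    for (int dd = -1; dd <= 1; ++dd) {
      for (int dw = -1; dw <= 1; ++dw) {
        for (int dh = -1; dh <= 1; ++dh) {
          int r = r0 + (dh + 1) + 3 * ((dw + 1) + 3 * (dd + 1));
          for (int d = 0; d < D; ++d) {
            int sd = d + dd;
            if (sd < 0 || sd >= D) continue;
            for (int w = 0; w < W; ++w) {
              int sw = w + dw;
              if (sw < 0 || sw >= W) continue;
              for (int h = 0; h < H; ++h) {
                int sh = h + dh;
                if (sh < 0 || sh >= H) continue;
                xc[vox(sh, sw, sd, H, W)] += col.at(r, vox(h, w, d, H, W));
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv3d_forward(const arma::cube &x, int H, int W, int D,
                              const arma::mat &weight, const arma::vec &bias) {
  const arma::uword V = x.n_rows, N = x.n_slices;
  const arma::uword Cout = weight.n_rows;
  arma::cube out(V, Cout, N);
  arma::mat col(weight.n_cols, V);
  for (arma::uword n = 0; n < N; ++n) {
    im2col3(x.slice(n), H, W, D, col);
    arma::mat o = weight * col;          // Cout x V
    o.each_col() += bias;
    out.slice(n) = o.t();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(const arma::cube &x, const arma::cube &dout,
                         int H, int W, int D, const arma::mat &weight,
                         bool need_dx) {
  const arma::uword V = x.n_rows, N = x.n_slices, Cin = x.n_cols;
  arma::mat dW(weight.n_rows, weight.n_cols, arma::fill::zeros);
  arma::vec db(weight.n_rows, arma::fill::zeros);
  arma::cube dx;
  if (need_dx) dx.zeros(V, Cin, N);
  arma::mat col(weight.n_cols, V);
  for (arma::uword n = 0; n < N; ++n) {
    im2col3(x.slice(n), H, W, D, col);
    arma::mat g = dout.slice(n).t();     // Cout x V
    dW += g * col.t();
    db += arma::sum(g, 1);
    if (need_dx) {
      arma::mat dcol = weight.t() * g;   // 27*Cin x V
      arma::mat dxs(V, Cin, arma::fill::zeros);
      col2im3(dcol, H, W, D, dxs);
      dx.slice(n) = dxs;
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// 2x max-pool; dims must be even. Returns pooled cube and flat argmax
// indices (1-based into the input voxel dimension) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool3d(const arma::cube &x, int H, int W, int D) {
  const int H2 = H / 2, W2 = W / 2, D2 = D / 2;
  const arma::uword V2 = (arma::uword)H2 * W2 * D2;
  const arma::uword C = x.n_cols, N = x.n_slices;
  arma::cube out(V2, C, N);
  arma::cube amax(V2, C, N);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword c = 0; c < C; ++c) {
      const double *xc = x.slice(n).colptr(c);
      for (int d = 0; d < D2; ++d)
        for (int w = 0; w < W2; ++w)
          for (int h = 0; h < H2; ++h) {
            double best = -std::numeric_limits<double>::infinity();
            arma::uword bi = 0;
            for (int od = 0; od < 2; ++od)
              for (int ow = 0; ow < 2; ++ow)
                for (int oh = 0; oh < 2; ++oh) {
                  arma::uword i = vox(2 * h + oh, 2 * w + ow, 2 * d + od, H, W);
                  if (xc[i] > best) { best = xc[i]; bi = i; }
                }
            arma::uword j = vox(h, w, d, H2, W2);
            out.at(j, c, n) = best;
            amax.at(j, c, n) = bi + 1;
          }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool3d_backward(const arma::cube &dout, const arma::cube &amax,
                                  int V, int C, int N) {
  arma::cube dx(V, C, N, arma::fill::zeros);
  for (arma::uword n = 0; n < (arma::uword)N; ++n)
    for (arma::uword c = 0; c < (arma::uword)C; ++c)
      for (arma::uword j = 0; j < dout.n_rows; ++j)
        dx.at((arma::uword)amax.at(j, c, n) - 1, c, n) += dout.at(j, c, n);
  return dx;
}

static inline double sample_trilinear(const double *x, int H, int W, int D,
                                      double sh, double sw, double sd,
                                      bool zero_outside) {
  if (zero_outside) {
    if (sh < -1.0 || sh > (double)H || sw < -1.0 || sw > (double)W ||
        sd < -1.0 || sd > (double)D)
      return 0.0;
  }
  // clamp to the valid sample range so border voxels extend outward
  auto clampc = [](double v, double hi) {
    return v < 0.0 ? 0.0 : (v > hi ? hi : v);
  };
  if (!zero_outside) {
    sh = clampc(sh, H - 1.0); sw = clampc(sw, W - 1.0); sd = clampc(sd, D - 1.0);
  }
  int h0 = (int)std::floor(sh), w0 = (int)std::floor(sw), d0 = (int)std::floor(sd);
  double fh = sh - h0, fw = sw - w0, fd = sd - d0;
  double acc = 0.0;
  for (int od = 0; od < 2; ++od)
    for (int ow = 0; ow < 2; ++ow)
      for (int oh = 0; oh < 2; ++oh) {
        int hh = h0 + oh, ww = w0 + ow, dd = d0 + od;
        double wgt = (oh ? fh : 1.0 - fh) * (ow ? fw : 1.0 - fw) * (od ? fd : 1.0 - fd);
        if (wgt == 0.0) continue;
        double val = 0.0;
        if (hh >= 0 && hh < H && ww >= 0 && ww < W && dd >= 0 && dd < D)
          val = x[vox(hh, ww, dd, H, W)];
        else if (!zero_outside) {
          int hc = std::min(std::max(hh, 0), H - 1);
          int wc = std::min(std::max(ww, 0), W - 1);
          int dc = std::min(std::max(dd, 0), D - 1);
          val = x[vox(hc, wc, dc, H, W)];
        }
        acc += wgt * val;
      }
  return acc;
}

// voxel-center-aligned trilinear resampling of a single scalar volume
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(const NumericVector &x, IntegerVector src,
                                     IntegerVector tgt) {
  int H = src[0], W = src[1], D = src[2];
  int H2 = tgt[0], W2 = tgt[1], D2 = tgt[2];
  double rh = (double)H / H2, rw = (double)W / W2, rd = (double)D / D2;
  NumericVector out((R_xlen_t)H2 * W2 * D2);
  const double *xp = x.begin();
  for (int d = 0; d < D2; ++d) {
    double sd = (d + 0.5) * rd - 0.5;
    for (int w = 0; w < W2; ++w) {
      double sw = (w + 0.5) * rw - 0.5;
      for (int h = 0; h < H2; ++h) {
        double sh = (h + 0.5) * rh - 0.5;
        out[vox(h, w, d, H2, W2)] = sample_trilinear(xp, H, W, D, sh, sw, sd, false);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, D2);
  return out;
}

// rotation by `angle` radians about principal axis (1=h, 2=w, 3=d) through
// the volume centre; voxels sampled from outside the source grid become 0
// [[Rcpp::export]]
NumericVector cpp_rotate_trilinear(const NumericVector &x, IntegerVector dims,
                                   int axis, double angle) {
  int H = dims[0], W = dims[1], D = dims[2];
  double ch = (H - 1) / 2.0, cw = (W - 1) / 2.0, cd = (D - 1) / 2.0;
  double ca = std::cos(angle), sa = std::sin(angle);
  NumericVector out((R_xlen_t)H * W * D);
  const double *xp = x.begin();
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double u = h - ch, v = w - cw, t = d - cd;
        double su, sv, st; // inverse rotation of target coords
        if (axis == 1)      { su = u; sv = ca * v + sa * t; st = -sa * v + ca * t; }
        else if (axis == 2) { sv = v; su = ca * u - sa * t; st = sa * u + ca * t; }
        else                { st = t; su = ca * u + sa * v; sv = -sa * u + ca * v; }
        out[vox(h, w, d, H, W)] =
          sample_trilinear(xp, H, W, D, su + ch, sv + cw, st + cd, true);
      }
  out.attr("dim") = IntegerVector::create(H, W, D);
  return out;
}

// per-channel batch mean and biased variance over (V, N)
// [[Rcpp::export]]
List cpp_channel_moments(const arma::cube &x) {
  const arma::uword V = x.n_rows, C = x.n_cols, N = x.n_slices;
  arma::vec mu(C, arma::fill::zeros), vr(C, arma::fill::zeros);
  const double M = (double)V * N;
  for (arma::uword c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (arma::uword n = 0; n < N; ++n) {
      const double *p = x.slice(n).colptr(c);
      for (arma::uword v = 0; v < V; ++v) { s += p[v]; s2 += p[v] * p[v]; }
    }
    mu[c] = s / M;
    vr[c] = s2 / M - mu[c] * mu[c];
    if (vr[c] < 0) vr[c] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = vr);
}

// fused batch-norm + rectifier forward
// [[Rcpp::export]]
List cpp_bn_relu_forward(const arma::cube &x, const arma::vec &mu,
                         const arma::vec &vr, const arma::vec &gamma,
                         const arma::vec &beta, double eps) {
  const arma::uword V = x.n_rows, C = x.n_cols, N = x.n_slices;
  arma::cube xhat(V, C, N), act(V, C, N);
  for (arma::uword c = 0; c < C; ++c) {
    double istd = 1.0 / std::sqrt(vr[c] + eps);
    for (arma::uword n = 0; n < N; ++n) {
      const double *p = x.slice(n).colptr(c);
      double *xh = xhat.slice(n).colptr(c);
      double *a = act.slice(n).colptr(c);
      for (arma::uword v = 0; v < V; ++v) {
        xh[v] = (p[v] - mu[c]) * istd;
        double y = gamma[c] * xh[v] + beta[c];
        a[v] = y > 0 ? y : 0.0;
      }
    }
  }
  return List::create(_["xhat"] = xhat, _["act"] = act);
}

// fused rectifier + batch-norm backward; `batch_stats` selects the
// training-mode formula (mean/variance depend on the batch) versus the
// inference-mode one (running statistics are constants)
// [[Rcpp::export]]
List cpp_bn_relu_backward(const arma::cube &dact, const arma::cube &act,
                          const arma::cube &xhat, const arma::vec &vr,
                          const arma::vec &gamma, double eps,
                          bool batch_stats) {
  const arma::uword V = dact.n_rows, C = dact.n_cols, N = dact.n_slices;
  arma::cube dx(V, C, N);
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  const double M = (double)V * N;
  for (arma::uword c = 0; c < C; ++c) {
    double sum_dy = 0, sum_dyxh = 0;
    for (arma::uword n = 0; n < N; ++n) {
      const double *da = dact.slice(n).colptr(c);
      const double *a = act.slice(n).colptr(c);
      const double *xh = xhat.slice(n).colptr(c);
      for (arma::uword v = 0; v < V; ++v) {
        double dy = a[v] > 0 ? da[v] : 0.0;
        sum_dy += dy;
        sum_dyxh += dy * xh[v];
      }
    }
    dgamma[c] = sum_dyxh;
    dbeta[c] = sum_dy;
    double istd = 1.0 / std::sqrt(vr[c] + eps);
    double m_dy = sum_dy / M, m_dyxh = sum_dyxh / M;
    for (arma::uword n = 0; n < N; ++n) {
      const double *da = dact.slice(n).colptr(c);
      const double *a = act.slice(n).colptr(c);
      const double *xh = xhat.slice(n).colptr(c);
      double *d = dx.slice(n).colptr(c);
      for (arma::uword v = 0; v < V; ++v) {
        double dy = a[v] > 0 ? da[v] : 0.0;
        d[v] = batch_stats
          ? gamma[c] * istd * (dy - m_dy - xh[v] * m_dyxh)
          : gamma[c] * istd * dy;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
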