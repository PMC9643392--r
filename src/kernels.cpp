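#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as C x (H*W*B) matrices, column-major positions
// p = x*H + y within each batch item, columns ordered batch-major:
// column j = b*H*W + x*H + y.  All convolutions are stride-1, zero-padded
// to "same" size with odd kernel k.

// [[Rcpp::export(name = ".nn_im2col")]]
NumericMatrix nn_im2col(const NumericMatrix& X, int H, int W, int B, int k) {
  const int C = X.nrow();
  const int HW = H * W;
  const int pad = (k - 1) / 2;
  const int K = k * k * C;
  NumericMatrix out(K, HW * B);
  for (int b = 0; b < B; ++b) {
    const int base = b * HW;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const int j = base + x * H + y;
        double* col = &out(0, j);
        for (int dx = -pad; dx <= pad; ++dx) {
          const int xx = x + dx;
          const bool xok = xx >= 0 && xx < W;
          for (int dy = -pad; dy <= pad; ++dy) {
            const int yy = y + dy;
            const int r = ((dx + pad) * k + (dy + pad)) * C;
            if (xok && yy >= 0 && yy < H) {
              const double* src = &X(0, base + xx * H + yy);
              for (int c = 0; c < C; ++c) col[r + c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) col[r + c] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_col2im")]]
NumericMatrix nn_col2im(const NumericMatrix& cols, int C, int H, int W,
                        int B, int k) {
  const int HW = H * W;
  const int pad = (k - 1) / 2;
  NumericMatrix out(C, HW * B);
  for (int b = 0; b < B; ++b) {
    const int base = b * HW;
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const int j = base + x * H + y;
        const double* col = &cols(0, j);
        for (int dx = -pad; dx <= pad; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= W) continue;
          for (int dy = -pad; dy <= pad; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= H) continue;
            const int r = ((dx + pad) * k + (dy + pad)) * C;
            double* dst = &out(0, base + xx * H + yy);
            for (int c = 0; c < C; ++c) dst[c] += col[r + c];
          }
        }
      }
    }
  }
  return out;
}

// f x f average pooling (f divides H and W).
// [[Rcpp::export(name = ".nn_pool_fwd")]]
NumericMatrix nn_pool_fwd(const NumericMatrix& X, int H, int W, int B, int f) {
  const int C = X.nrow();
  const int Ho = H / f, Wo = W / f;
  const int HW = H * W, HWo = Ho * Wo;
  const double inv = 1.0 / (f * f);
  NumericMatrix out(C, HWo * B);
  for (int b = 0; b < B; ++b) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        double* dst = &out(0, b * HWo + xo * Ho + yo);
        for (int dx = 0; dx < f; ++dx) {
          for (int dy = 0; dy < f; ++dy) {
            const double* src =
              &X(0, b * HW + (xo * f + dx) * H + (yo * f + dy));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
        for (int c = 0; c < C; ++c) dst[c] *= inv;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".nn_pool_bwd")]]
NumericMatrix nn_pool_bwd(const NumericMatrix& dY, int H, int W, int B,
                          int f) {
  const int C = dY.nrow();
  const int Ho = H / f, Wo = W / f;
  const int HW = H * W, HWo = Ho * Wo;
  const double inv = 1.0 / (f * f);
  NumericMatrix out(C, HW * B);
  for (int b = 0; b < B; ++b) {
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) {
        const double* src = &dY(0, b * HWo + (x / f) * Ho + (y / f));
        double* dst = &out(0, b * HW + x * H + y);
        for (int c = 0; c < C; ++c) dst[c] = src[c] * inv;
      }
    }
  }
  return out;
}

// Grayscale square max filter, window (2r+1)^2, edge-clamped.
// [[Rcpp::export(name = ".max_filter")]]
NumericMatrix max_filter(const NumericMatrix& img, int r) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix tmp(H, W), out(H, W);
  for (int x = 0; x < W; ++x) {          // vertical pass
    for (int y = 0; y < H; ++y) {
      double m = R_NegInf;
      const int lo = std::max(0, y - r), hi = std::min(H - 1, y + r);
      for (int yy = lo; yy <= hi; ++yy) m = std::max(m, img(yy, x));
      tmp(y, x) = m;
    }
  }
  for (int y = 0; y < H; ++y) {          // horizontal pass
    for (int x = 0; x < W; ++x) {
      double m = R_NegInf;
      const int lo = std::max(0, x - r), hi = std::min(W - 1, x + r);
      for (int xx = lo; xx <= hi; ++xx) m = std::max(m, tmp(y, xx));
      out(y, x) = m;
    }
  }
  return out;
}

// Accumulate truncated Gaussian kernels centred at detections onto a
// stride-sampled grid.  xs/ys are 0-based pixel coordinates; grid node
// (i, j) (0-based row i, col j) sits at pixel (x = j*stride, y = i*stride).
// [[Rcpp::export(name = ".density_accumulate")]]
NumericMatrix density_accumulate(const NumericVector& xs,
                                 const NumericVector& ys,
                                 int H, int W, double sigma, int stride) {
  const int nr = (H + stride - 1) / stride;
  const int nc = (W + stride - 1) / stride;
  NumericMatrix out(nr, nc);
  const double trunc = 4.0 * sigma;
  const double norm = 1.0 / (2.0 * M_PI * sigma * sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int d = 0; d < xs.size(); ++d) {
    const double cx = xs[d], cy = ys[d];
    const int j0 = std::max(0, (int)std::ceil((cx - trunc) / stride));
    const int j1 = std::min(nc - 1, (int)std::floor((cx + trunc) / stride));
    const int i0 = std::max(0, (int)std::ceil((cy - trunc) / stride));
    const int i1 = std::min(nr - 1, (int)std::floor((cy + trunc) / stride));
    for (int j = j0; j <= j1; ++j) {
      const double dx = j * (double)stride - cx;
      for (int i = i0; i <= i1; ++i) {
        const double dy = i * (double)stride - cy;
        const double r2 = dx * dx + dy * dy;
        if (r2 <= trunc * trunc)
          out(i, j) += norm * std::exp(-r2 * inv2s2);
      }
    }
  }
  return out;
}

// Additive rendering of shaded elliptical nuclei into an optical-density
// matrix (H x W).  Each nucleus adds baseOD inside its ellipse, modulated
// by a smooth chromatin texture (random cosine waves) of amplitude
// `contrast`, with a soft edge over ~1 px.  tex holds 6 numbers per
// nucleus: (a1, fx1, fy1, a2, fx2, fy2) wave parameters.
// [[Rcpp::export(name = ".render_nuclei_od")]]
NumericMatrix render_nuclei_od(NumericMatrix od,
                               const NumericVector& xs,
                               const NumericVector& ys,
                               const NumericVector& majors,
                               const NumericVector& minors,
                               const NumericVector& thetas,
                               const NumericVector& contrasts,
                               const NumericVector& baseODs,
                               const NumericMatrix& tex) {
  const int H = od.nrow(), W = od.ncol();
  for (int n = 0; n < xs.size(); ++n) {
    const double cx = xs[n], cy = ys[n];
    const double a = majors[n], b = minors[n];
    const double ct = std::cos(thetas[n]), st = std::sin(thetas[n]);
    const double ext = a + 1.5;
    const int x0 = std::max(0, (int)std::floor(cx - ext));
    const int x1 = std::min(W - 1, (int)std::ceil(cx + ext));
    const int y0 = std::max(0, (int)std::floor(cy - ext));
    const int y1 = std::min(H - 1, (int)std::ceil(cy + ext));
    const double amp = contrasts[n], base = baseODs[n];
    const double a1 = tex(0, n), fx1 = tex(1, n), fy1 = tex(2, n);
    const double a2 = tex(3, n), fx2 = tex(4, n), fy2 = tex(5, n);
    for (int x = x0; x <= x1; ++x) {
      for (int y = y0; y <= y1; ++y) {
        const double dx = x - cx, dy = y - cy;
        const double u = (dx * ct + dy * st) / a;
        const double v = (-dx * st + dy * ct) / b;
        const double r = std::sqrt(u * u + v * v);
        if (r > 1.0 + 1.5 / b) continue;
        // soft edge: full OD inside r<=1-w, linear ramp outside
        const double w = 1.0 / b;
        double cov = 1.0;
        if (r > 1.0 - w) cov = std::max(0.0, (1.0 + w - r) / (2.0 * w));
        if (cov <= 0.0) continue;
        const double txt = a1 * std::cos(fx1 * dx + fy1 * dy) +
                           a2 * std::cos(fx2 * dx + fy2 * dy);
        double val = base * (1.0 + amp * txt);
        if (val < 0.0) val = 0.0;
        od(y, x) += cov * val;
      }
    }
  }
  return od;
}
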