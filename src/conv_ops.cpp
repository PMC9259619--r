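// Minimal CNN primitives for the residual U-net: same-padding 3x3 / 1x1
// convolution via cache-blocked im2col + GEMM, 2x2 max-pooling and 2x
// nearest-neighbour upsampling, each with its adjoint for backpropagation.
// Arrays use the R layout (H, W, C, N) column-major. im2col works on blocks
// of image columns so the patch buffer stays cache-resident and no
// per-call allocation exceeds a few MB (persistent workspaces).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4D array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static arma::mat wrap_ws(std::vector<double> &buf, arma::uword nr,
                         arma::uword nc) {
  if (buf.size() < (size_t)nr * nc) buf.resize((size_t)nr * nc);
  return arma::mat(buf.data(), nr, nc, false, true);
}

// Fill the patch buffer for image columns [w0, w1) of sample n:
// cols(j, r) = x[h + ki - ph, w + kj - pw, c, n] (zero outside the slice),
// j = h + H*(w - w0), r = ki + kh*kj + kh*kw*c.
static void im2col_block(const double *xn, int H, int W, int C,
                         int kh, int kw, int w0, int w1, arma::mat &cols) {
  const int ph = kh / 2, pw = kw / 2;
  const long HW = (long)H * W;
  const int nb = w1 - w0;
  for (int c = 0; c < C; ++c) {
    const double *xc = xn + (long)c * HW;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * kj + kh * kw * c;
        double *col = cols.colptr(r);
        for (int wb = 0; wb < nb; ++wb) {
          const int sw = w0 + wb + kj - pw;
          double *dst = col + (long)wb * H;
          if (sw < 0 || sw >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const int h0 = std::max(0, ph - ki);
          const int h1 = std::min(H, H + ph - ki);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0);
          std::copy(xc + (long)sw * H + (h0 + ki - ph),
                    xc + (long)sw * H + (h1 + ki - ph), dst + h0);
          if (h1 < H) std::fill(dst + h1, dst + H, 0.0);
        }
      }
  }
}

// Adjoint: scatter-add the patch-buffer gradient for columns [w0, w1) of
// sample n back into the input gradient (accumulated across blocks).
static void col2im_block(const arma::mat &cols, int H, int W, int C,
                         int kh, int kw, int w0, int w1, double *dxn) {
  const int ph = kh / 2, pw = kw / 2;
  const long HW = (long)H * W;
  const int nb = w1 - w0;
  for (int c = 0; c < C; ++c) {
    double *xc = dxn + (long)c * HW;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * kj + kh * kw * c;
        const double *col = cols.colptr(r);
        for (int wb = 0; wb < nb; ++wb) {
          const int sw = w0 + wb + kj - pw;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, ph - ki);
          const int h1 = std::min(H, H + ph - ki);
          double *dst = xc + (long)sw * H + (h0 + ki - ph);
          const double *src = col + (long)wb * H + h0;
          for (int h = h0; h < h1; ++h) *dst++ += *src++;
        }
      }
  }
}

static int block_cols(int H, int W) {
  int wb = std::max(1, 4096 / H); // ~4k rows per GEMM block
  return std::min(wb, W);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix w,
                             NumericVector b, int kh, int kw, bool relu) {
  static thread_local std::vector<double> ws_cols, ws_y;
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = kh * kw * C, Cout = w.ncol();
  if (w.nrow() != K) stop("weight rows must equal kh*kw*Cin");
  const long HW = (long)H * W;
  arma::mat wm(w.begin(), K, Cout, false);
  NumericVector out((long)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double *po = out.begin();
  const int wb = block_cols(H, W);
  arma::mat cols = wrap_ws(ws_cols, (arma::uword)H * wb, K);
  arma::mat y = wrap_ws(ws_y, (arma::uword)H * wb, Cout);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (long)n * HW * C;
    double *on = po + (long)n * HW * Cout;
    for (int w0 = 0; w0 < W; w0 += wb) {
      const int w1 = std::min(W, w0 + wb);
      const long rows = (long)H * (w1 - w0);
      if (kh == 1 && kw == 1) {
        // patches are just pixels: gemm directly on strided channel views
        arma::mat xv((double *)xn, HW, C, false);
        y.head_rows(rows) =
          xv.rows((long)w0 * H, (long)w0 * H + rows - 1) * wm;
      } else {
        im2col_block(xn, H, W, C, kh, kw, w0, w1, cols);
        y.head_rows(rows) = cols.head_rows(rows) * wm;
      }
      for (int c = 0; c < Cout; ++c) {
        const double bias = b[c];
        const double *s = y.colptr(c);
        double *dst = on + (long)c * HW + (long)w0 * H;
        if (relu)
          for (long j = 0; j < rows; ++j) {
            double v = s[j] + bias;
            dst[j] = v > 0 ? v : 0;
          }
        else
          for (long j = 0; j < rows; ++j) dst[j] = s[j] + bias;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                    NumericVector y, int kh, int kw, bool relu) {
  static thread_local std::vector<double> ws_cols, ws_dz, ws_dcols;
  int d[4], dd[4];
  get_dims4(x, d);
  get_dims4(dy, dd);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = dd[2];
  const int K = kh * kw * C;
  const long HW = (long)H * W;
  arma::mat wm(w.begin(), K, Cout, false);
  NumericMatrix dwR(K, Cout);
  arma::mat dw(dwR.begin(), K, Cout, false);
  NumericVector dbR(Cout);
  arma::vec db(dbR.begin(), Cout, false);
  NumericVector dxR((long)H * W * C * N);
  dxR.attr("dim") = IntegerVector::create(H, W, C, N);
  const int wb = block_cols(H, W);
  arma::mat cols = wrap_ws(ws_cols, (arma::uword)H * wb, K);
  arma::mat dz = wrap_ws(ws_dz, (arma::uword)H * wb, Cout);
  arma::mat dcols = wrap_ws(ws_dcols, (arma::uword)H * wb, K);
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (long)n * HW * C;
    const double *dyn = dy.begin() + (long)n * HW * Cout;
    const double *yn = y.begin() + (long)n * HW * Cout;
    double *dxn = dxR.begin() + (long)n * HW * C;
    for (int w0 = 0; w0 < W; w0 += wb) {
      const int w1 = std::min(W, w0 + wb);
      const long rows = (long)H * (w1 - w0);
      for (int c = 0; c < Cout; ++c) {
        const double *s = dyn + (long)c * HW + (long)w0 * H;
        const double *yy = yn + (long)c * HW + (long)w0 * H;
        double *dst = dz.colptr(c);
        if (relu)
          for (long j = 0; j < rows; ++j) dst[j] = yy[j] > 0 ? s[j] : 0.0;
        else
          std::copy(s, s + rows, dst);
      }
      db += arma::sum(dz.head_rows(rows), 0).t();
      if (kh == 1 && kw == 1) {
        arma::mat xv((double *)xn, HW, C, false);
        dw += xv.rows((long)w0 * H, (long)w0 * H + rows - 1).t() *
          dz.head_rows(rows);
        arma::mat dxv(dxn, HW, C, false);
        dxv.rows((long)w0 * H, (long)w0 * H + rows - 1) =
          dz.head_rows(rows) * wm.t();
      } else {
        im2col_block(xn, H, W, C, kh, kw, w0, w1, cols);
        dw += cols.head_rows(rows).t() * dz.head_rows(rows);
        dcols.head_rows(rows) = dz.head_rows(rows) * wm.t();
        col2im_block(dcols, H, W, C, kh, kw, w0, w1, dxn);
      }
    }
  }
  return List::create(_["dx"] = dxR, _["dw"] = dwR, _["db"] = dbR);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max-pooling needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size()); // 0-based flat index of the argmax in x
  const double *px = x.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double *base = px + cn * H * W;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        long i00 = (long)(2 * w) * H + 2 * h;
        long cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
        long best = cand[0];
        for (int k = 1; k < 4; ++k)
          if (base[cand[k]] > base[best]) best = cand[k];
        py[o] = base[best];
        pi[o] = (int)(cn * H * W + best);
        ++o;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              int H, int W) {
  int d[4];
  get_dims4(dy, d);
  NumericVector dx((long)H * W * d[2] * d[3]);
  dx.attr("dim") = IntegerVector::create(H, W, d[2], d[3]);
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  const int *pi = idx.begin();
  for (long j = 0; j < (long)dy.size(); ++j) pdx[pi[j]] += pdy[j];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1];
  NumericVector y((long)4 * x.size());
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, d[2], d[3]);
  const double *px = x.begin();
  double *py = y.begin();
  for (long cn = 0; cn < (long)d[2] * d[3]; ++cn) {
    const double *xs = px + cn * H * W;
    double *ys = py + cn * (long)4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xs[(long)w * H + h];
        long b = (long)(2 * w) * (2 * H) + 2 * h;
        ys[b] = v; ys[b + 1] = v;
        ys[b + 2 * H] = v; ys[b + 2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dy) {
  int d[4];
  get_dims4(dy, d);
  const int H = d[0] / 2, W = d[1] / 2;
  NumericVector dx((long)H * W * d[2] * d[3]);
  dx.attr("dim") = IntegerVector::create(H, W, d[2], d[3]);
  const double *py = dy.begin();
  double *px = dx.begin();
  for (long cn = 0; cn < (long)d[2] * d[3]; ++cn) {
    const double *ys = py + cn * (long)4 * H * W;
    double *xs = px + cn * (long)H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        long b = (long)(2 * w) * (2 * H) + 2 * h;
        xs[(long)w * H + h] =
          ys[b] + ys[b + 1] + ys[b + 2 * H] + ys[b + 2 * H + 1];
      }
  }
  return dx;
}
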