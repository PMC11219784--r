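#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: (H, W, N, C), column-major, matching the R
// engine. im2col produces the (H*W*N) x (k*k*C) patch matrix with channel
// fastest inside each kernel-offset block and dy before dx, the layout the
// R-side weightMatrix() assumes. Same padding, stride 1, odd k.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], N = d[2], C = d[3];
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix out(rows, (R_xlen_t)k * k * C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy) {
      for (int c = 0; c < C; ++c) {
        const R_xlen_t col = ((R_xlen_t)dx * k + dy) * C + c;
        double* o = op + col * rows;
        const double* xc = xp + (R_xlen_t)c * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (R_xlen_t)n * H * W;
          double* on = o + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx - p;
            double* ocol = on + (R_xlen_t)w * H;
            if (sw < 0 || sw >= W) {
              for (int h = 0; h < H; ++h) ocol[h] = 0.0;
              continue;
            }
            const double* xcol = xn + (R_xlen_t)sw * H;
            const int sh0 = dy - p;  // source row for output row 0
            // rows [lo, hi) read inside the column; the rest are padding
            const int lo = sh0 < 0 ? -sh0 : 0;
            const int hi = sh0 + H > H ? H - sh0 : H;
            for (int h = 0; h < lo; ++h) ocol[h] = 0.0;
            if (hi > lo)
              memcpy(ocol + lo, xcol + lo + sh0,
                     (size_t)(hi - lo) * sizeof(double));
            for (int h = hi; h < H; ++h) ocol[h] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dXcol, int k, int H, int W, int N,
                         int C) {
  const int p = (k - 1) / 2;
  const R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericVector dX((R_xlen_t)H * W * N * C);
  dX.attr("dim") = IntegerVector::create(H, W, N, C);
  const double* ip = dXcol.begin();
  double* xp = dX.begin();
  for (int dx = 0; dx < k; ++dx) {
    for (int dy = 0; dy < k; ++dy) {
      for (int c = 0; c < C; ++c) {
        const R_xlen_t col = ((R_xlen_t)dx * k + dy) * C + c;
        const double* i0 = ip + col * rows;
        double* xc = xp + (R_xlen_t)c * H * W * N;
        for (int n = 0; n < N; ++n) {
          const double* in = i0 + (R_xlen_t)n * H * W;
          double* xn = xc + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dx - p;
            if (sw < 0 || sw >= W) continue;
            const double* icol = in + (R_xlen_t)w * H;
            double* xcol = xn + (R_xlen_t)sw * H;
            const int sh0 = dy - p;
            for (int h = 0; h < H; ++h) {
              const int sh = h + sh0;
              if (sh >= 0 && sh < H) xcol[sh] += icol[h];
            }
          }
        }
      }
    }
  }
  return dX;
}
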