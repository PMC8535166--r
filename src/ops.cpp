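#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Tensors are R arrays with dim (N, H, W, C), column-major, so the linear
// index of (n, h, w, c) is n + N*(h + H*(w + W*c)) with 0-based indices.

// Unfold kh x kw patches into a (N*Ho*Wo) x (kh*kw*C) matrix.
// Column order: offset-major, channel-minor: col = (di*kw + dj)*C + c.
// Row order matches the column-major flattening of (N, Ho, Wo).
// [[Rcpp::export]]
NumericMatrix im2col_nhwc(NumericVector x, int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be a 4-d array (N, H, W, C)");
  const int N = d[0], H = d[1], W = d[2], C = d[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(N * Ho * Wo, kh * kw * C);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  for (int di = 0; di < kh; ++di) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int c = 0; c < C; ++c) {
        const R_xlen_t colidx = (R_xlen_t)((di * kw + dj) * C + c);
        double* dst = op + colidx * nrow;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + dj;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + di;
            double* drow = dst + (R_xlen_t)N * (ho + (R_xlen_t)Ho * wo);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int n = 0; n < N; ++n) drow[n] = 0.0;
            } else {
              const double* src = xp + (R_xlen_t)N * (h + (R_xlen_t)H * (w + (R_xlen_t)W * c));
              for (int n = 0; n < N; ++n) drow[n] = src[n];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_nhwc: scatter-add patch gradients back to the input.
// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix col, int N, int H, int W, int C,
                          int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (col.nrow() != (R_xlen_t)N * Ho * Wo || col.ncol() != kh * kw * C)
    stop("col has wrong shape");
  NumericVector x((R_xlen_t)N * H * W * C);
  x.attr("dim") = IntegerVector::create(N, H, W, C);
  double* xp = x.begin();
  const double* cp = col.begin();
  const R_xlen_t nrow = (R_xlen_t)N * Ho * Wo;
  for (int di = 0; di < kh; ++di) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int c = 0; c < C; ++c) {
        const R_xlen_t colidx = (R_xlen_t)((di * kw + dj) * C + c);
        const double* src0 = cp + colidx * nrow;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + dj;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + di;
            if (h < 0 || h >= H) continue;
            const double* src = src0 + (R_xlen_t)N * (ho + (R_xlen_t)Ho * wo);
            double* dst = xp + (R_xlen_t)N * (h + (R_xlen_t)H * (w + (R_xlen_t)W * c));
            for (int n = 0; n < N; ++n) dst[n] += src[n];
          }
        }
      }
    }
  }
  return x;
}

// Label connected components of a logical matrix by flood fill.
// connectivity is 4 or 8; labels are positive integers in raster order of
// the first-seen pixel, background stays 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int n_off = connectivity == 4 ? 4 : 8;
  const int off8[8][2] = {{-1,0},{1,0},{0,-1},{0,1},{-1,-1},{-1,1},{1,-1},{1,1}};
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < n_off; ++k) {
          const int ii = p.first + off8[k][0], jj = p.second + off8[k][1];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
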