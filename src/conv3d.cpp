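#include <Rcpp.h>
using namespace Rcpp;

// Grouped 3D convolution kernels.
//
// Layout conventions (R column-major):
//   feature map x : dim (D, H, W, C)        -- one contiguous block per channel
//   weights     w : dim (K1, K2, K3, Cg, Co) -- Cg = C_in / groups
// Output channel co belongs to group g = co / (Co / groups) and sees input
// channels [g*Cg, (g+1)*Cg). groups = 1 is a standard convolution, groups = C_in
// with Cg = 1 is depthwise, a 1x1x1 kernel with groups = gcd(C_in, C_out) is the
// pointwise grouped convolution of the separable block.

static inline int out_extent(int in, int k, int pad, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b, int stride, int pad, int groups) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int K1 = wdim[0], K2 = wdim[1], K3 = wdim[2], Cg = wdim[3], Co = wdim[4];
  if (C != Cg * groups) stop("input channels (%d) != per-group channels (%d) * groups (%d)", C, Cg, groups);
  if (Co % groups != 0) stop("output channels (%d) not divisible by groups (%d)", Co, groups);
  const int Do = out_extent(D, K1, pad, stride);
  const int Ho = out_extent(H, K2, pad, stride);
  const int Wo = out_extent(W, K3, pad, stride);
  if (Do <= 0) stop("non-positive output extent on depth axis");
  if (Ho <= 0) stop("non-positive output extent on height axis");
  if (Wo <= 0) stop("non-positive output extent on width axis");
  const int Cog = Co / groups;

  NumericVector out(static_cast<R_xlen_t>(Do) * Ho * Wo * Co);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();

  for (int co = 0; co < Co; ++co) {
    const int g = co / Cog;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int dd = 0; dd < Do; ++dd) {
          double acc = pb[co];
          const int d0 = dd * stride - pad;
          const int h0 = ho * stride - pad;
          const int w0 = wo * stride - pad;
          for (int cg = 0; cg < Cg; ++cg) {
            const int ci = g * Cg + cg;
            const double *xc = px + static_cast<R_xlen_t>(ci) * D * H * W;
            for (int k3 = 0; k3 < K3; ++k3) {
              const int wi = w0 + k3;
              if (wi < 0 || wi >= W) continue;
              for (int k2 = 0; k2 < K2; ++k2) {
                const int hi = h0 + k2;
                if (hi < 0 || hi >= H) continue;
                for (int k1 = 0; k1 < K1; ++k1) {
                  const int di = d0 + k1;
                  if (di < 0 || di >= D) continue;
                  const double xv = xc[di + D * (hi + static_cast<R_xlen_t>(H) * wi)];
                  const double wv = pw[k1 + K1 * (k2 + K2 * (k3 + K3 * (cg + static_cast<R_xlen_t>(Cg) * co)))];
                  acc += xv * wv;
                }
              }
            }
          }
          po[dd + Do * (ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * co))] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Co);
  return out;
}

// Backward pass: gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gout, int stride, int pad, int groups) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int K1 = wdim[0], K2 = wdim[1], K3 = wdim[2], Cg = wdim[3], Co = wdim[4];
  const int Do = out_extent(D, K1, pad, stride);
  const int Ho = out_extent(H, K2, pad, stride);
  const int Wo = out_extent(W, K3, pad, stride);
  const int Cog = Co / groups;

  NumericVector gx(x.size());
  NumericVector gw(w.size());
  NumericVector gb(Co);
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();

  for (int co = 0; co < Co; ++co) {
    const int g = co / Cog;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        for (int dd = 0; dd < Do; ++dd) {
          const double go = pg[dd + Do * (ho + static_cast<R_xlen_t>(Ho) * (wo + static_cast<R_xlen_t>(Wo) * co))];
          if (go == 0.0) continue;
          pgb[co] += go;
          const int d0 = dd * stride - pad;
          const int h0 = ho * stride - pad;
          const int w0 = wo * stride - pad;
          for (int cg = 0; cg < Cg; ++cg) {
            const int ci = g * Cg + cg;
            const R_xlen_t xoff = static_cast<R_xlen_t>(ci) * D * H * W;
            for (int k3 = 0; k3 < K3; ++k3) {
              const int wi = w0 + k3;
              if (wi < 0 || wi >= W) continue;
              for (int k2 = 0; k2 < K2; ++k2) {
                const int hi = h0 + k2;
                if (hi < 0 || hi >= H) continue;
                for (int k1 = 0; k1 < K1; ++k1) {
                  const int di = d0 + k1;
                  if (di < 0 || di >= D) continue;
                  const R_xlen_t xi = xoff + di + D * (hi + static_cast<R_xlen_t>(H) * wi);
                  const R_xlen_t wiidx = k1 + K1 * (k2 + K2 * (k3 + K3 * (cg + static_cast<R_xlen_t>(Cg) * co)));
                  pgx[xi] += go * pw[wiidx];
                  pgw[wiidx] += go * px[xi];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
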