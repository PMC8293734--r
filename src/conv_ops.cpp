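#include <Rcpp.h>
using namespace Rcpp;

// Dimension conventions (all arrays are R arrays, column-major):
//   input   : H x W x C
//   filters : k x k x C x F   (square kernels, full channel depth)
//   output  : (H-k+1) x (W-k+1) x F
// "Valid" convolution, stride 1, no padding: each output cell is the dot
// product of a filter with the aligned input patch plus that filter's bias.

// [[Rcpp::export]]
NumericVector conv_forward_cpp(NumericVector input, NumericVector filters,
                               NumericVector biases) {
  IntegerVector di = input.attr("dim");
  IntegerVector df = filters.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  const int k = df[0], F = df[3];
  if (df[1] != k) stop("filters must be square");
  if (df[2] != C) stop("filter depth must equal input channels");
  if (H < k || W < k) stop("input smaller than kernel");
  const int Ho = H - k + 1, Wo = W - k + 1;

  NumericVector out(Ho * Wo * F);
  out.attr("dim") = IntegerVector::create(Ho, Wo, F);
  const double *in = input.begin(), *fw = filters.begin();
  double *o = out.begin();

  if (k == 3) {
    // unrolled 3x3 path: one filter channel at a time, accumulated into
    // the output plane (bias seeds the first channel)
    for (int f = 0; f < F; ++f) {
      double *po = o + (size_t)f * Ho * Wo;
      for (int c = 0; c < C; ++c) {
        const double *fc = fw + ((size_t)f * C + c) * 9;
        const double w00 = fc[0], w10 = fc[1], w20 = fc[2];
        const double w01 = fc[3], w11 = fc[4], w21 = fc[5];
        const double w02 = fc[6], w12 = fc[7], w22 = fc[8];
        const double *ic = in + (size_t)c * H * W;
        for (int x = 0; x < Wo; ++x) {
          const double *c0 = ic + (size_t)x * H;
          const double *c1 = c0 + H, *c2 = c1 + H;
          double *oc = po + (size_t)x * Ho;
          if (c == 0) {
            const double b = biases[f];
            for (int y = 0; y < Ho; ++y)
              oc[y] = b + w00 * c0[y] + w10 * c0[y + 1] + w20 * c0[y + 2]
                        + w01 * c1[y] + w11 * c1[y + 1] + w21 * c1[y + 2]
                        + w02 * c2[y] + w12 * c2[y + 1] + w22 * c2[y + 2];
          } else {
            for (int y = 0; y < Ho; ++y)
              oc[y] += w00 * c0[y] + w10 * c0[y + 1] + w20 * c0[y + 2]
                     + w01 * c1[y] + w11 * c1[y + 1] + w21 * c1[y + 2]
                     + w02 * c2[y] + w12 * c2[y + 1] + w22 * c2[y + 2];
          }
        }
      }
    }
    return out;
  }

  for (int f = 0; f < F; ++f) {
    const double b = biases[f];
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        double acc = b;
        for (int c = 0; c < C; ++c) {
          const double *inc = in + (size_t)c * H * W;
          const double *fwc = fw + ((size_t)f * C + c) * k * k;
          for (int j = 0; j < k; ++j) {
            const double *col = inc + (size_t)(x + j) * H + y;
            const double *frow = fwc + (size_t)j * k;
            for (int i = 0; i < k; ++i) acc += col[i] * frow[i];
          }
        }
        o[(size_t)f * Ho * Wo + (size_t)x * Ho + y] = acc;
      }
    }
  }
  return out;
}

// Reverse-mode gradients of the valid convolution.
// grad_out: Ho x Wo x F. Returns list(input=, filters=, biases=).
// [[Rcpp::export]]
List conv_backward_cpp(NumericVector input, NumericVector filters,
                       NumericVector grad_out) {
  IntegerVector di = input.attr("dim");
  IntegerVector df = filters.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  const int k = df[0], F = df[3];
  const int Ho = H - k + 1, Wo = W - k + 1;

  NumericVector gin(H * W * C), gfl(k * k * C * F), gb(F);
  gin.attr("dim") = di;
  gfl.attr("dim") = df;

  const double *in = input.begin(), *fw = filters.begin(),
               *go = grad_out.begin();
  double *gi = gin.begin(), *gf = gfl.begin();

  for (int f = 0; f < F; ++f) {
    const double *gof = go + (size_t)f * Ho * Wo;
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        const double g = gof[(size_t)x * Ho + y];
        if (g == 0.0) continue;
        for (int c = 0; c < C; ++c) {
          const double *inc = in + (size_t)c * H * W;
          double *gic = gi + (size_t)c * H * W;
          const double *fwc = fw + ((size_t)f * C + c) * k * k;
          double *gfc = gf + ((size_t)f * C + c) * k * k;
          for (int j = 0; j < k; ++j) {
            const size_t colin = (size_t)(x + j) * H + y;
            const size_t colfw = (size_t)j * k;
            for (int i = 0; i < k; ++i) {
              gfc[colfw + i] += g * inc[colin + i];
              gic[colin + i] += g * fwc[colfw + i];
            }
          }
        }
      }
    }
    double accb = 0.0;
    for (size_t t = 0; t < (size_t)Ho * Wo; ++t) accb += gof[t];
    gb[f] = accb;
  }
  return List::create(_["input"] = gin, _["filters"] = gfl,
                      _["biases"] = gb);
}

// Average pooling, window x window blocks with stride = window (trailing
// rows/columns that do not fill a block are dropped).
// [[Rcpp::export]]
NumericVector avgpool_forward_cpp(NumericVector input, int window) {
  IntegerVector di = input.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  if (H < window || W < window) stop("input smaller than pooling window");
  const int Ho = H / window, Wo = W / window;
  const double inv = 1.0 / (window * window);

  NumericVector out(Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  const double *in = input.begin();
  double *o = out.begin();

  for (int c = 0; c < C; ++c) {
    const double *inc = in + (size_t)c * H * W;
    double *oc = o + (size_t)c * Ho * Wo;
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        double acc = 0.0;
        for (int j = 0; j < window; ++j) {
          const double *col = inc + (size_t)(x * window + j) * H + y * window;
          for (int i = 0; i < window; ++i) acc += col[i];
        }
        oc[(size_t)x * Ho + y] = acc * inv;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool_backward_cpp(NumericVector grad_out, int H, int W,
                                   int window) {
  IntegerVector dgo = grad_out.attr("dim");
  const int Ho = dgo[0], Wo = dgo[1], C = dgo[2];
  const double inv = 1.0 / (window * window);

  NumericVector gin(H * W * C);
  gin.attr("dim") = IntegerVector::create(H, W, C);
  const double *go = grad_out.begin();
  double *gi = gin.begin();

  for (int c = 0; c < C; ++c) {
    const double *goc = go + (size_t)c * Ho * Wo;
    double *gic = gi + (size_t)c * H * W;
    for (int x = 0; x < Wo; ++x) {
      for (int y = 0; y < Ho; ++y) {
        const double g = goc[(size_t)x * Ho + y] * inv;
        for (int j = 0; j < window; ++j) {
          double *col = gic + (size_t)(x * window + j) * H + y * window;
          for (int i = 0; i < window; ++i) col[i] += g;
        }
      }
    }
  }
  return gin;
}
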