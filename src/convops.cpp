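#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major arrays with dim (H, W, N, C): rows, cols, batch, channels.
// im2col lowers a same-padded k x k neighbourhood gather to a dense matrix so that
// convolution becomes one BLAS matmul: out = P %*% Wmat, with Wmat of dim
// (k*k*Cin) x Cout flattened with the row offset fastest, column offset next,
// input channel slowest (matching the (k, k, Cin, Cout) weight array layout).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int N, int C,
                         int k, int pad) {
  const long HW = (long)H * W;
  const long rows = HW * N;
  const int kk = k * k;
  NumericMatrix P(no_init(rows, kk * C));
  const double* xp = x.begin();
  double* pp = P.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (long)c * HW * N;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * kk + dj * k + di;
        double* dst = pp + (long)col * rows;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (long)n * HW;
          double* dn = dst + (long)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - pad;
            double* dcol = dn + (long)j * H;
            if (jj < 0 || jj >= W) {
              for (int i = 0; i < H; ++i) dcol[i] = 0.0;
              continue;
            }
            const double* xcol = xn + (long)jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + di - pad;
              dcol[i] = (ii < 0 || ii >= H) ? 0.0 : xcol[ii];
            }
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col: scatter-add a (H*W*N) x (k*k*C) matrix of patch gradients
// back onto the input tensor (gradients of zero-padding are dropped).

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix P, int H, int W, int N, int C,
                         int k, int pad) {
  const long HW = (long)H * W;
  const long rows = HW * N;
  const int kk = k * k;
  NumericVector out((long)HW * N * C);
  double* op = out.begin();
  const double* pp = P.begin();
  for (int c = 0; c < C; ++c) {
    double* oc = op + (long)c * HW * N;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * kk + dj * k + di;
        const double* src = pp + (long)col * rows;
        for (int n = 0; n < N; ++n) {
          double* on = oc + (long)n * HW;
          const double* sn = src + (long)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            const double* scol = sn + (long)j * H;
            double* ocol = on + (long)jj * H;
            for (int i = 0; i < H; ++i) {
              const int ii = i + di - pad;
              if (ii >= 0 && ii < H) ocol[ii] += scol[i];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// 2x2 mean pooling and its adjoint, (H, W, N, C) layout; H and W must be even.

// [[Rcpp::export]]
NumericVector avgpool2_cpp(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const long NC = (long)N * C;
  NumericVector out((long)Ho * Wo * NC);
  const double* xp = x.begin();
  double* op = out.begin();
  for (long s = 0; s < NC; ++s) {
    const double* xs = xp + s * (long)H * W;
    double* os = op + s * (long)Ho * Wo;
    for (int j = 0; j < Wo; ++j) {
      const double* c0 = xs + (long)(2 * j) * H;
      const double* c1 = xs + (long)(2 * j + 1) * H;
      double* oc = os + (long)j * Ho;
      for (int i = 0; i < Ho; ++i)
        oc[i] = 0.25 * (c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1]);
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool2_back_cpp(NumericVector g, int Ho, int Wo, int N, int C) {
  const int H = Ho * 2, W = Wo * 2;
  const long NC = (long)N * C;
  NumericVector out((long)H * W * NC);
  const double* gp = g.begin();
  double* op = out.begin();
  for (long s = 0; s < NC; ++s) {
    const double* gs = gp + s * (long)Ho * Wo;
    double* os = op + s * (long)H * W;
    for (int j = 0; j < Wo; ++j) {
      const double* gc = gs + (long)j * Ho;
      double* c0 = os + (long)(2 * j) * H;
      double* c1 = os + (long)(2 * j + 1) * H;
      for (int i = 0; i < Ho; ++i) {
        const double v = 0.25 * gc[i];
        c0[2 * i] = v; c0[2 * i + 1] = v; c1[2 * i] = v; c1[2 * i + 1] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}

// Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).

// [[Rcpp::export]]
NumericVector upsample2_cpp(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H * 2, Wo = W * 2;
  const long NC = (long)N * C;
  NumericVector out((long)Ho * Wo * NC);
  const double* xp = x.begin();
  double* op = out.begin();
  for (long s = 0; s < NC; ++s) {
    const double* xs = xp + s * (long)H * W;
    double* os = op + s * (long)Ho * Wo;
    for (int j = 0; j < W; ++j) {
      const double* xc = xs + (long)j * H;
      double* c0 = os + (long)(2 * j) * Ho;
      double* c1 = os + (long)(2 * j + 1) * Ho;
      for (int i = 0; i < H; ++i) {
        c0[2 * i] = xc[i]; c0[2 * i + 1] = xc[i];
        c1[2 * i] = xc[i]; c1[2 * i + 1] = xc[i];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_back_cpp(NumericVector g, int Ho, int Wo, int N, int C) {
  const int H = Ho / 2, W = Wo / 2;
  const long NC = (long)N * C;
  NumericVector out((long)H * W * NC);
  const double* gp = g.begin();
  double* op = out.begin();
  for (long s = 0; s < NC; ++s) {
    const double* gs = gp + s * (long)Ho * Wo;
    double* os = op + s * (long)H * W;
    for (int j = 0; j < W; ++j) {
      const double* c0 = gs + (long)(2 * j) * Ho;
      const double* c1 = gs + (long)(2 * j + 1) * Ho;
      double* oc = os + (long)j * H;
      for (int i = 0; i < H; ++i)
        oc[i] = c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, N, C);
  return out;
}
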