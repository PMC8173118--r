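// Numerical kernels for the 3D segmentation network.
//
// Tensor layout convention (shared with the R code): 5-D arrays with
// dim = (X, Y, Z, C, N) where X/Y are the in-plane axes, Z the slice
// (depth) axis, C channels, N batch.  R arrays are column-major, so X
// varies fastest; each (channel, batch) spatial block is contiguous.
//
// Convolutions are im2col + GEMM (Armadillo/BLAS).  Strides and
// dilations are per-axis; the network only ever strides in-plane, but
// the kernels are general.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims5(const NumericVector& x, int d[5]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("expected a 5-D tensor");
  for (int i = 0; i < 5; ++i) d[i] = dm[i];
}

static inline int out_size(int n, int k, int s, int dl, int p) {
  return (n + 2 * p - ((k - 1) * dl + 1)) / s + 1;
}

// Fill col (K x P) for batch item n, channel range [c0, c0+Cg).
// K ordered (kx, ky, kz, c); P ordered (xo, yo, zo).
static void im2col(const double* x, int W, int H, int D, int C, int n,
                   int c0, int Cg, int kw, int kh, int kd,
                   int sw, int sh, int sd, int dw, int dh, int dd,
                   int pw, int ph, int pd, int Wo, int Ho, int Do,
                   arma::mat& col) {
  const int K = kw * kh * kd * Cg;
  for (int c = 0; c < Cg; ++c) {
    const double* xc = x + ((size_t)(c0 + c) + (size_t)C * n) * W * H * D;
    for (int kz = 0; kz < kd; ++kz)
      for (int ky = 0; ky < kh; ++ky)
        for (int kx = 0; kx < kw; ++kx) {
          const int krow = kx + kw * (ky + kh * (kz + kd * c));
          double* dst = col.memptr() + krow;
          size_t p = 0;
          for (int zo = 0; zo < Do; ++zo) {
            const int zi = zo * sd - pd + kz * dd;
            for (int yo = 0; yo < Ho; ++yo) {
              const int yi = yo * sh - ph + ky * dh;
              const bool ok = (zi >= 0 && zi < D && yi >= 0 && yi < H);
              const double* row = ok ? xc + (size_t)W * (yi + (size_t)H * zi) : 0;
              for (int xo = 0; xo < Wo; ++xo, ++p) {
                const int xi = xo * sw - pw + kx * dw;
                dst[p * K] = (ok && xi >= 0 && xi < W) ? row[xi] : 0.0;
              }
            }
          }
        }
  }
}

// Transpose of im2col: scatter-add col (K x P) back into gx.
static void col2im(double* gx, int W, int H, int D, int C, int n,
                   int c0, int Cg, int kw, int kh, int kd,
                   int sw, int sh, int sd, int dw, int dh, int dd,
                   int pw, int ph, int pd, int Wo, int Ho, int Do,
                   const arma::mat& col) {
  const int K = kw * kh * kd * Cg;
  for (int c = 0; c < Cg; ++c) {
    double* xc = gx + ((size_t)(c0 + c) + (size_t)C * n) * W * H * D;
    for (int kz = 0; kz < kd; ++kz)
      for (int ky = 0; ky < kh; ++ky)
        for (int kx = 0; kx < kw; ++kx) {
          const int krow = kx + kw * (ky + kh * (kz + kd * c));
          const double* src = col.memptr() + krow;
          size_t p = 0;
          for (int zo = 0; zo < Do; ++zo) {
            const int zi = zo * sd - pd + kz * dd;
            for (int yo = 0; yo < Ho; ++yo) {
              const int yi = yo * sh - ph + ky * dh;
              const bool ok = (zi >= 0 && zi < D && yi >= 0 && yi < H);
              double* row = ok ? xc + (size_t)W * (yi + (size_t)H * zi) : 0;
              for (int xo = 0; xo < Wo; ++xo, ++p) {
                const int xi = xo * sw - pw + kx * dw;
                if (ok && xi >= 0 && xi < W) row[xi] += src[p * K];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector stride, IntegerVector dil,
                             IntegerVector pad, int groups) {
  int xd[5]; dims5(x, xd);
  const int W = xd[0], H = xd[1], D = xd[2], C = xd[3], N = xd[4];
  IntegerVector wd = w.attr("dim");
  const int kw = wd[0], kh = wd[1], kd = wd[2], Cg = wd[3], Cout = wd[4];
  if (C != Cg * groups) stop("input channels inconsistent with weight/groups");
  const int Coutg = Cout / groups;
  // pointwise fast path: pure channel mixing, no im2col needed
  if (kw == 1 && kh == 1 && kd == 1 && stride[0] == 1 && stride[1] == 1 &&
      stride[2] == 1 && pad[0] == 0 && pad[1] == 0 && pad[2] == 0) {
    const size_t S = (size_t)W * H * D;
    NumericVector out(S * Cout * N);
    out.attr("dim") = IntegerVector::create(W, H, D, Cout, N);
    const bool has_b = b.size() == Cout;
    for (int n = 0; n < N; ++n)
      for (int g = 0; g < groups; ++g) {
        const arma::mat X(const_cast<double*>(x.begin()) +
                          ((size_t)g * Cg + (size_t)C * n) * S, S, Cg, false, true);
        const arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * Coutg * Cg,
                           Cg, Coutg, false, true);
        arma::mat O(out.begin() + ((size_t)g * Coutg + (size_t)Cout * n) * S,
                    S, Coutg, false, true);
        O = X * Wg;
        if (has_b)
          for (int j = 0; j < Coutg; ++j) O.col(j) += b[g * Coutg + j];
      }
    return out;
  }
  const int sw = stride[0], sh = stride[1], sd = stride[2];
  const int dw = dil[0], dh = dil[1], dd = dil[2];
  const int pw = pad[0], ph = pad[1], pd = pad[2];
  const int Wo = out_size(W, kw, sw, dw, pw);
  const int Ho = out_size(H, kh, sh, dh, ph);
  const int Do = out_size(D, kd, sd, dd, pd);
  if (Wo < 1 || Ho < 1 || Do < 1) stop("convolution output would be empty");
  const int K = kw * kh * kd * Cg;
  const size_t P = (size_t)Wo * Ho * Do;

  NumericVector out(P * Cout * N);
  out.attr("dim") = IntegerVector::create(Wo, Ho, Do, Cout, N);
  const arma::mat Wall(const_cast<double*>(w.begin()), K, Cout, false, true);
  const bool has_b = b.size() == Cout;
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), W, H, D, C, n, g * Cg, Cg, kw, kh, kd,
             sw, sh, sd, dw, dh, dd, pw, ph, pd, Wo, Ho, Do, col);
      arma::mat om = col.t() * Wall.cols(g * Coutg, (g + 1) * Coutg - 1); // P x Coutg
      for (int j = 0; j < Coutg; ++j) {
        const int co = g * Coutg + j;
        double* dst = out.begin() + ((size_t)co + (size_t)Cout * n) * P;
        const double* src = om.colptr(j);
        if (has_b) {
          const double bc = b[co];
          for (size_t p = 0; p < P; ++p) dst[p] = src[p] + bc;
        } else {
          std::copy(src, src + P, dst);
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gout,
                    IntegerVector stride, IntegerVector dil,
                    IntegerVector pad, int groups, bool has_bias,
                    bool need_gx) {
  int xd[5]; dims5(x, xd);
  const int W = xd[0], H = xd[1], D = xd[2], C = xd[3], N = xd[4];
  IntegerVector wd = w.attr("dim");
  const int kw = wd[0], kh = wd[1], kd = wd[2], Cg = wd[3], Cout = wd[4];
  const int Coutg = Cout / groups;
  // pointwise fast path
  if (kw == 1 && kh == 1 && kd == 1 && stride[0] == 1 && stride[1] == 1 &&
      stride[2] == 1 && pad[0] == 0 && pad[1] == 0 && pad[2] == 0) {
    const size_t S = (size_t)W * H * D;
    NumericVector gx(x.size());  gx.attr("dim") = x.attr("dim");
    NumericVector gw(w.size());  gw.attr("dim") = w.attr("dim");
    NumericVector gb(has_bias ? Cout : 0);
    for (int n = 0; n < N; ++n)
      for (int g = 0; g < groups; ++g) {
        const arma::mat X(const_cast<double*>(x.begin()) +
                          ((size_t)g * Cg + (size_t)C * n) * S, S, Cg, false, true);
        const arma::mat Wg(const_cast<double*>(w.begin()) + (size_t)g * Coutg * Cg,
                           Cg, Coutg, false, true);
        const arma::mat G(const_cast<double*>(gout.begin()) +
                          ((size_t)g * Coutg + (size_t)Cout * n) * S, S, Coutg, false, true);
        arma::mat GX(gx.begin() + ((size_t)g * Cg + (size_t)C * n) * S, S, Cg, false, true);
        arma::mat GW(gw.begin() + (size_t)g * Coutg * Cg, Cg, Coutg, false, true);
        if (need_gx) GX += G * Wg.t();
        GW += X.t() * G;
        if (has_bias)
          for (int j = 0; j < Coutg; ++j) gb[g * Coutg + j] += arma::accu(G.col(j));
      }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  const int sw = stride[0], sh = stride[1], sd = stride[2];
  const int dw = dil[0], dh = dil[1], dd = dil[2];
  const int pw = pad[0], ph = pad[1], pd = pad[2];
  int gd[5]; dims5(gout, gd);
  const int Wo = gd[0], Ho = gd[1], Do = gd[2];
  const int K = kw * kh * kd * Cg;
  const size_t P = (size_t)Wo * Ho * Do;

  NumericVector gx(x.size());  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());  gw.attr("dim") = w.attr("dim");
  NumericVector gb(has_bias ? Cout : 0);

  const arma::mat Wall(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat GWall(gw.begin(), K, Cout, false, true);
  arma::mat col(K, P), gm(P, Coutg);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      for (int j = 0; j < Coutg; ++j) {
        const int co = g * Coutg + j;
        const double* src = gout.begin() + ((size_t)co + (size_t)Cout * n) * P;
        std::copy(src, src + P, gm.colptr(j));
        if (has_bias) gb[co] += arma::accu(arma::vec(gm.colptr(j), P, false, true));
      }
      im2col(x.begin(), W, H, D, C, n, g * Cg, Cg, kw, kh, kd,
             sw, sh, sd, dw, dh, dd, pw, ph, pd, Wo, Ho, Do, col);
      GWall.cols(g * Coutg, (g + 1) * Coutg - 1) += col * gm;            // K x Coutg
      if (need_gx) {
        arma::mat cg = Wall.cols(g * Coutg, (g + 1) * Coutg - 1) * gm.t(); // K x P
        col2im(gx.begin(), W, H, D, C, n, g * Cg, Cg, kw, kh, kd,
               sw, sh, sd, dw, dh, dd, pw, ph, pd, Wo, Ho, Do, cg);
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// In-plane max pooling, kernel = stride = k, depth untouched.
// [[Rcpp::export]]
List maxpool_inplane_fwd_cpp(NumericVector x, int k) {
  int d[5]; dims5(x, d);
  const int W = d[0], H = d[1], D = d[2], C = d[3], N = d[4];
  if (W % k || H % k) stop("in-plane dims must be divisible by the pooling factor");
  const int Wo = W / k, Ho = H / k;
  NumericVector out((size_t)Wo * Ho * D * C * N);
  out.attr("dim") = IntegerVector::create(Wo, Ho, D, C, N);
  IntegerVector arg(out.size());
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xb = x.begin() + (size_t)cn * W * H * D;
    const size_t base = (size_t)cn * W * H * D;
    for (int z = 0; z < D; ++z)
      for (int yo = 0; yo < Ho; ++yo)
        for (int xo = 0; xo < Wo; ++xo, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dy = 0; dy < k; ++dy)
            for (int dx = 0; dx < k; ++dx) {
              const size_t idx = (size_t)(xo * k + dx) +
                (size_t)W * ((yo * k + dy) + (size_t)H * z);
              if (xb[idx] > best) { best = xb[idx]; bi = idx; }
            }
          out[o] = best;
          arg[o] = (double)(base + bi) < 2147483647.0 ? (int)(base + bi) : -1;
          if (arg[o] < 0) stop("tensor too large for pooling index");
        }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_inplane_bwd_cpp(NumericVector gout, IntegerVector argmax,
                                      IntegerVector xdim) {
  size_t n = 1; for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  return gx;
}

// In-plane up-sampling by integer factor f; depth copied through.
// mode 0 = nearest, 1 = bilinear (half-pixel centres, clamped edges).
// [[Rcpp::export]]
NumericVector upsample_inplane_fwd_cpp(NumericVector x, int f, int mode) {
  int d[5]; dims5(x, d);
  const int W = d[0], H = d[1], D = d[2], C = d[3], N = d[4];
  const int Wo = W * f, Ho = H * f;
  NumericVector out((size_t)Wo * Ho * D * C * N);
  out.attr("dim") = IntegerVector::create(Wo, Ho, D, C, N);
  std::vector<int> x0(Wo), x1(Wo), y0(Ho), y1(Ho);
  std::vector<double> tx(Wo), ty(Ho);
  for (int i = 0; i < Wo; ++i) {
    if (mode == 0) { x0[i] = x1[i] = i / f; tx[i] = 0; }
    else {
      double s = (i + 0.5) / f - 0.5;
      int lo = (int)std::floor(s);
      double t = s - lo;
      if (lo < 0) { lo = 0; t = 0; }
      if (lo >= W - 1) { lo = W - 1; t = 0; }
      x0[i] = lo; x1[i] = std::min(lo + 1, W - 1); tx[i] = t;
    }
  }
  for (int j = 0; j < Ho; ++j) {
    if (mode == 0) { y0[j] = y1[j] = j / f; ty[j] = 0; }
    else {
      double s = (j + 0.5) / f - 0.5;
      int lo = (int)std::floor(s);
      double t = s - lo;
      if (lo < 0) { lo = 0; t = 0; }
      if (lo >= H - 1) { lo = H - 1; t = 0; }
      y0[j] = lo; y1[j] = std::min(lo + 1, H - 1); ty[j] = t;
    }
  }
  size_t o = 0;
  for (int s = 0; s < D * C * N; ++s) {
    const double* pl = x.begin() + (size_t)s * W * H;
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Wo; ++i, ++o) {
        const double v00 = pl[x0[i] + (size_t)W * y0[j]];
        const double v10 = pl[x1[i] + (size_t)W * y0[j]];
        const double v01 = pl[x0[i] + (size_t)W * y1[j]];
        const double v11 = pl[x1[i] + (size_t)W * y1[j]];
        out[o] = (1 - ty[j]) * ((1 - tx[i]) * v00 + tx[i] * v10) +
                 ty[j] * ((1 - tx[i]) * v01 + tx[i] * v11);
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample_inplane_bwd_cpp(NumericVector gout, IntegerVector xdim,
                                       int f, int mode) {
  const int W = xdim[0], H = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int Wo = W * f, Ho = H * f;
  NumericVector gx((size_t)W * H * D * C * N);
  gx.attr("dim") = xdim;
  size_t o = 0;
  for (int s = 0; s < D * C * N; ++s) {
    double* pl = gx.begin() + (size_t)s * W * H;
    for (int j = 0; j < Ho; ++j) {
      int ylo, yhi; double t2;
      if (mode == 0) { ylo = yhi = j / f; t2 = 0; }
      else {
        double sy = (j + 0.5) / f - 0.5;
        ylo = (int)std::floor(sy); t2 = sy - ylo;
        if (ylo < 0) { ylo = 0; t2 = 0; }
        if (ylo >= H - 1) { ylo = H - 1; t2 = 0; }
        yhi = std::min(ylo + 1, H - 1);
      }
      for (int i = 0; i < Wo; ++i, ++o) {
        int xlo, xhi; double t1;
        if (mode == 0) { xlo = xhi = i / f; t1 = 0; }
        else {
          double sx = (i + 0.5) / f - 0.5;
          xlo = (int)std::floor(sx); t1 = sx - xlo;
          if (xlo < 0) { xlo = 0; t1 = 0; }
          if (xlo >= W - 1) { xlo = W - 1; t1 = 0; }
          xhi = std::min(xlo + 1, W - 1);
        }
        const double g = gout[o];
        pl[xlo + (size_t)W * ylo] += (1 - t2) * (1 - t1) * g;
        pl[xhi + (size_t)W * ylo] += (1 - t2) * t1 * g;
        pl[xlo + (size_t)W * yhi] += t2 * (1 - t1) * g;
        pl[xhi + (size_t)W * yhi] += t2 * t1 * g;
      }
    }
  }
  return gx;
}

// ---- group normalization ---------------------------------------------------

// [[Rcpp::export]]
NumericVector gn_fwd_cpp(NumericVector x, NumericVector gamma,
                         NumericVector beta, int groups, double eps) {
  int d[5]; dims5(x, d);
  const size_t S = (size_t)d[0] * d[1] * d[2];
  const int C = d[3], N = d[4];
  const int Cg = C / groups;
  const size_t M = S * Cg;
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const double* xb = x.begin() + ((size_t)g * Cg + (size_t)C * n) * S;
      double* ob = out.begin() + ((size_t)g * Cg + (size_t)C * n) * S;
      double mu = 0;
      for (size_t i = 0; i < M; ++i) mu += xb[i];
      mu /= M;
      double va = 0;
      for (size_t i = 0; i < M; ++i) { const double c = xb[i] - mu; va += c * c; }
      va /= M;
      const double istd = 1.0 / std::sqrt(va + eps);
      for (int c = 0; c < Cg; ++c) {
        const double ga = gamma[g * Cg + c], be = beta[g * Cg + c];
        const double* xc = xb + (size_t)c * S;
        double* oc = ob + (size_t)c * S;
        for (size_t i = 0; i < S; ++i) oc[i] = (xc[i] - mu) * istd * ga + be;
      }
    }
  return out;
}

// [[Rcpp::export]]
List gn_bwd_cpp(NumericVector x, NumericVector gamma, NumericVector gout,
                int groups, double eps) {
  int d[5]; dims5(x, d);
  const size_t S = (size_t)d[0] * d[1] * d[2];
  const int C = d[3], N = d[4];
  const int Cg = C / groups;
  const size_t M = S * Cg;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector ggamma(C), gbeta(C);
  std::vector<double> xhat(M), dyg(M);
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const double* xb = x.begin() + ((size_t)g * Cg + (size_t)C * n) * S;
      const double* gb = gout.begin() + ((size_t)g * Cg + (size_t)C * n) * S;
      double* gxb = gx.begin() + ((size_t)g * Cg + (size_t)C * n) * S;
      double mu = 0;
      for (size_t i = 0; i < M; ++i) mu += xb[i];
      mu /= M;
      double va = 0;
      for (size_t i = 0; i < M; ++i) { const double c = xb[i] - mu; va += c * c; }
      va /= M;
      const double istd = 1.0 / std::sqrt(va + eps);
      double mu1 = 0, mu2 = 0;
      for (int c = 0; c < Cg; ++c) {
        const double ga = gamma[g * Cg + c];
        double sgx = 0, sg = 0;
        for (size_t i = 0; i < S; ++i) {
          const size_t j = (size_t)c * S + i;
          xhat[j] = (xb[j] - mu) * istd;
          dyg[j] = gb[j] * ga;
          mu1 += dyg[j];
          mu2 += dyg[j] * xhat[j];
          sgx += gb[j] * xhat[j];
          sg += gb[j];
        }
        ggamma[g * Cg + c] += sgx;
        gbeta[g * Cg + c] += sg;
      }
      mu1 /= M; mu2 /= M;
      for (size_t i = 0; i < M; ++i)
        gxb[i] = (dyg[i] - mu1 - xhat[i] * mu2) * istd;
    }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- PReLU -----------------------------------------------------------------

// [[Rcpp::export]]
NumericVector prelu_fwd_cpp(NumericVector x, NumericVector alpha) {
  int d[5]; dims5(x, d);
  const size_t S = (size_t)d[0] * d[1] * d[2];
  const int C = d[3], N = d[4];
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = alpha[c];
      const double* xb = x.begin() + ((size_t)c + (size_t)C * n) * S;
      double* ob = out.begin() + ((size_t)c + (size_t)C * n) * S;
      for (size_t i = 0; i < S; ++i) ob[i] = xb[i] > 0 ? xb[i] : a * xb[i];
    }
  return out;
}

// [[Rcpp::export]]
List prelu_bwd_cpp(NumericVector x, NumericVector alpha, NumericVector gout) {
  int d[5]; dims5(x, d);
  const size_t S = (size_t)d[0] * d[1] * d[2];
  const int C = d[3], N = d[4];
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector galpha(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = alpha[c];
      const double* xb = x.begin() + ((size_t)c + (size_t)C * n) * S;
      const double* gb = gout.begin() + ((size_t)c + (size_t)C * n) * S;
      double* gxb = gx.begin() + ((size_t)c + (size_t)C * n) * S;
      double ga = 0;
      for (size_t i = 0; i < S; ++i) {
        if (xb[i] > 0) gxb[i] = gb[i];
        else { gxb[i] = a * gb[i]; ga += gb[i] * xb[i]; }
      }
      galpha[c] += ga;
    }
  return List::create(_["gx"] = gx, _["galpha"] = galpha);
}

// ---- Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxels) from every grid point to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int W = dims[0], H = dims[1], D = dims[2];
  const double INF = 1e30;
  std::vector<double> g((size_t)W * H * D);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(W, std::max(H, D));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along X
  for (int zz = 0; zz < D; ++zz)
    for (int y = 0; y < H; ++y) {
      double* row = &g[(size_t)W * (y + (size_t)H * zz)];
      for (int x = 0; x < W; ++x) f[x] = row[x];
      dt1d(f, d, v, z, W);
      for (int x = 0; x < W; ++x) row[x] = d[x];
    }
  // pass along Y
  for (int zz = 0; zz < D; ++zz)
    for (int x = 0; x < W; ++x) {
      for (int y = 0; y < H; ++y) f[y] = g[x + (size_t)W * (y + (size_t)H * zz)];
      dt1d(f, d, v, z, H);
      for (int y = 0; y < H; ++y) g[x + (size_t)W * (y + (size_t)H * zz)] = d[y];
    }
  // pass along Z
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      for (int zz = 0; zz < D; ++zz) f[zz] = g[x + (size_t)W * (y + (size_t)H * zz)];
      dt1d(f, d, v, z, D);
      for (int zz = 0; zz < D; ++zz) g[x + (size_t)W * (y + (size_t)H * zz)] = d[zz];
    }
  NumericVector out((size_t)W * H * D);
  out.attr("dim") = IntegerVector::create(W, H, D);
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
  return out;
}
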