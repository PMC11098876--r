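#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// A small 2D convolutional regression network, written from scratch because
// the interpolator itself is the package's core method and no deep-learning
// backend is assumed.  Architecture:
//   hidden layers h = 1..L-1: same-padded conv (kh x kw) + ReLU, F filters;
//     identity skip connections: a_h += a_{h - skip_period} for
//     h > skip_period with (h - 1) %% skip_period == 0;
//   output layer L: same-padded conv to a single channel (linear), plus a
//     global identity skip from the input, so a zero output layer reproduces
//     the (linearly interleaved) input exactly.
// Tensors are stored flat as [i + H*(j + W*c)]; weights as
// [di + kh*(dj + kw*(ci + Cin*co))].

static void conv_fwd(const double* in, int H, int W, int Cin,
                     const double* wt, const double* bias,
                     int kh, int kw, int Cout, double* out) {
  const int ph = kh / 2, pw = kw / 2;
  for (int co = 0; co < Cout; ++co) {
    const double b = bias[co];
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out[i + H * (j + (size_t)W * co)] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* wbase = wt + kh * (kw * (ci + (size_t)Cin * co));
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const double w = wbase[di + kh * dj];
          if (w == 0.0) continue;
          const int oi0 = std::max(0, ph - di), oi1 = std::min(H, H + ph - di);
          const int oj0 = std::max(0, pw - dj), oj1 = std::min(W, W + pw - dj);
          for (int j = oj0; j < oj1; ++j) {
            const double* icol = in + H * (j + dj - pw + (size_t)W * ci);
            double* ocol = out + H * (j + (size_t)W * co);
            for (int i = oi0; i < oi1; ++i)
              ocol[i] += w * icol[i + di - ph];
          }
        }
      }
    }
  }
}

// gradient w.r.t. weights and bias (accumulating)
static void conv_dW(const double* in, int H, int W, int Cin,
                    const double* dout, int kh, int kw, int Cout,
                    double* dwt, double* dbias) {
  const int ph = kh / 2, pw = kw / 2;
  for (int co = 0; co < Cout; ++co) {
    const double* dcol0 = dout + (size_t)H * W * co;
    double s = 0.0;
    for (size_t p = 0; p < (size_t)H * W; ++p) s += dcol0[p];
    dbias[co] += s;
    for (int ci = 0; ci < Cin; ++ci) {
      double* dwbase = dwt + kh * (kw * (ci + (size_t)Cin * co));
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const int oi0 = std::max(0, ph - di), oi1 = std::min(H, H + ph - di);
          const int oj0 = std::max(0, pw - dj), oj1 = std::min(W, W + pw - dj);
          double acc = 0.0;
          for (int j = oj0; j < oj1; ++j) {
            const double* icol = in + H * (j + dj - pw + (size_t)W * ci);
            const double* dcol = dout + H * (j + (size_t)W * co);
            for (int i = oi0; i < oi1; ++i)
              acc += icol[i + di - ph] * dcol[i];
          }
          dwbase[di + kh * dj] += acc;
        }
      }
    }
  }
}

// gradient w.r.t. the layer input (accumulating)
static void conv_dIn(const double* dout, int H, int W, int Cout,
                     const double* wt, int kh, int kw, int Cin, double* din) {
  const int ph = kh / 2, pw = kw / 2;
  for (int co = 0; co < Cout; ++co) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* wbase = wt + kh * (kw * (ci + (size_t)Cin * co));
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const double w = wbase[di + kh * dj];
          if (w == 0.0) continue;
          // din[ii,jj,ci] += dout[ii - di + ph, jj - dj + pw, co] * w
          const int ii0 = std::max(0, di - ph), ii1 = std::min(H, H + di - ph);
          const int jj0 = std::max(0, dj - pw), jj1 = std::min(W, W + dj - pw);
          for (int jj = jj0; jj < jj1; ++jj) {
            double* dincol = din + H * (jj + (size_t)W * ci);
            const double* dcol = dout + H * (jj - dj + pw + (size_t)W * co);
            for (int ii = ii0; ii < ii1; ++ii)
              dincol[ii] += w * dcol[ii - di + ph];
          }
        }
      }
    }
  }
}

struct CnnShape {
  int H, W, kh, kw, F, L, skip;
  std::vector<size_t> w_off, b_off;  // per conv layer (1..L), 0-based entries
  size_t n_par;
  CnnShape(int H_, int W_, int kh_, int kw_, int F_, int L_, int skip_)
      : H(H_), W(W_), kh(kh_), kw(kw_), F(F_), L(L_), skip(skip_) {
    size_t off = 0;
    for (int l = 1; l <= L; ++l) {
      int cin = (l == 1) ? 1 : F;
      int cout = (l == L) ? 1 : F;
      w_off.push_back(off); off += (size_t)kh * kw * cin * cout;
      b_off.push_back(off); off += cout;
    }
    n_par = off;
  }
  int cin(int l) const { return (l == 1) ? 1 : F; }
  int cout(int l) const { return (l == L) ? 1 : F; }
  bool has_skip(int h) const {
    return skip > 0 && h > skip && ((h - 1) % skip) == 0;
  }
};

// [[Rcpp::export]]
double cnn_n_params_cpp(int H, int W, int kh, int kw, int F, int L, int skip) {
  CnnShape sh(H, W, kh, kw, F, L, skip);
  return (double)sh.n_par;
}

// forward pass for a batch; x is n x H x W (R array, first index fastest)
// [[Rcpp::export]]
NumericVector cnn_forward_cpp(NumericVector par, NumericVector x, int n,
                              int H, int W, int kh, int kw, int F, int L,
                              int skip) {
  CnnShape sh(H, W, kh, kw, F, L, skip);
  if ((size_t)par.size() != sh.n_par) stop("parameter vector has wrong length");
  const double* p = REAL(par);
  const size_t plane = (size_t)H * W;
  NumericVector y((size_t)n * plane);
  std::vector<double> xin(plane), a_prev, a_cur, out(plane);
  std::vector<std::vector<double>> acts(L);  // post-skip activations, 1..L-1
  for (int h = 1; h < L; ++h) acts[h].resize(plane * F);

  for (int s = 0; s < n; ++s) {
    for (size_t q = 0; q < plane; ++q) {
      size_t i = q % H, j = q / H;
      xin[q] = x[s + (size_t)n * (i + (size_t)H * j)];
    }
    const double* prev = xin.data();
    for (int h = 1; h < L; ++h) {
      conv_fwd(prev, H, W, sh.cin(h), p + sh.w_off[h - 1], p + sh.b_off[h - 1],
               kh, kw, F, acts[h].data());
      for (size_t q = 0; q < plane * F; ++q)
        if (acts[h][q] < 0.0) acts[h][q] = 0.0;
      if (sh.has_skip(h))
        for (size_t q = 0; q < plane * F; ++q) acts[h][q] += acts[h - sh.skip][q];
      prev = acts[h].data();
    }
    conv_fwd(prev, H, W, F, p + sh.w_off[L - 1], p + sh.b_off[L - 1],
             kh, kw, 1, out.data());
    for (size_t q = 0; q < plane; ++q) {
      size_t i = q % H, j = q / H;
      y[s + (size_t)n * (i + (size_t)H * j)] = out[q] + xin[q];
    }
  }
  y.attr("dim") = IntegerVector::create(n, H, W);
  return y;
}

// mean-squared-error loss and gradient over a batch
// [[Rcpp::export]]
List cnn_loss_grad_cpp(NumericVector par, NumericVector x, NumericVector t,
                       int n, int H, int W, int kh, int kw, int F, int L,
                       int skip) {
  CnnShape sh(H, W, kh, kw, F, L, skip);
  if ((size_t)par.size() != sh.n_par) stop("parameter vector has wrong length");
  const double* p = REAL(par);
  const size_t plane = (size_t)H * W;
  NumericVector grad(sh.n_par);
  double* g = REAL(grad);
  double loss = 0.0;
  const double denom = (double)n * plane;

  std::vector<double> xin(plane), out(plane), dy(plane);
  std::vector<std::vector<double>> z(L), a(L), da(L);
  for (int h = 1; h < L; ++h) {
    z[h].resize(plane * F); a[h].resize(plane * F); da[h].resize(plane * F);
  }

  for (int s = 0; s < n; ++s) {
    for (size_t q = 0; q < plane; ++q) {
      size_t i = q % H, j = q / H;
      xin[q] = x[s + (size_t)n * (i + (size_t)H * j)];
    }
    // forward with caching
    const double* prev = xin.data();
    for (int h = 1; h < L; ++h) {
      conv_fwd(prev, H, W, sh.cin(h), p + sh.w_off[h - 1], p + sh.b_off[h - 1],
               kh, kw, F, z[h].data());
      for (size_t q = 0; q < plane * F; ++q)
        a[h][q] = z[h][q] > 0.0 ? z[h][q] : 0.0;
      if (sh.has_skip(h))
        for (size_t q = 0; q < plane * F; ++q) a[h][q] += a[h - sh.skip][q];
      prev = a[h].data();
    }
    conv_fwd(prev, H, W, F, p + sh.w_off[L - 1], p + sh.b_off[L - 1],
             kh, kw, 1, out.data());
    for (size_t q = 0; q < plane; ++q) {
      size_t i = q % H, j = q / H;
      const double resid = out[q] + xin[q] - t[s + (size_t)n * (i + (size_t)H * j)];
      loss += resid * resid;
      dy[q] = 2.0 * resid / denom;
    }
    // backward
    for (int h = 1; h < L; ++h)
      std::fill(da[h].begin(), da[h].end(), 0.0);
    conv_dW(a[L - 1].data(), H, W, F, dy.data(), kh, kw, 1,
            g + sh.w_off[L - 1], g + sh.b_off[L - 1]);
    conv_dIn(dy.data(), H, W, 1, p + sh.w_off[L - 1], kh, kw, F,
             da[L - 1].data());
    for (int h = L - 1; h >= 1; --h) {
      if (sh.has_skip(h))
        for (size_t q = 0; q < plane * F; ++q)
          da[h - sh.skip][q] += da[h][q];
      // through ReLU
      for (size_t q = 0; q < plane * F; ++q)
        if (z[h][q] <= 0.0) da[h][q] = 0.0;
      const double* in_h = (h == 1) ? xin.data() : a[h - 1].data();
      conv_dW(in_h, H, W, sh.cin(h), da[h].data(), kh, kw, F,
              g + sh.w_off[h - 1], g + sh.b_off[h - 1]);
      if (h > 1)
        conv_dIn(da[h].data(), H, W, F, p + sh.w_off[h - 1], kh, kw, sh.cin(h),
                 da[h - 1].data());
    }
  }
  return List::create(_["loss"] = loss / denom, _["grad"] = grad);
}
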