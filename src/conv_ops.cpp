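// Low-level tensor ops for the sequential conv-net engine.
// Tensors are (H, W, C) cubes; conv weights are (kh*kw*Cin) x Cout matrices
// with patch rows ordered ki (fastest), kj, c — matching im2col below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::cube& x, int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  mat cols(kh * kw * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int xj = oj * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int xi = oi * stride + ki - pad;
            if (xi < 0 || xi >= H) continue;
            cols(row, oi + Ho * oj) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add inverse of im2col
static cube col2im(const mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad) {
  const int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < Wo; ++oj) {
          const int xj = oj * stride + kj - pad;
          if (xj < 0 || xj >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int xi = oi * stride + ki - pad;
            if (xi < 0 || xi >= H) continue;
            x(xi, xj, c) += cols(row, oi + Ho * oj);
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube conv_forward_cpp(const arma::cube& x, const arma::mat& w,
                            int kh, int kw, int stride, int pad) {
  const int Ho = out_dim(x.n_rows, kh, stride, pad);
  const int Wo = out_dim(x.n_cols, kw, stride, pad);
  const int Cout = w.n_cols;
  mat cols = im2col_cpp(x, kh, kw, stride, pad);
  mat res = cols.t() * w;                       // (Ho*Wo) x Cout, column-major
  return cube(res.memptr(), Ho, Wo, Cout);      // same memory layout
}

// forward that also returns the unfolded input, reused by the backward pass
// [[Rcpp::export]]
Rcpp::List conv_forward_train_cpp(const arma::cube& x, const arma::mat& w,
                                  int kh, int kw, int stride, int pad) {
  const int Ho = out_dim(x.n_rows, kh, stride, pad);
  const int Wo = out_dim(x.n_cols, kw, stride, pad);
  const int Cout = w.n_cols;
  mat cols = im2col_cpp(x, kh, kw, stride, pad);
  mat res = cols.t() * w;
  cube out(res.memptr(), Ho, Wo, Cout);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("cols") = cols);
}

// [[Rcpp::export]]
Rcpp::List conv_backward_cpp(const arma::mat& cols, const arma::mat& w,
                             const arma::cube& dout, int H, int W, int C,
                             int kh, int kw, int stride, int pad) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  mat dout_mat(const_cast<double*>(dout.memptr()), Ho * Wo, Cout, false, true);
  mat dW = cols * dout_mat;                     // (kh*kw*Cin) x Cout
  mat dcols = w * dout_mat.t();                 // (kh*kw*Cin) x (Ho*Wo)
  cube dx = col2im(dcols, H, W, C, kh, kw, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("dx") = dx);
}

// [[Rcpp::export]]
Rcpp::List maxpool_forward_cpp(const arma::cube& x, int k, int stride) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_dim(H, k, stride, 0), Wo = out_dim(W, k, stride, 0);
  cube out(Ho, Wo, C);
  Rcpp::IntegerVector arg(Ho * Wo * C);         // 0-based linear index into x
  for (int c = 0; c < C; ++c) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double best = -datum::inf;
        int best_idx = 0;
        for (int kj = 0; kj < k; ++kj) {
          for (int ki = 0; ki < k; ++ki) {
            const int xi = oi * stride + ki, xj = oj * stride + kj;
            const double v = x(xi, xj, c);
            if (v > best) { best = v; best_idx = xi + H * (xj + W * c); }
          }
        }
        out(oi, oj, c) = best;
        arg[oi + Ho * (oj + Wo * c)] = best_idx;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::cube maxpool_backward_cpp(const arma::cube& dout,
                                const Rcpp::IntegerVector& argmax,
                                int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  const int n = dout.n_elem;
  const double* dptr = dout.memptr();
  for (int t = 0; t < n; ++t) dx(argmax[t]) += dptr[t];
  return dx;
}
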