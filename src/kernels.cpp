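// Compiled kernels for the network's hot inner ops. Each forward has a
// matching backward returning exact gradients; the R-level autodiff tape
// wraps them as primitives. Conventions follow the R code: centered kernel
// offsets (seq_len(k) - (k+1)%/%2), zero padding, column-major cubes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// ---- shared-weight batched multiply: (n,k,B) x (k,m) -> (n,m,B) ----

// [[Rcpp::export]]
arma::cube mat3_mult(const arma::cube& x, const arma::mat& W) {
  cube out(x.n_rows, W.n_cols, x.n_slices);
  for (uword b = 0; b < x.n_slices; ++b) out.slice(b) = x.slice(b) * W;
  return out;
}

// [[Rcpp::export]]
Rcpp::List mat3_mult_bwd(const arma::cube& x, const arma::mat& W,
                         const arma::cube& g) {
  cube dx(size(x));
  mat dW(size(W), fill::zeros);
  for (uword b = 0; b < x.n_slices; ++b) {
    dx.slice(b) = g.slice(b) * W.t();
    dW += x.slice(b).t() * g.slice(b);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW);
}

// ---- temporal convolution over dim 1 of (T,F,B), zero padded ----
// W rows are offset-major: row (o*F + c) weights map c at offset o.

// [[Rcpp::export]]
arma::cube conv_time(const arma::cube& x, const arma::mat& W, int k) {
  int T = x.n_rows, F = x.n_cols, B = x.n_slices, nf = W.n_cols;
  int off0 = -((k + 1) / 2 - 1); // first centred offset
  cube out(T, nf, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    mat& os = out.slice(b);
    for (int o = 0; o < k; ++o) {
      int sh = off0 + o; // out[t] += x[t + sh] * W_block
      int t_lo = std::max(0, -sh), t_hi = std::min(T, T - sh);
      if (t_lo >= t_hi) continue;
      os.rows(t_lo, t_hi - 1) +=
          xs.rows(t_lo + sh, t_hi - 1 + sh) * W.rows(o * F, o * F + F - 1);
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv_time_bwd(const arma::cube& x, const arma::mat& W, int k,
                         const arma::cube& g) {
  int T = x.n_rows, F = x.n_cols, B = x.n_slices;
  int off0 = -((k + 1) / 2 - 1);
  cube dx(size(x), fill::zeros);
  mat dW(size(W), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    const mat& gs = g.slice(b);
    mat& ds = dx.slice(b);
    for (int o = 0; o < k; ++o) {
      int sh = off0 + o;
      int t_lo = std::max(0, -sh), t_hi = std::min(T, T - sh);
      if (t_lo >= t_hi) continue;
      dW.rows(o * F, o * F + F - 1) +=
          xs.rows(t_lo + sh, t_hi - 1 + sh).t() * gs.rows(t_lo, t_hi - 1);
      ds.rows(t_lo + sh, t_hi - 1 + sh) +=
          gs.rows(t_lo, t_hi - 1) * W.rows(o * F, o * F + F - 1).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW);
}

// ---- local spatial convolution with channel-max collapse ----
// x (C,T,B), W (k,nf); z[c,t,f,b] = sum_o x[c+o,t,b] W[o,f] (zero pad),
// out[t,f,b] = max_c z, argmax returned 1-based for the backward pass.

// [[Rcpp::export]]
Rcpp::List conv_spatial_max(const arma::cube& x, const arma::mat& W, int k) {
  int C = x.n_rows, T = x.n_cols, B = x.n_slices, nf = W.n_cols;
  int off0 = -((k + 1) / 2 - 1);
  cube out(T, nf, B);
  Rcpp::IntegerVector arg(T * nf * B);
  mat z(C, T);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    for (int f = 0; f < nf; ++f) {
      z.zeros();
      for (int o = 0; o < k; ++o) {
        int sh = off0 + o;
        int c_lo = std::max(0, -sh), c_hi = std::min(C, C - sh);
        if (c_lo >= c_hi) continue;
        z.rows(c_lo, c_hi - 1) += W(o, f) * xs.rows(c_lo + sh, c_hi - 1 + sh);
      }
      for (int t = 0; t < T; ++t) {
        uword ci;
        double m = z.col(t).max(ci);
        out(t, f, b) = m;
        arg[t + T * (f + nf * b)] = (int)ci + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
Rcpp::List conv_spatial_max_bwd(const arma::cube& x, const arma::mat& W, int k,
                                const arma::cube& g,
                                const Rcpp::IntegerVector& arg) {
  int C = x.n_rows, T = x.n_cols, B = x.n_slices, nf = W.n_cols;
  int off0 = -((k + 1) / 2 - 1);
  cube dx(size(x), fill::zeros);
  mat dW(size(W), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    mat& ds = dx.slice(b);
    for (int f = 0; f < nf; ++f) {
      for (int t = 0; t < T; ++t) {
        double gv = g(t, f, b);
        if (gv == 0.0) continue;
        int cstar = arg[t + T * (f + nf * b)] - 1;
        for (int o = 0; o < k; ++o) {
          int c = cstar + off0 + o;
          if (c < 0 || c >= C) continue;
          ds(c, t) += W(o, f) * gv;
          dW(o, f) += xs(c, t) * gv;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW);
}

// ---- depthwise temporal convolution: x (T,F,B), Wd (F,k) ----

// [[Rcpp::export]]
arma::cube depthwise_time(const arma::cube& x, const arma::mat& Wd) {
  int T = x.n_rows, F = x.n_cols, B = x.n_slices, k = Wd.n_cols;
  int off0 = -((k + 1) / 2 - 1);
  cube out(T, F, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    mat& os = out.slice(b);
    for (int o = 0; o < k; ++o) {
      int sh = off0 + o;
      int t_lo = std::max(0, -sh), t_hi = std::min(T, T - sh);
      if (t_lo >= t_hi) continue;
      mat xm = xs.rows(t_lo + sh, t_hi - 1 + sh);
      os.rows(t_lo, t_hi - 1) += xm.each_row() % Wd.col(o).t();
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List depthwise_time_bwd(const arma::cube& x, const arma::mat& Wd,
                              const arma::cube& g) {
  int T = x.n_rows, B = x.n_slices, k = Wd.n_cols;
  int off0 = -((k + 1) / 2 - 1);
  cube dx(size(x), fill::zeros);
  mat dW(size(Wd), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    const mat& gs = g.slice(b);
    mat& ds = dx.slice(b);
    for (int o = 0; o < k; ++o) {
      int sh = off0 + o;
      int t_lo = std::max(0, -sh), t_hi = std::min(T, T - sh);
      if (t_lo >= t_hi) continue;
      mat gm = gs.rows(t_lo, t_hi - 1);
      mat xm = xs.rows(t_lo + sh, t_hi - 1 + sh);
      ds.rows(t_lo + sh, t_hi - 1 + sh) += gm.each_row() % Wd.col(o).t();
      dW.col(o) += sum(xm % gm, 0).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW);
}

// ---- layer normalization over dim 2 of (T,F,B) with gain/bias ----

// [[Rcpp::export]]
Rcpp::List layernorm_filters(const arma::cube& x, const arma::vec& gamma,
                             const arma::vec& beta, double eps) {
  int T = x.n_rows, F = x.n_cols, B = x.n_slices;
  cube y(T, F, B), yhat(T, F, B);
  mat inv(T, B);
  for (int b = 0; b < B; ++b) {
    const mat& xs = x.slice(b);
    for (int t = 0; t < T; ++t) {
      rowvec r = xs.row(t);
      double mu = mean(r);
      rowvec c = r - mu;
      double v = mean(c % c);
      double iv = 1.0 / std::sqrt(v + eps);
      inv(t, b) = iv;
      rowvec yh = c * iv;
      yhat.slice(b).row(t) = yh;
      y.slice(b).row(t) = yh % gamma.t() + beta.t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("yhat") = yhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export]]
Rcpp::List layernorm_filters_bwd(const arma::cube& yhat, const arma::mat& inv,
                                 const arma::vec& gamma, const arma::cube& g) {
  int T = yhat.n_rows, F = yhat.n_cols, B = yhat.n_slices;
  cube dx(T, F, B);
  vec dgamma(F, fill::zeros), dbeta(F, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& ys = yhat.slice(b);
    const mat& gs = g.slice(b);
    for (int t = 0; t < T; ++t) {
      rowvec gy = gs.row(t) % gamma.t();
      rowvec yh = ys.row(t);
      double m1 = mean(gy);
      double m2 = mean(gy % yh);
      dx.slice(b).row(t) = inv(t, b) * (gy - m1 - yh * m2);
      dgamma += (gs.row(t) % yh).t();
      dbeta += gs.row(t).t();
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
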