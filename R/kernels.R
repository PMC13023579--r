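# Tape primitives backed by the compiled kernels in src/kernels.cpp.

#' Shared-weight batched multiply (compiled): (n,k,B) x (k,m) -> (n,m,B)
#' @rdname ad_ops
#' @export
ad_bmm_shared <- function(t, a, w) {
  av <- a$value
  wv <- w$value
  .ad_push(t, mat3_mult(av, wv), c(a$id, w$id), function(g) {
    r <- mat3_mult_bwd(av, wv, g)
    list(r$dx, r$dW)
  })
}

# temporal convolution over dim 1 of (T,F,B); W is (F*k, nf), offset-major
ad_conv_time <- function(t, x, w, k) {
  xv <- x$value
  wv <- w$value
  .ad_push(t, conv_time(xv, wv, k), c(x$id, w$id), function(g) {
    r <- conv_time_bwd(xv, wv, k, g)
    list(r$dx, r$dW)
  })
}

# local spatial convolution with channel-max collapse; x (C,T,B), W (k,nf)
ad_conv_spatial_max <- function(t, x, w, k) {
  xv <- x$value
  wv <- w$value
  f <- conv_spatial_max(xv, wv, k)
  arg <- f$argmax
  .ad_push(t, f$out, c(x$id, w$id), function(g) {
    r <- conv_spatial_max_bwd(xv, wv, k, g, arg)
    list(r$dx, r$dW)
  })
}

# depthwise temporal convolution; x (T,F,B), Wd (F,k)
ad_depthwise_time <- function(t, x, wd) {
  xv <- x$value
  wv <- wd$value
  .ad_push(t, depthwise_time(xv, wv), c(x$id, wd$id), function(g) {
    r <- depthwise_time_bwd(xv, wv, g)
    list(r$dx, r$dW)
  })
}

# layer normalization over dim 2 of (T,F,B) with gain and bias
ad_layernorm_filters <- function(t, x, g, b, eps = 1e-5) {
  f <- layernorm_filters(x$value, g$value, b$value, eps)
  yhat <- f$yhat
  inv <- f$inv
  gv <- g$value
  .ad_push(t, f$y, c(x$id, g$id, b$id), function(gr) {
    r <- layernorm_filters_bwd(yhat, inv, gv, gr)
    list(r$dx, as.numeric(r$dgamma), as.numeric(r$dbeta))
  })
}
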