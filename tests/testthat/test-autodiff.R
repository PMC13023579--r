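# Finite-difference verification of the autodiff tape: every primitive (and
# the compiled kernels) must agree with central differences.

gradcheck <- function(build, x0, tol = 1e-5) {
  force(x0)
  fn <- function(x) {
    set.seed(123)
    t <- ad_tape()
    p <- ad_param(t, x, "p")
    build(t, p)$value
  }
  set.seed(123)
  t <- ad_tape()
  p <- ad_param(t, x0, "p")
  loss <- build(t, p)
  g <- ad_backward(t, loss)$p
  max(abs(as.numeric(g) - as.numeric(numgrad(fn, x0))))
}

test_that("elementwise, shape and reduction primitives backpropagate exactly", {
  set.seed(42)
  m <- matrix(rnorm(12), 3, 4)
  a3 <- array(rnorm(24), c(2, 3, 4))

  cases <- list(
    mm_relu = list(function(t, p) {
      w <- ad_const(t, matrix(rnorm(8), 4, 2))
      ad_mean_all(t, ad_relu(t, ad_mm(t, p, w)))
    }, m),
    softmax = list(function(t, p) {
      s <- ad_softmax_rows(t, p)
      ad_mean_all(t, ad_mul(t, s, ad_const(t, matrix(seq_len(12), 3, 4))))
    }, m),
    layernorm = list(function(t, p) {
      y <- ad_layernorm_rows(t, p)
      ad_mean_all(t, ad_mul(t, y, ad_const(t, matrix(seq_len(12) / 3, 3, 4))))
    }, m),
    cross_entropy = list(function(t, p) ad_cross_entropy(t, p, c(1L, 3L, 2L)), m),
    aperm_reshape = list(function(t, p) {
      ad_mean_all(t, ad_square(t, ad_reshape(t, ad_aperm(t, p, c(3, 1, 2)), c(4, 6))))
    }, a3),
    gather_pad = list(function(t, p) {
      ad_mean_all(t, ad_leaky_relu(t, ad_gather_rows(t, p, c(0L, 2L, 2L, 1L, 0L, 3L)), 0.2))
    }, m),
    bmm = list(function(t, p) {
      b <- ad_const(t, array(rnorm(24), c(3, 2, 4)))
      ad_mean_all(t, ad_bmm(t, p, b))
    }, a3),
    outer_sum = list(function(t, p) {
      f2 <- ad_const(t, matrix(rnorm(15), 5, 3))
      ad_mean_all(t, ad_square(t, ad_outer_sum(t, p, f2)))
    }, matrix(rnorm(6), 2, 3)),
    cat2 = list(function(t, p) {
      b <- ad_const(t, array(rnorm(16), c(2, 2, 4)))
      ad_mean_all(t, ad_square(t, ad_cat(t, list(p, b), 2)))
    }, a3),
    shift = list(function(t, p) {
      ad_mean_all(t, ad_square(t, ad_shift(t, ad_shift(t, p, 1, -1), 2, 2)))
    }, a3),
    biases = list(function(t, p) {
      x <- ad_add_bias(t, p, ad_const(t, rnorm(3)), 2)
      ad_mean_all(t, ad_square(t, ad_mul_bias(t, x, ad_const(t, rnorm(4)), 3)))
    }, a3),
    bias_param = list(function(t, p) {
      ad_mean_all(t, ad_square(t, ad_add_bias(t, ad_const(t, a3), p, 3)))
    }, rnorm(4)),
    reductions = list(function(t, p) {
      ad_mean_all(t, ad_add(t, ad_rowmax(t, p), ad_rowmean(t, p)))
    }, m),
    colmax = list(function(t, p) ad_mean_all(t, ad_colmax(t, p)), m),
    pow_clamp = list(function(t, p) {
      ad_mean_all(t, ad_pow(t, ad_clamp_min(t, p, 0.1), -0.5))
    }, matrix(abs(rnorm(12)) + 0.5, 3, 4)),
    bmm_blocked = list(function(t, p) {
      y <- ad_const(t, array(rnorm(24), c(3, 2, 4)))
      ad_mean_all(t, ad_square(t, ad_bmm_blocked(t, p, y)))
    }, matrix(rnorm(60), 20, 3))
  )
  for (nm in names(cases)) {
    err <- gradcheck(cases[[nm]][[1]], cases[[nm]][[2]])
    expect_lt(err, 1e-5, label = sprintf("gradcheck '%s' (err=%.3g)", nm, err))
  }
})

test_that("compiled convolution and normalization kernels backpropagate exactly", {
  set.seed(7)
  x3 <- array(rnorm(8 * 6 * 3), c(8, 6, 3)) # (T, F, B)
  xc <- array(rnorm(7 * 8 * 3), c(7, 8, 3)) # (C, T, B)

  cases <- list(
    bmm_shared = list(function(t, p) {
      w <- ad_const(t, matrix(rnorm(12), 6, 2))
      ad_mean_all(t, ad_square(t, ad_bmm_shared(t, p, w)))
    }, x3),
    bmm_shared_w = list(function(t, p) {
      x <- ad_const(t, x3)
      ad_mean_all(t, ad_square(t, ad_bmm_shared(t, x, p)))
    }, matrix(rnorm(12), 6, 2)),
    conv_time = list(function(t, p) {
      w <- ad_const(t, matrix(rnorm(6 * 3 * 4), 18, 4))
      ad_mean_all(t, ad_square(t, emofuse:::ad_conv_time(t, p, w, 3L)))
    }, x3),
    conv_time_w = list(function(t, p) {
      x <- ad_const(t, x3)
      ad_mean_all(t, ad_square(t, emofuse:::ad_conv_time(t, x, p, 5L)))
    }, matrix(rnorm(6 * 5 * 2), 30, 2)),
    conv_spatial_max = list(function(t, p) {
      w <- ad_const(t, matrix(rnorm(3 * 4), 3, 4))
      ad_mean_all(t, ad_square(t, emofuse:::ad_conv_spatial_max(t, p, w, 3L)))
    }, xc),
    conv_spatial_max_w = list(function(t, p) {
      x <- ad_const(t, xc)
      ad_mean_all(t, ad_square(t, emofuse:::ad_conv_spatial_max(t, x, p, 5L)))
    }, matrix(rnorm(5 * 4), 5, 4)),
    depthwise = list(function(t, p) {
      w <- ad_const(t, matrix(rnorm(6 * 5), 6, 5))
      ad_mean_all(t, ad_square(t, emofuse:::ad_depthwise_time(t, p, w)))
    }, x3),
    depthwise_w = list(function(t, p) {
      x <- ad_const(t, x3)
      ad_mean_all(t, ad_square(t, emofuse:::ad_depthwise_time(t, x, p)))
    }, matrix(rnorm(6 * 5), 6, 5)),
    ln_filters = list(function(t, p) {
      g <- ad_const(t, runif(6, 0.5, 1.5))
      b <- ad_const(t, rnorm(6))
      ad_mean_all(t, ad_square(t, emofuse:::ad_layernorm_filters(t, p, g, b)))
    }, x3),
    ln_filters_gb = list(function(t, p) {
      x <- ad_const(t, x3)
      g <- ad_reshape(t, ad_gather_rows(t, ad_reshape(t, p, c(12, 1)), 1:6), 6)
      b <- ad_reshape(t, ad_gather_rows(t, ad_reshape(t, p, c(12, 1)), 7:12), 6)
      ad_mean_all(t, ad_square(t, emofuse:::ad_layernorm_filters(t, x, g, b)))
    }, rnorm(12))
  )
  for (nm in names(cases)) {
    err <- gradcheck(cases[[nm]][[1]], cases[[nm]][[2]])
    expect_lt(err, 1e-5, label = sprintf("gradcheck '%s' (err=%.3g)", nm, err))
  }
})

test_that("compiled kernels match their plain-R reference computations", {
  set.seed(11)
  # conv_time vs explicit shift-and-multiply
  x <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  W <- matrix(rnorm(4 * 3 * 2), 12, 2)
  t <- ad_tape()
  out <- emofuse:::ad_conv_time(t, ad_const(t, x), ad_const(t, W), 3L)$value
  ref <- array(0, c(6, 2, 2))
  for (b in 1:2) {
    for (tt in 1:6) {
      acc <- numeric(2)
      for (oi in 1:3) {
        o <- oi - 2L
        if (tt + o >= 1 && tt + o <= 6) {
          acc <- acc + x[tt + o, , b] %*% W[((oi - 1) * 4 + 1):(oi * 4), ]
        }
      }
      ref[tt, , b] <- acc
    }
  }
  expect_equal(out, ref, tolerance = 1e-12)

  # conv_spatial_max vs explicit conv + max over channels
  xc <- array(rnorm(5 * 6 * 2), c(5, 6, 2))
  Wl <- matrix(rnorm(3 * 4), 3, 4)
  t <- ad_tape()
  out <- emofuse:::ad_conv_spatial_max(t, ad_const(t, xc), ad_const(t, Wl), 3L)$value
  for (b in 1:2) {
    for (f in 1:4) {
      zmat <- matrix(0, 5, 6)
      for (ch in 1:5) {
        for (oi in 1:3) {
          o <- oi - 2L
          if (ch + o >= 1 && ch + o <= 5) {
            zmat[ch, ] <- zmat[ch, ] + xc[ch + o, , b] * Wl[oi, f]
          }
        }
      }
      expect_equal(out[, f, b], apply(zmat, 2, max), tolerance = 1e-12)
    }
  }
})

test_that("the tape accumulates gradients through shared sub-expressions", {
  set.seed(1)
  x0 <- matrix(rnorm(6), 2, 3)
  t <- ad_tape()
  p <- ad_param(t, x0, "p")
  s <- ad_add(t, ad_relu(t, p), ad_scale(t, p, 2)) # p used twice
  g <- ad_backward(t, ad_mean_all(t, s))$p
  expect_equal(g, ((x0 > 0) + 2) / 6, tolerance = 1e-12, ignore_attr = TRUE)
})
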