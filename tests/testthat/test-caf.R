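test_that("view tokenization preserves token positions and shapes", {
  set.seed(1)
  B <- 3L
  f <- array(rnorm(B * 62 * 60), c(B, 62, 60))
  tk <- tokenize_view(f, "eeg_f")
  expect_equal(dim(tk), c(B, 62L, 32L))
  m <- array(rnorm(B * 10 * 9), c(B, 10, 9))
  tk2 <- tokenize_view(m, "eeg_t")
  expect_equal(dim(tk2), c(B, 9L, 32L))
  expect_error(tokenize_view(m, "nope"), "unknown view tag")

  # zero features with zero bias give zero tokens (linearity)
  cfg <- caf_config()
  params <- list(
    caf_proj_eeg_f_W = matrix(rnorm(60 * 32), 60, 32),
    caf_proj_eeg_f_b = rep(0, 32)
  )
  z <- tokenize_view(array(0, c(2, 62, 60)), "eeg_f", cfg, params)
  expect_equal(max(abs(z)), 0)
})

test_that("cross-attention rows normalize and a single key degenerates to its value", {
  set.seed(2)
  B <- 2L
  h1 <- array(rnorm(B * 4 * 32), c(B, 4, 32))
  h2 <- array(rnorm(B * 6 * 32), c(B, 6, 32))
  res <- cross_attend(h1, h2, return_attention = TRUE)
  for (a in res$attention) {
    sums <- apply(a, c(1, 3), sum)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  }
  # attention mass over keys sums to the number of query tokens
  mass <- apply(res$attention[[1]], 3, sum)
  expect_equal(mass, rep(6, B), tolerance = 1e-6)

  # single token in h1: every query receives exactly V1
  h1s <- array(rnorm(B * 1 * 32), c(B, 1, 32))
  params <- stats::setNames(
    lapply(1:6, function(i) diag(32)), c("q1", "k1", "v1", "q2", "k2", "v2")
  )
  res1 <- cross_attend(h1s, h2, params = params)
  expect_equal(res1$h1_attended, h1s[, 1, ], tolerance = 1e-10)
})

test_that("two-token cross-attention matches the brute-force oracle", {
  set.seed(3)
  h1 <- array(rnorm(1 * 2 * 32), c(1, 2, 32))
  h2 <- array(rnorm(1 * 3 * 32), c(1, 3, 32))
  params <- stats::setNames(
    lapply(1:6, function(i) matrix(rnorm(32 * 32, sd = 0.3), 32, 32)),
    c("q1", "k1", "v1", "q2", "k2", "v2")
  )
  res <- cross_attend(h1, h2, params = params)
  ref1 <- attention_oracle(
    h1[1, , ], h2[1, , ], params$q2, params$k1, params$v1,
    scale = sqrt(32)
  )
  ref2 <- attention_oracle(
    h2[1, , ], h1[1, , ], params$q1, params$k2, params$v2,
    scale = sqrt(32)
  )
  expect_equal(drop(res$h1_attended), ref1, tolerance = 1e-6)
  expect_equal(drop(res$h2_attended), ref2, tolerance = 1e-6)

  # literal (linear) scaling variant divides by D instead of sqrt(D)
  res_lin <- cross_attend(h1, h2, caf_config(scale = "linear"), params = params)
  ref_lin <- attention_oracle(h1[1, , ], h2[1, , ], params$q2, params$k1,
    params$v1,
    scale = 32
  )
  expect_equal(drop(res_lin$h1_attended), ref_lin, tolerance = 1e-6)
})

test_that("three-view fusion emits six blocks in a fixed order", {
  set.seed(4)
  B <- 2L
  tokens <- list(
    eeg_f = array(rnorm(B * 62 * 32), c(B, 62, 32)),
    eeg_t = array(rnorm(B * 9 * 32), c(B, 9, 32)),
    fnirs_t = array(rnorm(B * 9 * 32), c(B, 9, 32))
  )
  fused <- caf_fuse(tokens)
  expect_equal(dim(fused), c(B, 6L * 32L))
  # the pair order is canonical: permuting the input list changes nothing
  fused2 <- caf_fuse(tokens[c(3, 1, 2)])
  expect_equal(fused2, fused, tolerance = 1e-12)
  # two views: one pair, two attended outputs
  expect_equal(dim(caf_fuse(tokens[1:2])), c(B, 2L * 32L))
  expect_error(caf_fuse(tokens[1]), "at least two")
})

test_that("identical inputs with mirrored weights give equal attended outputs", {
  set.seed(5)
  h <- array(rnorm(2 * 5 * 32), c(2, 5, 32))
  W <- matrix(rnorm(32 * 32, sd = 0.3), 32, 32)
  params <- list(q1 = W, k1 = W * 0.5, v1 = W * 0.2, q2 = W, k2 = W * 0.5, v2 = W * 0.2)
  res <- cross_attend(h, h, params = params)
  expect_equal(res$h1_attended, res$h2_attended, tolerance = 1e-10)
})

test_that("all fusion paths receive gradient", {
  set.seed(6)
  mo <- tiny_montage()
  B <- 4L
  batch <- list(
    eeg_de = array(rnorm(62 * 5 * B), c(62, 5, B)),
    eeg_psd = array(rnorm(62 * 5 * B), c(62, 5, B)),
    eeg_time = array(rnorm(22 * 62 * B), c(22, 62, B)),
    fnirs_time = array(rnorm(22 * 18 * B), c(22, 18, B))
  )
  set.seed(7)
  model <- build_model(model_variant("fgcn_tcnn_caf"), mo)
  t <- ad_tape()
  logits <- emofuse:::.model_forward_node(t, model, batch, training = FALSE)
  g <- ad_backward(t, ad_cross_entropy(t, logits, c(1L, 2L, 3L, 4L)))
  pairs <- c("eeg_f.eeg_t", "eeg_f.fnirs_t", "eeg_t.fnirs_t")
  for (pr in pairs) {
    for (s in c("q1", "v1", "q2", "v2")) {
      nm <- paste0("caf_", pr, "_", s)
      expect_gt(max(abs(g[[nm]])), 0, label = nm)
    }
  }
  # finite-difference spot check on one weight per pair
  lossfn <- function(m) {
    t <- ad_tape()
    lg <- emofuse:::.model_forward_node(t, m, batch, training = FALSE)
    ad_cross_entropy(t, lg, c(1L, 2L, 3L, 4L))$value
  }
  for (pr in pairs) {
    nm <- paste0("caf_", pr, "_v1")
    i <- 17L
    e <- 1e-5
    mp <- model
    mp$params[[nm]][i] <- mp$params[[nm]][i] + e
    mm <- model
    mm$params[[nm]][i] <- mm$params[[nm]][i] - e
    fd <- (lossfn(mp) - lossfn(mm)) / (2 * e)
    expect_equal(as.numeric(g[[nm]])[i], fd, tolerance = 1e-4)
  }
})
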