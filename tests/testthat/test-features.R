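test_that("windowing follows floor(duration / window) per trial", {
  # study-scale trial table: 4694 s of usable signal -> 2347 windows
  cfg <- sim_config()
  trials <- data.frame(
    onset_s = cumsum(c(0, cfg$trial_duration_s))[1:60],
    duration_s = cfg$trial_duration_s,
    label = rep(cfg$classes, length.out = 60)
  )
  ws <- segment_windows(trials, 2)
  expect_equal(nrow(ws), 2347L)

  expect_equal(nrow(segment_windows(
    data.frame(onset_s = 0, duration_s = 2, label = "happy"), 2
  )), 1L)
  # 5 s trial: two windows, the trailing second discarded
  ws5 <- segment_windows(
    data.frame(onset_s = 0, duration_s = 5, label = "sad"), 2
  )
  expect_equal(nrow(ws5), 2L)
  expect_equal(ws5$start_s, c(0, 2))
})

test_that("window count identity holds for arbitrary trial tables", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    durs <- round(stats::runif(n, 2, 30), 1)
    trials <- data.frame(
      onset_s = cumsum(c(0, durs))[1:n], duration_s = durs,
      label = sample(c("a", "b"), n, replace = TRUE)
    )
    ws <- segment_windows(trials, 2)
    expect_equal(nrow(ws), sum(floor(durs / 2 + 1e-9)))
    # windows are contiguous and non-overlapping within each trial
    for (i in seq_len(n)) {
      st <- ws$start_s[ws$trial == i]
      if (length(st) > 1) expect_equal(diff(st), rep(2, length(st) - 1))
    }
  }
})

test_that("resampling preserves length contract and sinusoid amplitude", {
  x <- matrix(sin(2 * pi * 10 * seq_len(400) / 200), 1) # 2 s at 200 Hz
  y <- resample_series(x, 200, 11)
  expect_equal(ncol(y), 22L)

  x2 <- matrix(rnorm(100), 2, 50)
  expect_equal(resample_series(x2, 11, 11), x2)

  # 1 Hz sinusoid survives 200 -> 11 Hz with amplitude within 2%
  tt <- seq(1 / 200, 20, by = 1 / 200)
  s <- matrix(sin(2 * pi * 1 * tt), 1)
  y <- resample_series(s, 200, 11)
  core <- y[1, 12:(ncol(y) - 11)] # away from filter edges
  expect_lt(abs(max(core) - 1), 0.02)
  expect_error(resample_series(s, 200, 0), "positive")
})

test_that("band power concentrates where the signal lives", {
  fs <- 200
  tt <- seq_len(400) / fs
  alpha_sine <- matrix(sin(2 * pi * 10 * tt), 1)
  p <- compute_psd(alpha_sine, fs)
  expect_gt(p[1, "alpha"] / sum(p), 0.95)

  # white noise: band powers proportional to bandwidth within 20%
  set.seed(4)
  acc <- matrix(0, 1, 5)
  for (i in 1:100) acc <- acc + compute_psd(matrix(rnorm(400), 1), fs)
  bw <- band_set()$hi - band_set()$lo
  ratio <- (acc / sum(acc)) / (bw / sum(bw))
  expect_true(all(ratio > 0.8 & ratio < 1.2))

  expect_warning(pz <- compute_psd(matrix(0, 2, 400), fs), "zero-variance")
  expect_true(all(pz == 1e-12))
})

test_that("differential entropy follows the Gaussian closed form", {
  expect_equal(de_gaussian(1 / (2 * pi * exp(1))), 0)
  expect_equal(de_gaussian(1), 0.5 * log(2 * pi * exp(1)), tolerance = 1e-12)
  expect_equal(de_gaussian(1), 1.41894, tolerance = 1e-5)

  # doubling the amplitude raises DE by exactly ln 2, through the filter
  set.seed(8)
  w <- matrix(rnorm(3 * 400), 3, 400)
  d1 <- compute_de(w, 200)
  d2 <- compute_de(2 * w, 200)
  expect_equal(d2 - d1, matrix(log(2), 3, 5), tolerance = 1e-9, ignore_attr = TRUE)

  # DE and PSD stay mutually consistent on random windows
  ps <- compute_psd(w, 200)
  expect_equal(d1, de_gaussian(ps), ignore_attr = TRUE)
})

test_that("view tensors share windowing, labels and shapes", {
  v <- tiny_views()
  W <- length(v$labels)
  expect_equal(dim(v$eeg_de), c(W, 62L, 5L))
  expect_equal(dim(v$eeg_psd), c(W, 62L, 5L))
  expect_equal(dim(v$eeg_time), c(W, 62L, 22L))
  expect_equal(dim(v$fnirs_time), c(W, 18L, 22L))
  expect_true(all(v$eeg_psd > 0))
  expect_false(anyNA(v$eeg_de))
  expect_false(any(!is.finite(v$eeg_time)))

  # single 2 s trial: one window, all views populated
  cfg1 <- sim_config(n_trials_per_class = 1L, trial_duration_s = 2, seed = 5L)
  v1 <- build_views(simulate_session(cfg1, tiny_montage(), 1L))
  expect_equal(dim(v1$eeg_de)[1], 4L) # 4 trials (one per class), 1 window each
  expect_true(all(abs(v1$fnirs_time) < Inf))
})

test_that("permuting trial labels permutes window labels identically", {
  s <- tiny_session()
  perm <- c(3L, 1L, 4L, 2L, 7L, 5L, 8L, 6L)
  s2 <- s
  s2$trials$label <- s$trials$label[perm]
  v1 <- build_views(s)
  v2 <- build_views(s2)
  expect_equal(
    as.character(v2$labels),
    as.character(factor(s$trials$label[perm][v1$trial], levels = s$classes))
  )
  expect_equal(v1$eeg_time, v2$eeg_time) # signals untouched
})

test_that("normalization z-scores channels and log-transforms band powers", {
  v <- normalize_views(tiny_views())
  expect_true(isTRUE(v$normalized))
  m <- apply(v$eeg_de, c(2, 3), mean)
  expect_lt(max(abs(m)), 1e-10)
  s <- apply(v$eeg_psd, c(2, 3), stats::sd)
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-10)
  expect_lt(max(abs(apply(v$eeg_time, 2, mean))), 1e-10)
  # idempotent
  expect_identical(normalize_views(v), v)
})
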