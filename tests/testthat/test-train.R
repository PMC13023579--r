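test_that("classifier head yields normalized probabilities", {
  set.seed(1)
  fused <- matrix(rnorm(12), 3, 4)
  W1 <- matrix(rnorm(4 * 8), 4, 8)
  b1 <- rnorm(8)
  W2 <- matrix(rnorm(8 * 4), 8, 4)
  b2 <- rnorm(4)
  r <- classify(fused, W1, b1, W2, b2)
  expect_equal(rowSums(r$probs), rep(1, 3), tolerance = 1e-6)
  # zero weights: uniform over the four classes
  r0 <- classify(fused, W1 * 0, b1 * 0, W2 * 0, b2 * 0)
  expect_equal(r0$probs, matrix(0.25, 3, 4), tolerance = 1e-12)
  # hand-computed toy head (positive pre-activations keep LeakyReLU linear)
  f <- matrix(c(1, 2), 1, 2)
  W1t <- matrix(c(1, 0, 0, 1), 2, 2)
  W2t <- matrix(c(1, 2, 3, 4), 2, 2)
  rt <- classify(f, W1t, c(0, 0), W2t, c(0.5, -0.5))
  expect_equal(rt$logits, matrix(c(1 * 1 + 2 * 2 + 0.5, 1 * 3 + 2 * 4 - 0.5), 1, 2))
})

test_that("metrics follow the macro-average definitions", {
  r <- evaluate_predictions(1:4, factor(letters[1:4]))
  expect_equal(r$accuracy, 100)
  expect_equal(r$macro_f1, 100)
  expect_equal(unname(diag(r$confusion)), rep(1L, 4))

  # printed toy confusion [[3,1],[1,3]]
  truth <- factor(rep(c("a", "b"), each = 4))
  pred <- c(1, 1, 1, 2, 1, 2, 2, 2)
  r2 <- evaluate_predictions(pred, truth)
  expect_equal(unclass(r2$confusion), matrix(c(3L, 1L, 1L, 3L), 2, 2),
    ignore_attr = TRUE
  )
  expect_equal(r2$accuracy, 75)
  expect_equal(r2$macro_f1, 75)

  # all-one-class predictions on balanced 4-class labels
  truth4 <- factor(rep(letters[1:4], each = 5))
  r3 <- evaluate_predictions(rep(1L, 20), truth4)
  expect_equal(r3$accuracy, 25)
  expect_equal(r3$macro_recall, 25)
  expect_equal(r3$macro_precision, 25 / 4) # zero-division guarded as 0
  expect_error(evaluate_predictions(integer(0), factor(character(0))), "empty")
  expect_error(evaluate_predictions(1:3, truth4), "length mismatch")
})

test_that("stratified window folds have balanced sizes", {
  labels <- factor(rep(c("a", "b", "c", "d"), length.out = 2347))
  fold <- make_folds(labels, seq_along(labels), k = 5, policy = "window", seed = 1)
  expect_equal(sort(as.integer(table(fold)), decreasing = TRUE), c(470L, 470L, 469L, 469L, 469L))
  # per-class balance within one window
  perclass <- table(labels, fold)
  expect_lte(max(perclass) - min(perclass), 1)
})

test_that("trial folds keep whole trials together and stratify by class", {
  v <- tiny_views() # 8 trials x 5 windows
  fold <- make_folds(v$labels, v$trial, k = 2, policy = "trial", seed = 3)
  for (tr in unique(v$trial)) {
    expect_length(unique(fold[v$trial == tr]), 1L)
  }
  expect_true(all(table(v$labels, fold) > 0))
  # a class with fewer trials than folds cannot be stratified
  expect_error(
    make_folds(v$labels, v$trial, k = 5, policy = "trial", seed = 1),
    "stratification failure"
  )
})

test_that("training is reproducible: same seed, same folds, same first-epoch loss", {
  v <- tiny_views()
  va <- model_variant("fgcn_tcnn_caf", views = "fnirs_t")
  tc <- train_config(epochs = 2L, folds = 2L, batch_size = 32L, seed = 11L)
  cv1 <- cross_validate(v, va, tc)
  cv2 <- cross_validate(v, va, tc)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_identical(cv1$loss_curves, cv2$loss_curves)
  expect_identical(cv1$summary, cv2$summary)
  tc2 <- train_config(epochs = 2L, folds = 2L, batch_size = 32L, seed = 12L)
  cv3 <- cross_validate(v, va, tc2)
  expect_false(identical(cv1$loss_curves[[1]][1], cv3$loss_curves[[1]][1]))
})

test_that("the ablation grid enumerates the listed view combinations", {
  grid <- default_ablation_grid()
  expect_length(grid, 8L)
  # single-view variants bypass fusion
  single <- Filter(function(v) length(v$views) == 1L, grid)
  expect_true(all(!vapply(single, `[[`, TRUE, "uses_caf")))
  multi <- Filter(function(v) length(v$views) >= 2L, grid)
  expect_true(all(vapply(multi, `[[`, TRUE, "uses_caf")))
  # order flag is the only difference between convolution-order variants
  v1 <- model_variant("fgcn_tcnn_caf", order = "sfts")
  v2 <- model_variant("fgcn_tcnn_caf", order = "tfss")
  expect_equal(v1$views, v2$views)
  expect_false(v1$order == v2$order)
  # graph-only variants require the frequency view
  expect_error(model_variant("fgcn", views = "eeg_t"), "require")
})

test_that("ablation grid and delta sweep produce one result row per setting", {
  v <- tiny_views()
  mo <- tiny_montage()
  tc <- train_config(epochs = 2L, folds = 2L, batch_size = 32L, seed = 5L)
  grid <- list(
    model_variant("fgcn_tcnn_caf", views = "fnirs_t", label = "fNIRS-T"),
    model_variant("fgcn_tcnn_caf", views = c("eeg_t", "fnirs_t"), label = "EEG-T+fNIRS-T")
  )
  res <- run_ablation_grid(v, grid, tc, mo)
  expect_equal(nrow(res), 2L)
  expect_equal(res$variant, c("fNIRS-T", "EEG-T+fNIRS-T"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  expect_length(attr(res, "cv"), 2L)

  sw <- sweep_delta(v, mo, deltas = c(3, 9), cfg = tc)
  expect_equal(sw$delta, c(3, 9))
  expect_true(all(is.finite(sw$accuracy)))
})

test_that("spatial-first ordering does not trail temporal-first on spatially coded views", {
  # classes carried by a stationary spatial amplitude pattern + temporal noise
  make_views <- function(seed) {
    set.seed(seed)
    W <- 90L
    lab <- rep(1:2, length.out = W)
    x <- array(stats::rnorm(W * 18 * 22, sd = 1), c(W, 18, 22))
    pat1 <- sin(seq(0, pi, length.out = 18))
    pat2 <- rev(pat1)
    for (w in seq_len(W)) {
      x[w, , ] <- x[w, , ] + 3 * (if (lab[w] == 1) pat1 else pat2)
    }
    structure(
      list(
        eeg_de = array(0, c(W, 62, 5)), eeg_psd = array(0, c(W, 62, 5)),
        eeg_time = array(0, c(W, 62, 22)), fnirs_time = x,
        labels = factor(c("a", "b"))[lab], trial = seq_len(W),
        classes = c("a", "b"), normalized = TRUE
      ),
      class = "view_tensors"
    )
  }
  acc <- function(order, seed) {
    d <- make_views(seed)
    tr_idx <- which(seq_len(90L) %% 3 != 0)
    te_idx <- setdiff(seq_len(90L), tr_idx)
    set.seed(seed)
    m <- build_model(
      model_variant("fgcn_tcnn_caf", views = "fnirs_t", order = order),
      n_classes = 2L
    )
    m <- train_model(m, d, tr_idx, train_config(epochs = 15L, batch_size = 64L, seed = seed))
    mean(predict_model(m, d, te_idx)$pred == as.integer(d$labels[te_idx]))
  }
  sfts <- mean(vapply(1:3, function(s) acc("sfts", s), 0))
  tfss <- mean(vapply(1:3, function(s) acc("tfss", s), 0))
  expect_gte(sfts, tfss)
})

test_that("label shuffling permutes labels and nothing else", {
  v <- tiny_views()
  vs <- shuffle_labels(v, seed = 2)
  expect_equal(sort(as.integer(table(vs$labels))), sort(as.integer(table(v$labels))))
  expect_false(all(vs$labels == v$labels))
  expect_identical(vs$eeg_de, v$eeg_de)
})
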