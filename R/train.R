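# Training loop, stratified cross-validation, metrics, ablation grid.

#' Training configuration
#'
#' Defaults follow the study protocol: AdamW at learning rate 0.001, batch
#' size 128, 100 epochs, cross-entropy loss, 5 folds.
#'
#' @param lr learning rate
#' @param batch_size minibatch size
#' @param epochs training epochs (no early stopping)
#' @param folds number of cross-validation folds
#' @param seed controls fold assignment, weight init, shuffling and dropout
#' @param split `"trial"` assigns whole trials to folds (no window leakage
#'   between train and test within a trial; default) or `"window"`
#' @param weight_decay AdamW decoupled decay
#' @return object of class `train_config`
#' @export
train_config <- function(lr = 0.001, batch_size = 128L, epochs = 100L,
                         folds = 5L, seed = 1L,
                         split = c("trial", "window"),
                         weight_decay = 0.01) {
  stopifnot(folds >= 2L, lr > 0)
  structure(
    list(
      lr = lr, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), folds = as.integer(folds),
      seed = as.integer(seed), split = match.arg(split),
      weight_decay = weight_decay
    ),
    class = "train_config"
  )
}

#' Stratified fold assignment
#'
#' Units (trials or windows) are shuffled within class and dealt round-robin
#' with a fold pointer carried across classes, so fold sizes differ by at
#' most one overall and per class. Aborts if any class would miss a fold.
#'
#' @param labels factor of window labels
#' @param trial integer trial index per window
#' @param k number of folds
#' @param policy `"trial"` or `"window"`
#' @param seed RNG seed
#' @return integer fold id (1..k) per window
#' @export
make_folds <- function(labels, trial, k = 5L, policy = c("trial", "window"),
                       seed = 1L) {
  policy <- match.arg(policy)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  fold <- integer(length(labels))
  ptr <- 0L
  if (policy == "window") {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      for (i in idx) {
        fold[i] <- ptr %% k + 1L
        ptr <- ptr + 1L
      }
    }
  } else {
    tr_lab <- labels[!duplicated(trial)]
    tr_id <- trial[!duplicated(trial)]
    tfold <- integer(length(tr_id))
    for (cl in levels(labels)) {
      idx <- sample(which(tr_lab == cl))
      for (i in idx) {
        tfold[i] <- ptr %% k + 1L
        ptr <- ptr + 1L
      }
    }
    fold <- tfold[match(trial, tr_id)]
  }
  tab <- table(labels, fold)
  if (any(tab == 0)) {
    stop("stratification failure: some class is absent from a fold")
  }
  fold
}

#' Train a model on a subset of windows
#'
#' Minibatch AdamW on the cross-entropy loss; all randomness (shuffling,
#' dropout) comes from the current RNG state.
#'
#' @param model an [build_model()] object
#' @param views normalized view tensors
#' @param idx training window indices
#' @param cfg a [train_config()]
#' @param verbose print per-epoch loss
#' @return the model with trained parameters and a `loss_curve` field
#' @export
train_model <- function(model, views, idx, cfg, verbose = FALSE) {
  labels <- as.integer(views$labels)
  opt <- adamw_init(model$params)
  frozen <- if (!model$learn_adjacency && "fgcn_A" %in% names(model$params)) {
    "fgcn_A"
  } else {
    character(0)
  }
  curve <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tot <- 0
    for (b in batches) {
      t <- ad_tape()
      logits <- .model_forward_node(
        t, model, .batch_views(views, b),
        training = TRUE
      )
      loss <- ad_cross_entropy(t, logits, labels[b])
      grads <- ad_backward(t, loss)
      step <- adamw_step(opt, model$params, grads,
        lr = cfg$lr, weight_decay = cfg$weight_decay, frozen = frozen
      )
      model$params <- step$params
      opt <- step$state
      tot <- tot + loss$value * length(b)
    }
    curve[ep] <- tot / length(idx)
    if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, curve[ep]))
  }
  model$loss_curve <- curve
  model
}

#' Confusion matrix and macro-averaged metrics
#'
#' @param pred integer or factor predictions
#' @param truth factor (or integer) ground truth
#' @param classes class labels (defaults to levels of `truth`)
#' @return object of class `fold_result`: `confusion` (rows = truth),
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `per_class_accuracy` (all in percent), `n`
#' @export
evaluate_predictions <- function(pred, truth, classes = NULL) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) == 0L) stop("empty input")
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth) else sort(unique(truth))
  }
  truth_i <- if (is.factor(truth)) as.integer(truth) else match(truth, classes)
  pred_i <- if (is.factor(pred)) as.integer(pred) else as.integer(pred)
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(truth = classes, pred = classes))
  for (i in seq_along(truth_i)) {
    cm[truth_i[i], pred_i[i]] <- cm[truth_i[i], pred_i[i]] + 1L
  }
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(
    list(
      confusion = cm,
      accuracy = 100 * sum(tp) / sum(cm),
      macro_precision = 100 * mean(prec),
      macro_recall = 100 * mean(rec),
      macro_f1 = 100 * mean(f1),
      per_class_accuracy = 100 * rec,
      n = sum(cm)
    ),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result> n=%d acc=%.2f%% macroP=%.2f%% macroR=%.2f%% macroF1=%.2f%%\n",
    x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1
  ))
  invisible(x)
}

#' Within-subject stratified k-fold cross-validation
#'
#' Splits the subject's windows into stratified folds (by trial, by
#' default, so windows of one trial never straddle the train/test boundary),
#' trains one model per fold and evaluates on the held-out fold.
#' Deterministic given `cfg$seed`.
#'
#' @param views [build_views()] tensors (normalized automatically)
#' @param variant a [model_variant()]
#' @param cfg a [train_config()]
#' @param montage montage for the adjacency prior (frequency view only)
#' @param verbose print progress
#' @return object of class `cv_result`: per-fold results, summary data frame
#'   (mean and sd per metric), loss curves, fold assignment
#' @export
cross_validate <- function(views, variant, cfg = train_config(),
                           montage = NULL, verbose = FALSE) {
  views <- normalize_views(views)
  fold <- make_folds(views$labels, views$trial,
    k = cfg$folds,
    policy = cfg$split, seed = cfg$seed
  )
  results <- vector("list", cfg$folds)
  curves <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    old <- .Random.seed_get()
    set.seed(cfg$seed * 1000L + f)
    model <- build_model(variant, montage)
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- train_model(model, views, tr, cfg)
    .Random.seed_set(old)
    pr <- predict_model(model, views, te)
    results[[f]] <- evaluate_predictions(
      pr$pred, views$labels[te],
      classes = levels(views$labels)
    )
    results[[f]]$adjacency_shift <-
      if (model$learn_adjacency) {
        A0 <- init_adjacency(montage, variant$delta)$A
        sqrt(sum((model$params$fgcn_A - A0)^2))
      } else {
        NA_real_
      }
    curves[[f]] <- model$loss_curve
    if (verbose) {
      message(sprintf(
        "[%s] fold %d/%d acc %.2f%%",
        variant$label, f, cfg$folds, results[[f]]$accuracy
      ))
    }
  }
  metrics <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  vals <- sapply(results, function(r) unlist(r[metrics]))
  structure(
    list(
      folds = results,
      summary = data.frame(
        metric = metrics,
        mean = rowMeans(vals),
        sd = apply(vals, 1, stats::sd)
      ),
      loss_curves = curves,
      fold_assignment = fold,
      variant = variant,
      config = cfg
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  cat(sprintf(
    "<cv_result> %s: accuracy %.2f (%.2f) %% over %d folds\n",
    x$variant$label, acc$mean, acc$sd, length(x$folds)
  ))
  invisible(x)
}

#' Mean accuracy of a cross-validation result
#' @param cv a `cv_result`
#' @export
cv_accuracy <- function(cv) {
  cv$summary$mean[cv$summary$metric == "accuracy"]
}

#' The view-combination ablation grid
#'
#' The eight rows compare single views, dual-modality combinations and the
#' full three-view fusion (the modality-level EEG row shares its views with
#' the two-view EEG row but is kept as its own listed entry).
#'
#' @param order TCNN convolution order applied to every row
#' @param delta adjacency scaling factor
#' @return list of [model_variant()]s
#' @export
default_ablation_grid <- function(order = "sfts", delta = 9) {
  v <- function(views, label, model = "fgcn_tcnn_caf") {
    if (length(views) == 1L && identical(views, "eeg_f")) model <- "fgcn"
    model_variant(model, views = views, order = order, delta = delta, label = label)
  }
  list(
    v("eeg_t", "EEG-T"),
    v("eeg_f", "EEG-F"),
    v(c("eeg_f", "eeg_t"), "EEG-F+EEG-T"),
    v("fnirs_t", "fNIRS-T"),
    v(c("eeg_f", "eeg_t"), "EEG (both views)"),
    v(c("eeg_t", "fnirs_t"), "EEG-T+fNIRS-T"),
    v(c("eeg_f", "fnirs_t"), "EEG-F+fNIRS-T"),
    v(c("eeg_f", "eeg_t", "fnirs_t"), "EEG-F+EEG-T+fNIRS-T")
  )
}

#' Run a grid of ablation variants
#'
#' @param views view tensors
#' @param grid list of [model_variant()]s
#' @param cfg a [train_config()]
#' @param montage montage for variants with the frequency view
#' @param verbose print progress
#' @return data frame with one row per variant: label, mean and sd of each
#'   metric; the per-variant `cv_result`s are attached as attribute `cv`
#' @export
run_ablation_grid <- function(views, grid, cfg = train_config(),
                              montage = NULL, verbose = FALSE) {
  cvs <- lapply(grid, function(va) {
    cross_validate(views, va, cfg, montage, verbose = verbose)
  })
  rows <- lapply(cvs, function(cv) {
    s <- cv$summary
    data.frame(
      variant = cv$variant$label,
      model = cv$variant$model,
      views = paste(cv$variant$views, collapse = "+"),
      order = cv$variant$order,
      accuracy = s$mean[s$metric == "accuracy"],
      accuracy_sd = s$sd[s$metric == "accuracy"],
      macro_f1 = s$mean[s$metric == "macro_f1"],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "cv") <- cvs
  out
}

#' Sensitivity sweep over the adjacency scaling factor
#'
#' Cross-validates the frequency-graph variant for each candidate value of
#' the distance-prior scaling factor.
#'
#' @param views view tensors
#' @param montage montage
#' @param deltas candidate scaling factors
#' @param cfg a [train_config()]
#' @param verbose print progress
#' @return data frame with `delta`, `accuracy`, `accuracy_sd`
#' @export
sweep_delta <- function(views, montage, deltas = c(1, 3, 6, 9, 12, 15),
                        cfg = train_config(), verbose = FALSE) {
  rows <- lapply(deltas, function(d) {
    va <- model_variant("fgcn",
      views = "eeg_f", delta = d,
      label = sprintf("FGCN delta=%g", d)
    )
    cv <- cross_validate(views, va, cfg, montage, verbose = verbose)
    s <- cv$summary
    data.frame(
      delta = d,
      accuracy = s$mean[s$metric == "accuracy"],
      accuracy_sd = s$sd[s$metric == "accuracy"]
    )
  })
  do.call(rbind, rows)
}

#' Permute window labels (chance-level control)
#'
#' @param views view tensors
#' @param seed RNG seed
#' @return views with labels randomly permuted
#' @export
shuffle_labels <- function(views, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  views$labels <- views$labels[sample(length(views$labels))]
  views
}
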