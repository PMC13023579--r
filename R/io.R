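# Session / view / result I/O: plain CSV matrices with JSON sidecars, so
# every artifact is portable and diffable.

#' Write a session to a directory
#'
#' Layout: `eeg.csv`, `fnirs_hbo.csv`, `fnirs_hbr.csv` (time in rows,
#' channels in columns, header = channel names) and `meta.json` (subject id,
#' sampling rates, classes, trial table).
#'
#' @param session a `raw_session`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    data.table::fwrite(data.table::as.data.table(t(m)), file.path(dir, f))
  }
  wr(session$eeg, "eeg.csv")
  wr(session$fnirs_hbo, "fnirs_hbo.csv")
  wr(session$fnirs_hbr, "fnirs_hbr.csv")
  meta <- list(
    subject_id = session$subject_id,
    eeg_fs = session$eeg_fs, fnirs_fs = session$fnirs_fs,
    classes = session$classes,
    trials = session$trials
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(dir)
}

#' Read a session written by [write_session()]
#' @param dir session directory
#' @return a `raw_session`
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rd <- function(f) {
    m <- t(as.matrix(data.table::fread(file.path(dir, f))))
    m
  }
  structure(
    list(
      subject_id = as.integer(meta$subject_id),
      eeg = rd("eeg.csv"),
      fnirs_hbo = rd("fnirs_hbo.csv"),
      fnirs_hbr = rd("fnirs_hbr.csv"),
      eeg_fs = meta$eeg_fs, fnirs_fs = meta$fnirs_fs,
      trials = as.data.frame(meta$trials),
      classes = meta$classes
    ),
    class = "raw_session"
  )
}

#' Write view tensors to a directory
#'
#' Each view is stored as a CSV of `W` rows with the channel/feature axes
#' flattened; `manifest.json` records dimensions, labels, trial indices and
#' window starts for lossless round-tripping.
#'
#' @param views a [build_views()] object
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_views <- function(views, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- list()
  for (nm in c("eeg_de", "eeg_psd", "eeg_time", "fnirs_time")) {
    a <- views[[nm]]
    dims[[nm]] <- dim(a)
    m <- matrix(a, nrow = dim(a)[1])
    data.table::fwrite(data.table::as.data.table(m), file.path(dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    dims = dims,
    labels = as.character(views$labels),
    classes = views$classes,
    trial = views$trial,
    window_start_s = views$window_start_s,
    win_s = views$win_s,
    subject_id = views$subject_id,
    normalized = isTRUE(views$normalized)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read view tensors written by [write_views()]
#' @param dir views directory
#' @return a `view_tensors` object
#' @export
read_views <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  out <- list()
  for (nm in c("eeg_de", "eeg_psd", "eeg_time", "fnirs_time")) {
    m <- as.matrix(data.table::fread(file.path(dir, paste0(nm, ".csv"))))
    out[[nm]] <- array(m, man$dims[[nm]])
  }
  out$labels <- factor(man$labels, levels = man$classes)
  out$classes <- man$classes
  out$trial <- man$trial
  out$window_start_s <- man$window_start_s
  out$win_s <- man$win_s
  out$subject_id <- man$subject_id
  out$normalized <- isTRUE(man$normalized)
  class(out) <- "view_tensors"
  out
}

#' Write cross-validation results
#'
#' Produces `metrics.csv` (tidy: variant, fold, metric, value),
#' `summary.json` (per-metric mean and sd) and `loss_curves.csv`.
#'
#' @param cv a `cv_result`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_cv_results <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- c("accuracy", "macro_precision", "macro_recall", "macro_f1")
  rows <- do.call(rbind, lapply(seq_along(cv$folds), function(f) {
    data.frame(
      variant = cv$variant$label, fold = f, metric = metrics,
      value = unlist(cv$folds[[f]][metrics]), row.names = NULL
    )
  }))
  data.table::fwrite(rows, file.path(dir, "metrics.csv"))
  jsonlite::write_json(
    list(
      variant = cv$variant$label,
      summary = cv$summary,
      confusion = lapply(cv$folds, function(f) unclass(f$confusion)),
      n_folds = length(cv$folds)
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  curves <- do.call(rbind, lapply(seq_along(cv$loss_curves), function(f) {
    data.frame(fold = f, epoch = seq_along(cv$loss_curves[[f]]), loss = cv$loss_curves[[f]])
  }))
  data.table::fwrite(curves, file.path(dir, "loss_curves.csv"))
  invisible(dir)
}
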