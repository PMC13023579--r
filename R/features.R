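# Feature extraction: non-overlapping 2 s windows, band-wise PSD and
# differential entropy at the EEG analysis rate, and 11 Hz time-domain views
# for both modalities.
#
# Band-pass filtering is a 4th-order Butterworth applied with zero phase:
# the filter's squared magnitude response multiplies the signal spectrum
# (the steady-state equivalent of forward-backward filtering), which lets a
# whole trial be filtered with three FFTs per band. The same filtered signal
# feeds both the PSD (mean band power) and the DE (Gaussian closed form), so
# the two features stay mutually consistent.

#' The five classical EEG frequency bands
#'
#' @return data frame with columns `band`, `lo`, `hi` (Hz): delta 0.5-4,
#'   theta 4-8, alpha 8-13, beta 13-30, gamma 30-50
#' @export
band_set <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(0.5, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

.poly_z <- function(coef, zi) {
  acc <- 0 + 0i
  for (k in rev(seq_along(coef))) acc <- acc * zi + coef[k]
  acc
}

# squared magnitude response of an order-2n Butterworth band-pass at the FFT
# bin frequencies of a length-T series; cached per (T, fs, lo, hi)
.mag2_cache <- new.env(parent = emptyenv())
.butter_mag2 <- function(T, fs, lo, hi) {
  key <- paste(T, fs, lo, hi, sep = "_")
  hit <- .mag2_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  bt <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(T) - 1) / T
  zi <- exp(-1i * w)
  H <- .poly_z(bt$b, zi) / .poly_z(bt$a, zi)
  m2 <- Mod(H)^2
  .mag2_cache[[key]] <- m2
  m2
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied via its squared magnitude response in the
#' frequency domain (zero phase, periodic boundary).
#'
#' @param x numeric matrix, channels in rows, time in columns
#' @param fs sampling rate (Hz)
#' @param lo,hi band edges (Hz)
#' @return filtered matrix of the same shape
#' @export
bandpass_filter <- function(x, fs, lo, hi) {
  one_d <- is.null(dim(x))
  if (one_d) x <- matrix(x, nrow = 1)
  T <- ncol(x)
  m2 <- .butter_mag2(T, fs, lo, hi)
  X <- stats::mvfft(t(x))
  y <- t(Re(stats::mvfft(X * m2, inverse = TRUE)) / T)
  if (one_d) y <- drop(y)
  y
}

#' Segment a session into non-overlapping analysis windows
#'
#' Windows are contiguous within each trial; a trailing partial window is
#' dropped, so a trial of duration `d` contributes `floor(d / win_s)` windows.
#'
#' @param x a `raw_session` or a trial data frame with columns `onset_s`,
#'   `duration_s`, `label`
#' @param win_s window length in seconds (default 2)
#' @return object of class `window_set`: data frame with `trial`, `start_s`
#'   (absolute), `label`, and attribute `win_s`
#' @export
segment_windows <- function(x, win_s = 2) {
  stopifnot(win_s > 0)
  trials <- if (inherits(x, "raw_session")) x$trials else x
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    n <- floor(trials$duration_s[i] / win_s + 1e-9)
    if (n < 1) {
      return(NULL)
    }
    data.frame(
      trial = i,
      start_s = trials$onset_s[i] + (seq_len(n) - 1) * win_s,
      label = trials$label[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(trial = integer(), start_s = numeric(), label = character())
  }
  attr(out, "win_s") <- win_s
  class(out) <- c("window_set", class(out))
  out
}

#' Band power of one window (PSD feature)
#'
#' Mean squared amplitude of the band-passed signal per channel and band.
#' Constant channels are floored at `1e-12` with a warning.
#'
#' @param window channels x samples matrix
#' @param fs sampling rate (Hz)
#' @param bands a [band_set()]-shaped data frame
#' @return channels x bands matrix of strictly positive powers
#' @export
compute_psd <- function(window, fs, bands = band_set()) {
  out <- matrix(0, nrow(window), nrow(bands))
  rownames(out) <- rownames(window)
  colnames(out) <- bands$band
  flat <- apply(window, 1, stats::var) == 0
  if (any(flat)) {
    warning("zero-variance channel(s): band power floored at 1e-12")
  }
  for (b in seq_len(nrow(bands))) {
    y <- bandpass_filter(window, fs, bands$lo[b], bands$hi[b])
    out[, b] <- rowMeans(y^2)
  }
  pmax(out, 1e-12)
}

#' Differential entropy of a Gaussian with variance `sigma2` (nats)
#'
#' `DE = 0.5 * log(2 * pi * e * sigma2)`; the closed form used for band-passed
#' EEG under the Gaussian model.
#' @param sigma2 variance (floored at 1e-12)
#' @export
de_gaussian <- function(sigma2) {
  0.5 * log(2 * pi * exp(1) * pmax(sigma2, 1e-12))
}

#' Differential entropy of one window (DE feature, nats)
#'
#' Applies the same band-pass filtering as [compute_psd()] and evaluates the
#' Gaussian closed form on the band power.
#'
#' @inheritParams compute_psd
#' @return channels x bands matrix of finite entropies
#' @export
compute_de <- function(window, fs, bands = band_set()) {
  de_gaussian(compute_psd(window, fs, bands))
}

#' Resample a multichannel series with polyphase anti-aliasing
#'
#' @param x channels x time matrix (or vector)
#' @param fs_in,fs_out sampling rates (Hz); `fs_in >= fs_out`
#' @return resampled series with `round(T * fs_out / fs_in)` samples
#' @export
resample_series <- function(x, fs_in, fs_out) {
  if (fs_out <= 0) stop("fs_out must be positive")
  stopifnot(fs_in >= fs_out)
  one_d <- is.null(dim(x))
  if (one_d) x <- matrix(x, nrow = 1)
  if (fs_in == fs_out) {
    return(if (one_d) drop(x) else x)
  }
  r <- .as_rational(fs_out / fs_in)
  n_out <- round(ncol(x) * fs_out / fs_in)
  y <- matrix(0, nrow(x), n_out)
  for (i in seq_len(nrow(x))) {
    z <- signal::resample(x[i, ], p = r$p, q = r$q)
    if (length(z) < n_out) z <- c(z, rep(z[length(z)], n_out - length(z)))
    y[i, ] <- z[seq_len(n_out)]
  }
  rownames(y) <- rownames(x)
  if (one_d) y <- drop(y)
  y
}

.as_rational <- function(x, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) {
      return(list(p = as.integer(round(p)), q = q))
    }
  }
  stop("cannot express rate ratio as a small rational")
}

#' Build the three model views from a session
#'
#' Produces the four tensors the model consumes, sharing one windowing and one
#' label vector: EEG differential entropy and band power (W x 62 x 5, computed
#' at the EEG analysis rate), the EEG time view resampled to 11 Hz
#' (W x 62 x 22) and the fNIRS time view (W x 18 x 22). Tensors are returned
#' raw (band powers strictly positive); apply [normalize_views()] before
#' training.
#'
#' @param session a `raw_session`
#' @param win_s window length in seconds
#' @param fnirs_channel `"hbo"` (default) or `"hbr"`
#' @return object of class `view_tensors`
#' @export
build_views <- function(session, win_s = 2, fnirs_channel = c("hbo", "hbr")) {
  fnirs_channel <- match.arg(fnirs_channel)
  ws <- segment_windows(session, win_s)
  W <- nrow(ws)
  if (W == 0L) stop("no complete analysis window in any trial")
  bands <- band_set()
  n_eeg <- nrow(session$eeg)
  n_fn <- nrow(session$fnirs_hbo)
  fs_e <- session$eeg_fs
  fs_f <- session$fnirs_fs
  spw_e <- round(win_s * fs_e) # EEG samples per window at analysis rate
  spw_t <- round(win_s * fs_f) # samples per window in the 11 Hz time views

  psd <- array(0, c(W, n_eeg, 5))
  de <- array(0, c(W, n_eeg, 5))
  eeg_time <- array(0, c(W, n_eeg, spw_t))
  fnirs_time <- array(0, c(W, n_fn, spw_t))

  trials <- session$trials
  off_e <- cumsum(c(0, round(trials$duration_s * fs_e)))
  off_f <- cumsum(c(0, round(trials$duration_s * fs_f)))
  fn_sig <- if (fnirs_channel == "hbo") session$fnirs_hbo else session$fnirs_hbr

  for (i in seq_len(nrow(trials))) {
    rows <- which(ws$trial == i)
    n_win <- length(rows)
    if (n_win == 0L) next
    seg <- session$eeg[, (off_e[i] + 1):off_e[i + 1], drop = FALSE]
    for (b in seq_len(5)) {
      y <- bandpass_filter(seg, fs_e, bands$lo[b], bands$hi[b])
      y <- y[, seq_len(n_win * spw_e), drop = FALSE]
      pw <- colMeans(array(t(y)^2, c(spw_e, n_win, n_eeg)))
      psd[rows, , b] <- pw
    }
    seg11 <- resample_series(seg, fs_e, fs_f)
    y <- seg11[, seq_len(n_win * spw_t), drop = FALSE]
    eeg_time[rows, , ] <- aperm(array(t(y), c(spw_t, n_win, n_eeg)), c(2, 3, 1))

    segf <- fn_sig[, (off_f[i] + 1):off_f[i + 1], drop = FALSE]
    y <- segf[, seq_len(n_win * spw_t), drop = FALSE]
    fnirs_time[rows, , ] <- aperm(array(t(y), c(spw_t, n_win, n_fn)), c(2, 3, 1))
  }

  psd <- pmax(psd, 1e-12)
  de <- de_gaussian(psd)

  structure(
    list(
      eeg_de = de, eeg_psd = psd,
      eeg_time = eeg_time, fnirs_time = fnirs_time,
      labels = factor(ws$label, levels = session$classes),
      trial = ws$trial,
      window_start_s = ws$start_s,
      win_s = win_s,
      subject_id = session$subject_id,
      classes = session$classes,
      normalized = FALSE
    ),
    class = "view_tensors"
  )
}

#' Normalize view tensors for training
#'
#' Per-subject, per-channel z-scoring: DE and the time views are z-scored per
#' channel (and band, for DE); band powers are log-transformed first so the
#' heavy-tailed power distribution becomes approximately Gaussian. Required
#' for stable training through the square activations.
#'
#' @param views a [build_views()] object
#' @return the views with normalized tensors and `normalized = TRUE`
#' @export
normalize_views <- function(views) {
  if (isTRUE(views$normalized)) {
    return(views)
  }
  zs_cb <- function(a) { # z per (channel, band) across windows
    mu <- apply(a, c(2, 3), mean)
    sd <- apply(a, c(2, 3), stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(a, c(2, 3), mu, "-"), c(2, 3), sd, "/")
  }
  zs_ch <- function(a) { # z per channel across windows and samples
    mu <- apply(a, 2, mean)
    sd <- apply(a, 2, stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(a, 2, mu, "-"), 2, sd, "/")
  }
  views$eeg_de <- zs_cb(views$eeg_de)
  views$eeg_psd <- zs_cb(log(views$eeg_psd))
  views$eeg_time <- zs_ch(views$eeg_time)
  views$fnirs_time <- zs_ch(views$fnirs_time)
  views$normalized <- TRUE
  views
}

#' @export
print.view_tensors <- function(x, ...) {
  d <- dim(x$eeg_de)
  cat(sprintf(
    "<view_tensors> W=%d windows: eeg_de/psd %dx%dx%d, eeg_time %dx%dx%d, fnirs_time %dx%dx%d%s\n",
    d[1], d[1], d[2], d[3],
    dim(x$eeg_time)[1], dim(x$eeg_time)[2], dim(x$eeg_time)[3],
    dim(x$fnirs_time)[1], dim(x$fnirs_time)[2], dim(x$fnirs_time)[3],
    if (isTRUE(x$normalized)) " (normalized)" else ""
  ))
  invisible(x)
}
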