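# Class-conditioned EEG-fNIRS session simulator.
#
# EEG per trial: pink (1/f) background plus five band-limited Gaussian noise
# components whose power is scaled per class by a 4 x 5 gain matrix, spatially
# mixed with a Gaussian distance kernel over the montage. fNIRS per trial: a
# canonical double-gamma hemodynamic block response with class- and channel-
# dependent amplitude, slow sinusoidal drift and white noise. The class signal
# is stationary within a trial, so band-power ground truth stays analytic.

#' Default per-class band-power gain matrix (4 classes x 5 bands)
#'
#' Rows are happy / sad / fear / neutral, columns delta..gamma. Rows are
#' distinct by construction so classes are separable from EEG band power.
#' @return 4 x 5 numeric matrix
#' @export
default_band_gains <- function() {
  g <- rbind(
    happy   = c(1.0, 1.0, 1.0, 1.8, 2.2),
    sad     = c(1.5, 1.2, 2.0, 0.8, 0.7),
    fear    = c(1.0, 1.6, 0.8, 2.0, 1.4),
    neutral = c(1.2, 1.0, 1.4, 1.0, 1.0)
  )
  colnames(g) <- c("delta", "theta", "alpha", "beta", "gamma")
  g
}

#' Default per-class hemodynamic amplitude matrix (4 classes x 18 channels)
#'
#' Smooth, class-specific spatial activation profiles in micromolar units.
#' @return 4 x 18 numeric matrix
#' @export
default_hrf_amps <- function() {
  a <- outer(1:4, 1:18, function(cl, ch) {
    0.8 + 0.6 * sin(2 * pi * ch / 18 * cl + cl / 2)
  })
  rownames(a) <- c("happy", "sad", "fear", "neutral")
  a
}

# 60-trial layout totalling 4694 s with every duration a multiple of the 2 s
# window, so segmentation yields exactly 2347 windows with no truncation loss
.study_layout <- function() c(rep(78, 53), rep(80, 7))

#' Simulation configuration
#'
#' Defaults reproduce the scale of the study conditions: 15 trials per class
#' over 4 classes, 4694 s of usable signal, EEG at 200 Hz and fNIRS at 11 Hz.
#'
#' @param n_trials_per_class trials per emotion class
#' @param trial_duration_s scalar or per-trial vector of durations in seconds;
#'   `NULL` selects the default 4694 s layout when there are 60 trials, else
#'   78 s per trial
#' @param classes four class labels
#' @param eeg_fs,fnirs_fs sampling rates in Hz
#' @param band_gain_matrix 4 x 5 per-class multiplicative gains on band power
#' @param hrf_amp_matrix 4 x 18 per-class hemodynamic amplitudes (micromolar)
#' @param noise_sd white measurement-noise scale (a.u.)
#' @param spatial_corr_length length scale of the spatial mixing kernel (cm)
#' @param seed base RNG seed for simulation
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_trials_per_class = 15L,
                       trial_duration_s = NULL,
                       classes = c("happy", "sad", "fear", "neutral"),
                       eeg_fs = 200,
                       fnirs_fs = 11,
                       band_gain_matrix = default_band_gains(),
                       hrf_amp_matrix = default_hrf_amps(),
                       noise_sd = 1,
                       spatial_corr_length = 3,
                       seed = 1L) {
  n_trials <- n_trials_per_class * length(classes)
  if (is.null(trial_duration_s)) {
    trial_duration_s <- if (n_trials == 60L) .study_layout() else 78
  }
  if (length(trial_duration_s) == 1L) {
    trial_duration_s <- rep(trial_duration_s, n_trials)
  }
  cfg <- structure(
    list(
      n_trials_per_class = as.integer(n_trials_per_class),
      trial_duration_s = trial_duration_s,
      classes = classes,
      eeg_fs = eeg_fs, fnirs_fs = fnirs_fs,
      band_gain_matrix = band_gain_matrix,
      hrf_amp_matrix = hrf_amp_matrix,
      noise_sd = noise_sd,
      spatial_corr_length = spatial_corr_length,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Simulation config with complementary modality signatures
#'
#' Two classes (happy, sad) are separable only through EEG band power
#' (gamma- vs alpha-dominant); the other two (fear, neutral) are separable
#' only through the spatial pattern of the fNIRS response amplitude. Either
#' modality alone can thus resolve at most three of the four classes, while
#' the fused model can resolve all four -- the construction behind the
#' multimodal-gain checks.
#'
#' @param n_trials_per_class trials per class
#' @param trial_duration_s trial length in seconds
#' @param seed RNG seed
#' @return a [sim_config()]
#' @export
complementary_sim_config <- function(n_trials_per_class = 20L,
                                     trial_duration_s = 2,
                                     seed = 1L) {
  gains <- rbind(
    happy   = c(1, 1, 1, 1, 6), # gamma-dominant
    sad     = c(1, 1, 6, 1, 1), # alpha-dominant
    fear    = c(1, 1, 1, 1, 1),
    neutral = c(1.02, 1, 1, 1, 1) # indistinguishable from fear in EEG
  )
  colnames(gains) <- c("delta", "theta", "alpha", "beta", "gamma")
  amps <- rbind(
    happy   = rep(1, 18),
    sad     = rep(1.02, 18), # indistinguishable from happy in fNIRS
    fear    = c(rep(2.5, 9), rep(0.2, 9)),
    neutral = c(rep(0.2, 9), rep(2.5, 9))
  )
  sim_config(
    n_trials_per_class = n_trials_per_class,
    trial_duration_s = trial_duration_s,
    band_gain_matrix = gains,
    hrf_amp_matrix = amps,
    seed = seed
  )
}

#' Validate a simulation configuration
#' @param cfg a [sim_config()] object
#' @return the config, invisibly; stops on violation
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$classes) == 4L,
    cfg$n_trials_per_class >= 1L,
    nrow(cfg$band_gain_matrix) == 4L, ncol(cfg$band_gain_matrix) == 5L,
    all(cfg$band_gain_matrix > 0),
    nrow(cfg$hrf_amp_matrix) == 4L, ncol(cfg$hrf_amp_matrix) == 18L,
    cfg$fnirs_fs > 0, cfg$noise_sd >= 0, cfg$spatial_corr_length > 0,
    length(cfg$trial_duration_s) == cfg$n_trials_per_class * 4L
  )
  if (cfg$eeg_fs < 100) {
    stop("eeg_fs must be at least 100 Hz (twice the 50 Hz gamma band edge)")
  }
  if (any(cfg$trial_duration_s < 2)) {
    stop("trial_duration_s must be at least 2 s (one analysis window)")
  }
  if (anyDuplicated(lapply(seq_len(4), function(i) cfg$band_gain_matrix[i, ]))) {
    stop("band_gain_matrix rows must be distinct (classes separable by design)")
  }
  invisible(cfg)
}

# All five band-limited components drawn from one white spectrum: the band
# masks are disjoint in frequency, so the components are independent Gaussian
# processes. Mask weights are set so each band contributes expected variance
# equal to its configured gain.
.banded_noise <- function(T, n_ch, fs, gains, bands) {
  x <- matrix(stats::rnorm(T * n_ch), T, n_ch)
  X <- stats::mvfft(x)
  f <- (seq_len(T) - 1) * fs / T
  f <- pmin(f, fs - f) # two-sided bin frequencies
  w <- numeric(T)
  for (b in seq_len(nrow(bands))) {
    idx <- f >= bands$lo[b] & f <= bands$hi[b]
    nb <- sum(idx)
    if (nb > 0) w[idx] <- sqrt(gains[b] * T / nb)
  }
  Re(stats::mvfft(X * w, inverse = TRUE)) / T
}

# pink (1/f amplitude) background noise, unit expected variance per column
.pink_noise <- function(T, n_ch, fs) {
  x <- matrix(stats::rnorm(T * n_ch), T, n_ch)
  X <- stats::mvfft(x)
  f <- (seq_len(T) - 1) * fs / T
  f <- pmin(f, fs - f)
  w <- 1 / sqrt(pmax(f, 0.5))
  w[1] <- 0
  w <- w * sqrt(T / sum(w^2))
  Re(stats::mvfft(X * w, inverse = TRUE)) / T
}

# canonical double-gamma HRF sampled at fs, peak-normalized
.hrf_kernel <- function(fs, len_s = 30) {
  t <- seq(0, len_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Simulate one EEG-fNIRS session
#'
#' Trials are laid out back to back (class labels cycle through the four
#' classes). The result is bit-identical for identical `(cfg, subject_id)`.
#'
#' @param cfg a [sim_config()]
#' @param montage a [make_montage()] object
#' @param subject_id integer subject index (enters the RNG seed)
#' @return object of class `raw_session`: `eeg` (62 x T_e, microvolts),
#'   `fnirs_hbo` / `fnirs_hbr` (18 x T_f, micromolar), `trials` data frame
#'   with `onset_s`, `duration_s`, `label`, plus sampling rates and names
#' @export
simulate_session <- function(cfg, montage, subject_id = 1L) {
  validate_sim_config(cfg)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed((cfg$seed * 1009L + as.integer(subject_id) * 9973L) %% 2147483647L)

  n_trials <- cfg$n_trials_per_class * 4L
  labels <- rep(cfg$classes, length.out = n_trials)
  durs <- cfg$trial_duration_s
  onsets <- cumsum(c(0, durs))[seq_len(n_trials)]

  d <- channel_distances(montage)
  K <- exp(-(d / cfg$spatial_corr_length)^2)
  K <- K / rowSums(K)
  bands <- band_set()

  eeg_parts <- vector("list", n_trials)
  hbo_parts <- vector("list", n_trials)
  hbr_parts <- vector("list", n_trials)
  hrf <- .hrf_kernel(cfg$fnirs_fs)

  for (i in seq_len(n_trials)) {
    cls <- match(labels[i], cfg$classes)
    T_e <- round(durs[i] * cfg$eeg_fs)
    sig <- 0.3 * .pink_noise(T_e, 62L, cfg$eeg_fs) +
      .banded_noise(T_e, 62L, cfg$eeg_fs, cfg$band_gain_matrix[cls, ], bands)
    sig <- sig %*% t(K) # spatial mixing across channels
    sig <- sig + 0.2 * cfg$noise_sd * matrix(stats::rnorm(T_e * 62L), T_e, 62L)
    eeg_parts[[i]] <- 10 * t(sig) # channels x time, microvolt scale

    T_f <- round(durs[i] * cfg$fnirs_fs)
    resp <- stats::convolve(rep(1, T_f), rev(hrf), type = "open")[seq_len(T_f)]
    resp <- resp / max(abs(resp))
    amp <- cfg$hrf_amp_matrix[cls, ]
    tt <- seq_len(T_f) / cfg$fnirs_fs
    drift <- outer(
      stats::runif(18L, 0, 2 * pi), tt,
      function(ph, x) 0.1 * sin(2 * pi * 0.01 * x + ph)
    )
    hbo <- outer(amp, resp) + drift +
      0.1 * cfg$noise_sd * matrix(stats::rnorm(18L * T_f), 18L, T_f)
    hbr <- -0.3 * hbo + 0.05 * matrix(stats::rnorm(18L * T_f), 18L, T_f)
    hbo_parts[[i]] <- hbo
    hbr_parts[[i]] <- hbr
  }

  eeg <- do.call(cbind, eeg_parts)
  rownames(eeg) <- montage$eeg_names
  hbo <- do.call(cbind, hbo_parts)
  hbr <- do.call(cbind, hbr_parts)
  rownames(hbo) <- rownames(hbr) <- montage$fnirs_names

  structure(
    list(
      subject_id = as.integer(subject_id),
      eeg = eeg, fnirs_hbo = hbo, fnirs_hbr = hbr,
      eeg_fs = cfg$eeg_fs, fnirs_fs = cfg$fnirs_fs,
      trials = data.frame(
        onset_s = onsets, duration_s = durs, label = labels,
        stringsAsFactors = FALSE
      ),
      classes = cfg$classes
    ),
    class = "raw_session"
  )
}

#' Total usable signal duration of a session in seconds
#' @param session a `raw_session`
#' @export
session_duration <- function(session) {
  sum(session$trials$duration_s)
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf(
    "<raw_session> subject %d: %d EEG ch @ %g Hz, %d fNIRS ch @ %g Hz, %d trials, %.1f s\n",
    x$subject_id, nrow(x$eeg), x$eeg_fs, nrow(x$fnirs_hbo), x$fnirs_fs,
    nrow(x$trials), session_duration(x)
  ))
  invisible(x)
}
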