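# Sensor layout: 62 EEG electrodes on a 10-20-style grid plus 18 fNIRS
# channels interleaved between the electrode sites, all on a 9 cm sphere.
# The exact coordinates of the recording cap are not published for the
# target dataset; the template below provides physically plausible inter-
# channel distances, which is all the distance-prior adjacency needs.

.eeg_rows <- list(
  list(a = 0.4, labs = c("Fp1", "Fpz", "Fp2"), m = c(-0.1, 0, 0.1)),
  list(a = 0.3, labs = c("AF7", "AF3", "AF4", "AF8"), m = c(-0.4, -0.2, 0.2, 0.4)),
  list(
    a = 0.2, labs = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    m = seq(-0.4, 0.4, by = 0.1)
  ),
  list(
    a = 0.1, labs = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    m = seq(-0.4, 0.4, by = 0.1)
  ),
  list(
    a = 0.0, labs = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    m = seq(-0.4, 0.4, by = 0.1)
  ),
  list(
    a = -0.1, labs = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    m = seq(-0.4, 0.4, by = 0.1)
  ),
  list(
    a = -0.2, labs = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    m = seq(-0.4, 0.4, by = 0.1)
  ),
  list(
    a = -0.3, labs = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
    m = c(-0.4, -0.27, -0.13, 0, 0.13, 0.27, 0.4)
  ),
  list(a = -0.4, labs = c("O1", "Oz", "O2"), m = c(-0.13, 0, 0.13))
)

# map (anterior fraction a, lateral fraction m) to xyz on a sphere of radius r:
# polar angle from the vertex grows with radial grid distance, azimuth points
# from anterior (+x) to lateral (+/- y)
.grid_to_xyz <- function(a, m, r) {
  theta <- pi * sqrt(a^2 + m^2)
  psi <- atan2(m, a)
  psi[a == 0 & m == 0] <- 0
  cbind(
    x = r * sin(theta) * cos(psi),
    y = r * sin(theta) * sin(psi),
    z = r * cos(theta)
  )
}

#' Build the EEG + fNIRS sensor montage
#'
#' Places 62 EEG electrodes on a 10-20-style template grid and 18 fNIRS
#' channels at grid midpoints so that optode positions do not overlap with
#' electrodes. All positions lie on a sphere of radius `radius_cm`; a small
#' seeded jitter models cap-placement variability without ever producing
#' duplicate or near-duplicate sites.
#'
#' @param seed integer; controls the placement jitter
#' @param radius_cm head sphere radius in cm
#' @param jitter_cm standard deviation of tangential placement jitter (cm)
#' @return object of class `montage` with fields `eeg_names`, `eeg_xyz`
#'   (62 x 3, cm), `fnirs_names`, `fnirs_xyz` (18 x 3, cm)
#' @export
make_montage <- function(seed = 0L, radius_cm = 9, jitter_cm = 0.05) {
  a <- unlist(lapply(.eeg_rows, function(r) rep(r$a, length(r$labs))))
  m <- unlist(lapply(.eeg_rows, function(r) r$m))
  labs <- unlist(lapply(.eeg_rows, function(r) r$labs))
  stopifnot(length(labs) == 62L)
  eeg <- .grid_to_xyz(a, m, radius_cm)

  # fNIRS: 3 bands x 6 columns, offset half a grid step from electrode rows
  fa <- rep(c(0.25, 0.05, -0.25), each = 6)
  fm <- rep(c(-0.35, -0.21, -0.07, 0.07, 0.21, 0.35), times = 3)
  fnirs <- .grid_to_xyz(fa, fm, radius_cm)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  jit <- function(x) {
    y <- x + matrix(stats::rnorm(length(x), sd = jitter_cm), nrow(x), 3)
    # re-project onto the sphere so the sector invariant holds
    y * (radius_cm / sqrt(rowSums(y^2)))
  }
  eeg <- jit(eeg)
  fnirs <- jit(fnirs)
  rownames(eeg) <- labs
  fn_names <- sprintf("fNIRS%02d", seq_len(18))
  rownames(fnirs) <- fn_names

  structure(
    list(
      eeg_names = labs, eeg_xyz = eeg,
      fnirs_names = fn_names, fnirs_xyz = fnirs,
      radius_cm = radius_cm, seed = as.integer(seed)
    ),
    class = "montage"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Pairwise 3-D distances between EEG channels
#'
#' @param montage a [make_montage()] object
#' @return 62 x 62 matrix of Euclidean distances in cm
#' @export
channel_distances <- function(montage) {
  as.matrix(stats::dist(montage$eeg_xyz))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf(
    "<montage> %d EEG + %d fNIRS channels on a %.1f cm sphere (seed %d)\n",
    length(x$eeg_names), length(x$fnirs_names), x$radius_cm, x$seed
  ))
  invisible(x)
}
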