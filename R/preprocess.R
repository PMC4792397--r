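#' Default temporal-preprocessing configuration
#'
#' Holds the steps applied to each subject's 4D series before ReHo:
#' dropping initial volumes (scanner equilibration), removal of linear
#' trends, band-pass filtering to the low-frequency BOLD band, and the
#' per-axis head-motion exclusion rule.
#'
#' @param n_discard number of initial volumes to drop (default 10)
#' @param band_low_hz,band_high_hz pass band in Hz (default 0.01–0.08)
#' @param detrend remove a least-squares linear trend first (default TRUE)
#' @param max_translation_mm,max_rotation_deg motion exclusion limits;
#'   a subject fails QC if any translation axis exceeds
#'   `max_translation_mm` (mm) or any rotation axis exceeds
#'   `max_rotation_deg` (degrees), strictly
#' @return a list of class `preprocess_config`
#' @export
preprocess_config <- function(n_discard = 10L, band_low_hz = 0.01,
                              band_high_hz = 0.08, detrend = TRUE,
                              max_translation_mm = 3.0,
                              max_rotation_deg = 3.0) {
  stopifnot(n_discard >= 0, band_low_hz >= 0, band_high_hz > band_low_hz,
            max_translation_mm > 0, max_rotation_deg > 0)
  structure(
    list(
      n_discard = as.integer(n_discard), band_low_hz = band_low_hz,
      band_high_hz = band_high_hz, detrend = isTRUE(detrend),
      max_translation_mm = max_translation_mm,
      max_rotation_deg = max_rotation_deg
    ),
    class = "preprocess_config"
  )
}

#' Discard initial volumes of a 4D series
#'
#' @param vol 4-D array (x, y, z, t)
#' @param n_discard number of leading timepoints to drop
#' @return 4-D array with the last `t - n_discard` volumes, order preserved
#' @export
discard_volumes <- function(vol, n_discard) {
  stopifnot(length(dim(vol)) == 4L)
  nt <- dim(vol)[4]
  if (n_discard >= nt) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, nt))
  }
  if (n_discard == 0L) return(vol)
  vol[, , , (n_discard + 1):nt, drop = FALSE]
}

#' Remove a least-squares linear trend from a time series
#'
#' @param series numeric vector, length >= 3
#' @return the residual after regressing on an intercept and linear term
#' @export
detrend_linear <- function(series) {
  n <- length(series)
  if (n < 3L) stop("need at least 3 timepoints to detrend")
  t <- seq_len(n)
  stats::lsfit(t, series)$residuals
}

#' Ideal (brick-wall) frequency-domain band-pass filter
#'
#' Zeroes every discrete-Fourier component whose frequency falls outside
#' the closed band \[low, high\] Hz; the DC component is always removed
#' when `band_low_hz > 0`. This is the filter convention of the standard
#' resting-state toolchains, chosen over IIR designs because its response
#' is exact on sinusoids.
#'
#' @param series numeric vector
#' @param tr_seconds sampling interval (repetition time) in seconds
#' @param band_low_hz,band_high_hz pass band in Hz; `band_high_hz` must
#'   be below the Nyquist frequency `1/(2 * tr_seconds)`
#' @return filtered real series of the same length
#' @export
bandpass_filter <- function(series, tr_seconds, band_low_hz = 0.01,
                            band_high_hz = 0.08) {
  n <- length(series)
  stopifnot(n >= 2L, tr_seconds > 0)
  if (band_low_hz < 0 || band_low_hz >= band_high_hz) {
    stop("require 0 <= band_low_hz < band_high_hz")
  }
  keep <- bandpass_mask(n, tr_seconds, band_low_hz, band_high_hz)
  Re(stats::fft(stats::fft(series) * keep, inverse = TRUE)) / n
}

#' Head-motion quality-control gate
#'
#' Applies the per-axis exclusion rule: a subject fails if the maximum
#' absolute value of any translation column exceeds `max_translation_mm`
#' or of any rotation column exceeds `max_rotation_deg`. The comparison
#' is strict, so a subject at exactly the limit passes.
#'
#' @param motion_table numeric matrix/data frame with 6 columns: three
#'   translations (mm) then three rotations (degrees), one row per volume
#' @param max_translation_mm translation limit in mm (default 3)
#' @param max_rotation_deg rotation limit in degrees (default 3)
#' @return list with `pass` (logical), `col_max` (named per-column maxima
#'   of absolute motion) and `offending` (names of columns over the limit)
#' @export
motion_qc <- function(motion_table, max_translation_mm = 3.0,
                      max_rotation_deg = 3.0) {
  motion_table <- as.matrix(motion_table)
  if (ncol(motion_table) != 6L) {
    stop("motion table must have 6 columns (3 translations mm, 3 rotations deg)")
  }
  colnames(motion_table) <- c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z")
  col_max <- apply(abs(motion_table), 2, max)
  limits <- c(rep(max_translation_mm, 3), rep(max_rotation_deg, 3))
  over <- col_max > limits
  list(pass = !any(over), col_max = col_max,
       offending = names(col_max)[over])
}

#' Full temporal preprocessing of one subject's 4D volume
#'
#' Applies, in order: initial-volume discard, voxelwise linear detrend,
#' and voxelwise ideal band-pass filtering. Only in-mask voxels are
#' processed; out-of-mask voxels are set to zero.
#'
#' @param vol 4-D array (x, y, z, t)
#' @param mask 3-D binary array on the same spatial grid
#' @param tr_seconds repetition time in seconds
#' @param config a [preprocess_config()]
#' @return 4-D array of preprocessed series (t reduced by `n_discard`)
#' @export
preprocess_volume <- function(vol, mask, tr_seconds,
                              config = preprocess_config()) {
  stopifnot(length(dim(vol)) == 4L, all(dim(vol)[1:3] == dim(mask)))
  vol <- discard_volumes(vol, config$n_discard)
  nt <- dim(vol)[4]
  idx <- mask_indices(mask)
  mat <- matrix(aperm(vol, c(4, 1, 2, 3)), nrow = nt)[, idx, drop = FALSE]
  if (config$detrend) {
    t <- seq_len(nt)
    X <- cbind(1, t)
    mat <- mat - X %*% solve(crossprod(X), crossprod(X, mat))
  }
  keep <- bandpass_mask(nt, tr_seconds, config$band_low_hz, config$band_high_hz)
  mat <- Re(stats::mvfft(stats::mvfft(mat) * keep, inverse = TRUE)) / nt
  out <- array(0, dim(vol))
  flat <- matrix(out, nrow = prod(dim(vol)[1:3]))
  flat[idx, ] <- t(mat)
  array(flat, dim(vol))
}

# frequency retention mask shared by bandpass_filter and preprocess_volume
bandpass_mask <- function(n, tr_seconds, low, high) {
  nyquist <- 1 / (2 * tr_seconds)
  if (high >= nyquist) stop("band_high_hz must be below Nyquist")
  freqs <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * tr_seconds)
  if (n %% 2 == 0) freqs[n %/% 2 + 1] <- abs(freqs[n %/% 2 + 1])
  abs(freqs) >= low & abs(freqs) <= high
}
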