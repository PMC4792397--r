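#' Kendall's coefficient of concordance (W) for a block of time series
#'
#' Measures the agreement of K time series ranked over n timepoints:
#' each series is ranked over time (average ranks for ties), the rank
#' sums \eqn{R_t = \sum_{j=1}^{K} r_{jt}} are formed per timepoint, and
#' \deqn{W = \frac{12 \sum_t (R_t - \bar R)^2}{K^2 (n^3 - n)}, \quad
#'       \bar R = K (n + 1) / 2.}
#' With `tie_correction`, the denominator becomes
#' \eqn{K^2 (n^3 - n) - K \sum_j T_j} with
#' \eqn{T_j = \sum_{\mathrm{tie\ groups}} (t^3 - t)}.
#' W is 1 for perfectly concordant series and 0 when rank sums are
#' constant; it is invariant under strictly increasing transforms of any
#' single series.
#'
#' @param series_matrix numeric matrix, n timepoints x K series (K >= 2,
#'   n >= 3)
#' @param tie_correction apply the tie correction to the denominator
#'   (default FALSE, matching common ReHo tools on continuous data)
#' @return W in \[0, 1\]
#' @export
compute_kcc <- function(series_matrix, tie_correction = FALSE) {
  series_matrix <- as.matrix(series_matrix)
  n <- nrow(series_matrix)
  K <- ncol(series_matrix)
  if (n < 3L) stop("Kendall's W needs at least 3 timepoints")
  if (K < 2L) stop("Kendall's W needs at least 2 series")
  ranks <- apply(series_matrix, 2, rank)
  R <- rowSums(ranks)
  S <- sum((R - K * (n + 1) / 2)^2)
  denom <- K^2 * (n^3 - n)
  if (tie_correction) {
    Tsum <- sum(apply(ranks, 2, tie_term))
    denom <- denom - K * Tsum
  }
  if (denom <= 0) return(0)
  min(1, 12 * S / denom)
}

# sum of (t^3 - t) over tie groups of one ranked series
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Voxelwise regional homogeneity (ReHo) map
#'
#' Computes Kendall's W between each in-mask voxel's time series and its
#' nearest neighbors (27-voxel neighborhood by default: the voxel plus
#' its 26 face, edge and corner neighbors). At mask edges the
#' neighborhood is restricted per `edge_policy`:
#' \describe{
#'   \item{"available"}{use however many in-mask neighbors exist (K =
#'     actual count), the behavior of the standard toolboxes;}
#'   \item{"skip"}{exclude voxels whose full neighborhood is not in the
#'     mask (their map value is 0 and they leave the map support).}
#' }
#'
#' The whole map is computed with one sparse-matrix product: voxel
#' series are ranked once over time and rank sums over each neighborhood
#' are accumulated through the mask adjacency matrix, so it agrees
#' exactly with [compute_kcc()] applied per voxel.
#'
#' @param vol preprocessed 4-D array (x, y, z, t)
#' @param mask 3-D binary array, same spatial grid
#' @param neighborhood 7, 19 or 27 (voxel included)
#' @param edge_policy "available" (default) or "skip"
#' @param tie_correction apply the tie correction (default FALSE)
#' @return object of class `reho_map`: list with `data` (3-D array,
#'   zero outside support), `support` (linear indices of voxels with a
#'   computed W), `normalized` (FALSE) and `smoothed_fwhm_mm` (NA)
#' @export
reho_volume <- function(vol, mask, neighborhood = 27,
                        edge_policy = c("available", "skip"),
                        tie_correction = FALSE) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(length(dim(vol)) == 4L, all(dim(vol)[1:3] == dim(mask)))
  nt <- dim(vol)[4]
  if (nt < 3L) stop("need at least 3 timepoints for ReHo")
  adj <- mask_adjacency(mask, neighborhood)
  idx <- adj$idx
  mat <- matrix(aperm(vol, c(4, 1, 2, 3)), nrow = nt)[, idx, drop = FALSE]
  ranks <- apply(mat, 2, rank)
  K <- as.numeric(Matrix::colSums(adj$adj))
  # R_t per voxel: accumulate neighbor ranks through the adjacency
  Rsum <- as.matrix(ranks %*% adj$adj)
  S <- colSums(sweep(Rsum, 2, K * (nt + 1) / 2)^2)
  denom <- K^2 * (nt^3 - nt)
  if (tie_correction) {
    tsum <- apply(ranks, 2, tie_term)
    denom <- denom - K * as.numeric(tsum %*% adj$adj)
  }
  W <- ifelse(denom > 0, pmin(1, 12 * S / denom), 0)
  keep <- if (edge_policy == "skip") {
    K == neighborhood
  } else {
    K >= 2
  }
  out <- array(0, dim(mask))
  out[idx[keep]] <- W[keep]
  structure(
    list(data = out, support = idx[keep], normalized = FALSE,
         smoothed_fwhm_mm = NA_real_),
    class = "reho_map"
  )
}

#' Normalize a ReHo map by its whole-brain mean
#'
#' Divides every supported voxel by the arithmetic mean of the map over
#' its support, reducing between-subject scale differences; the in-mask
#' mean of the result is exactly 1.
#'
#' @param map a `reho_map`
#' @return a `reho_map` with `normalized = TRUE`
#' @export
normalize_reho <- function(map) {
  stopifnot(inherits(map, "reho_map"))
  m <- mean(map$data[map$support])
  if (!is.finite(m) || m <= 0) stop("in-mask mean ReHo must be positive")
  map$data[map$support] <- map$data[map$support] / m
  map$normalized <- TRUE
  map
}

#' Gaussian-smooth a 3-D map
#'
#' Separable Gaussian smoothing with per-axis standard deviation
#' `sigma = (fwhm_mm / voxel_size_mm) / (2 sqrt(2 log 2))` voxels. The
#' kernel is the normalized Gaussian sampled at integer offsets,
#' truncated at 4 sigma. Smoothing runs on the full grid and the result
#' is re-masked, so values near the mask edge borrow from zero-valued
#' out-of-mask voxels (the convention of volume-based smoothing).
#'
#' @param map a `reho_map` (or any list with `data` and `support`)
#' @param fwhm_mm full width at half maximum in mm (0 = identity)
#' @param voxel_size_mm isotropic voxel edge length in mm
#' @return the map with smoothed data and `smoothed_fwhm_mm` set
#' @export
smooth_volume <- function(map, fwhm_mm, voxel_size_mm = 3) {
  stopifnot(inherits(map, "reho_map"))
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm > 0) {
    map$data <- gaussian_smooth_3d(map$data, fwhm_mm, voxel_size_mm)
    keep <- array(FALSE, dim(map$data))
    keep[map$support] <- TRUE
    map$data[!keep] <- 0
  }
  map$smoothed_fwhm_mm <- fwhm_mm
  map
}

#' Separable 3-D Gaussian convolution on a full grid
#' @param arr 3-D array
#' @param fwhm_mm kernel FWHM in mm
#' @param voxel_size_mm voxel edge in mm
#' @keywords internal
gaussian_smooth_3d <- function(arr, fwhm_mm, voxel_size_mm) {
  sigma <- (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
  if (sigma == 0) return(arr)
  r <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  for (axis in 1:3) {
    arr <- convolve_axis(arr, kern, axis)
  }
  arr
}

# zero-padded 1-D convolution along one axis of a 3-D array
convolve_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(kern) - 1L) %/% 2L
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kern)) {
    out <- out + kern[k] * padded[k:(k + nrow(m) - 1L), , drop = FALSE]
  }
  aperm(array(out, da), order(perm))
}
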