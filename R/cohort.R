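#' Define an implanted synchrony cluster
#'
#' A spherical region in which the generator mixes a cluster-shared
#' latent series into every voxel's time series, raising the local
#' temporal synchrony (hence ReHo) of one group relative to the other.
#' `direction = +1` implants the effect in group A (MHE-like) subjects,
#' `direction = -1` in group B (NHE-like) subjects, so the two signs
#' correspond to regionally increased and decreased homogeneity in
#' group A.
#'
#' @param center integer grid coordinates (x, y, z) of the sphere center
#' @param radius_voxels sphere radius in voxels (>= 1)
#' @param direction +1 (higher synchrony in group A) or -1 (higher in B)
#' @param strength shared-signal mixing proportion in \[0, 1\]; equals the
#'   expected correlation between any two in-cluster voxel series
#' @return a list of class `effect_cluster`
#' @export
effect_cluster <- function(center, radius_voxels = 2, direction = 1,
                           strength = 0.8) {
  stopifnot(length(center) == 3, radius_voxels >= 1,
            direction %in% c(-1, 1), strength >= 0, strength <= 1)
  structure(
    list(center = as.integer(center), radius_voxels = radius_voxels,
         direction = as.integer(direction), strength = strength),
    class = "effect_cluster"
  )
}

#' Specify a synthetic resting-state cohort
#'
#' Describes two subject groups scanned on a common isotropic grid, the
#' synchrony clusters that differ between them, and a model linking each
#' subject's effect magnitude to an integer PHES-like clinical score.
#' Defaults emulate a cohort of 16 MHE-like and 19 unimpaired cirrhotic
#' subjects on a 3-mm grid with TR = 2 s and 170 acquired volumes (of
#' which the first 10 are discarded downstream).
#'
#' @param n_group_a,n_group_b subjects per group (>= 2 each); group A is
#'   the MHE-like (impaired) group
#' @param grid_shape 3 integers, each >= 9 so a full 27-voxel
#'   neighborhood fits inside the mask
#' @param voxel_size_mm isotropic voxel edge in mm
#' @param n_timepoints acquired volumes, including the ones discarded
#' @param n_discard leading volumes the preprocessing will drop
#' @param tr_seconds repetition time in seconds
#' @param effect_clusters list of [effect_cluster()] objects
#' @param noise_sd standard deviation of the voxel noise
#' @param covariate_model list with per-group PHES means (`mean_a`,
#'   `mean_b`), the slope linking a subject's effect scale (centered at
#'   1) to their PHES score, the score noise SD, and the integer
#'   clipping `range`. Group A defaults to mean -7 and group B to
#'   mean -0.6 (SD 2), matching the impaired/unimpaired contrast of the
#'   PHES instrument, with a negative slope so larger implanted effects
#'   accompany worse (lower) scores.
#' @param effect_scale_sd SD of the per-subject effect-scale multiplier
#'   around 1 (truncated to keep strengths in \[0, 1\])
#' @param motion_amplitude scale of the simulated motion random walks;
#'   defaults produce traces comfortably inside the 3 mm / 3 degree QC
#'   limits
#' @param seed integer RNG seed; everything derives from it
#' @return a list of class `cohort_spec`
#' @export
cohort_spec <- function(n_group_a = 16L, n_group_b = 19L,
                        grid_shape = c(30L, 36L, 30L), voxel_size_mm = 3,
                        n_timepoints = 170L, n_discard = 10L,
                        tr_seconds = 2,
                        effect_clusters = list(),
                        noise_sd = 1,
                        covariate_model = list(mean_a = -7, mean_b = -0.6,
                                               slope = -8, noise_sd = 1.2,
                                               range = c(-15, 5)),
                        effect_scale_sd = 0.25,
                        motion_amplitude = 0.05,
                        seed = 1L) {
  stopifnot(n_group_a >= 2, n_group_b >= 2, all(grid_shape >= 9),
            voxel_size_mm > 0, tr_seconds > 0, noise_sd > 0)
  if (n_timepoints <= n_discard) {
    stop("n_timepoints must exceed n_discard")
  }
  for (cl in effect_clusters) {
    stopifnot(inherits(cl, "effect_cluster"))
    lo <- cl$center - cl$radius_voxels
    hi <- cl$center + cl$radius_voxels
    if (any(lo < 1) || any(hi > grid_shape)) {
      stop(sprintf("effect cluster at (%s) radius %.1f exceeds the grid",
                   paste(cl$center, collapse = ","), cl$radius_voxels))
    }
  }
  structure(
    list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
         grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
         n_timepoints = as.integer(n_timepoints),
         n_discard = as.integer(n_discard), tr_seconds = tr_seconds,
         effect_clusters = effect_clusters, noise_sd = noise_sd,
         covariate_model = covariate_model,
         effect_scale_sd = effect_scale_sd,
         motion_amplitude = motion_amplitude, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Brain mask of a cohort spec
#'
#' An ellipsoid inscribed in the grid (semi-axes at 90% of the half
#' extents), standing in for a brain-shaped analysis domain.
#'
#' @param spec a `cohort_spec`
#' @return 3-D 0/1 integer array
#' @export
cohort_mask <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  ax <- pmax((d - 1) / 2 * 0.9, 1)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  array(as.integer(inside), d)
}

#' Linear indices of an effect cluster's voxels
#' @param cl an `effect_cluster`
#' @param dim3 grid dimensions
#' @return integer vector of linear grid indices inside the sphere
#' @export
cluster_voxels <- function(cl, dim3) {
  g <- expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                   z = seq_len(dim3[3]))
  d2 <- (g$x - cl$center[1])^2 + (g$y - cl$center[2])^2 +
    (g$z - cl$center[3])^2
  which(d2 <= cl$radius_voxels^2)
}

# standardized band-limited Gaussian series (unit variance)
band_limited_series <- function(n, tr_seconds, low = 0.01, high = 0.08) {
  x <- stats::rnorm(n)
  y <- bandpass_filter(x, tr_seconds, low, high)
  s <- stats::sd(y)
  if (s < .Machine$double.eps) return(y)
  y / s
}

#' Generate one subject's 4D volume
#'
#' Background voxels receive independent Gaussian noise. Inside every
#' effect cluster assigned to the subject's group, each voxel's series
#' is a strength-weighted mixture of a cluster-shared band-limited
#' latent series and an independent band-limited noise series, both
#' standardized:
#' \deqn{x = \sqrt{s}\,\ell + \sqrt{1 - s}\,\epsilon,}
#' so the mixing proportion `s` equals the expected correlation between
#' any two in-cluster voxels. `s` is the cluster strength scaled by the
#' subject's effect multiplier (capped at 1).
#'
#' @param spec a `cohort_spec`
#' @param group "A" or "B"
#' @param effect_scale per-subject effect multiplier (1 = nominal)
#' @return list with `data` (4-D array) and `truth` (3-D integer array:
#'   +1 / -1 marking voxels of implanted positive / negative clusters,
#'   0 elsewhere)
#' @export
generate_subject_volume <- function(spec, group = c("A", "B"),
                                    effect_scale = 1) {
  group <- match.arg(group)
  d <- spec$grid_shape
  nt <- spec$n_timepoints
  vol <- array(stats::rnorm(prod(d) * nt, sd = spec$noise_sd), c(d, nt))
  truth <- array(0L, d)
  flat <- matrix(vol, nrow = prod(d))
  for (cl in spec$effect_clusters) {
    vox <- cluster_voxels(cl, d)
    truth[vox] <- cl$direction
    applies <- (cl$direction == 1 && group == "A") ||
      (cl$direction == -1 && group == "B")
    if (!applies) next
    s <- min(1, max(0, cl$strength * effect_scale))
    if (s == 0) next
    latent <- band_limited_series(nt, spec$tr_seconds)
    for (v in vox) {
      eps <- band_limited_series(nt, spec$tr_seconds)
      flat[v, ] <- spec$noise_sd * (sqrt(s) * latent + sqrt(1 - s) * eps)
    }
  }
  list(data = array(flat, c(d, nt)), truth = truth)
}

# smooth random-walk motion trace, t x 6 (translations mm, rotations deg)
simulate_motion <- function(nt, amplitude) {
  steps <- matrix(stats::rnorm(nt * 6, sd = amplitude), nt, 6)
  apply(steps, 2, cumsum)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one gzipped NIfTI per subject, a 0/1 mask NIfTI, per-subject
#' 6-column motion tables, a ground-truth effect-mask NIfTI, and a
#' metadata TSV with columns `subject_id, group, phes, age, education,
#' volume, motion`. Group labels are `MHE` (group A) and `NHE`
#' (group B). Each subject's PHES score is
#' `round(group mean + slope * (effect_scale - 1) + noise)`, clipped to
#' the model's integer range, so the score co-varies with the subject's
#' implanted effect magnitude. Identical specs (including the seed)
#' produce byte-identical files.
#'
#' @param spec a `cohort_spec`
#' @param out_dir output directory (created if needed)
#' @return list with `metadata` (data frame), `mask_path`, `truth_path`,
#'   `dir`, and `truth` (3-D array)
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  mask <- cohort_mask(spec)
  n <- spec$n_group_a + spec$n_group_b
  groups <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  cm <- spec$covariate_model
  effect_scale <- pmin(pmax(stats::rnorm(n, 1, spec$effect_scale_sd), 0), 2)
  group_mean <- ifelse(groups == "A", cm$mean_a, cm$mean_b)
  phes <- round(group_mean + cm$slope * (effect_scale - 1) +
                  stats::rnorm(n, 0, cm$noise_sd))
  phes <- as.integer(pmin(pmax(phes, cm$range[1]), cm$range[2]))
  age <- round(stats::rnorm(n, 50, 8))
  education <- pmax(round(stats::rnorm(n, 9, 3)), 0)

  mask_path <- file.path(out_dir, "mask.nii.gz")
  write_nifti_vol(mask, mask_path, spec$voxel_size_mm)

  meta <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = ifelse(groups == "A", "MHE", "NHE"),
    phes = phes, age = age, education = education,
    effect_scale = effect_scale,
    volume = NA_character_, motion = NA_character_,
    stringsAsFactors = FALSE
  )
  truth <- NULL
  for (i in seq_len(n)) {
    sub <- generate_subject_volume(spec, groups[i], effect_scale[i])
    truth <- sub$truth
    vpath <- file.path(out_dir, sprintf("sub-%03d.nii.gz", i))
    write_nifti_vol(sub$data, vpath, spec$voxel_size_mm,
                    tr = spec$tr_seconds)
    mpath <- file.path(out_dir, sprintf("sub-%03d_motion.txt", i))
    utils::write.table(
      round(simulate_motion(spec$n_timepoints, spec$motion_amplitude), 6),
      mpath, row.names = FALSE, col.names = FALSE
    )
    meta$volume[i] <- basename(vpath)
    meta$motion[i] <- basename(mpath)
  }
  truth_path <- file.path(out_dir, "truth.nii.gz")
  write_nifti_vol(truth, truth_path, spec$voxel_size_mm)
  meta_path <- file.path(out_dir, "metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  list(metadata = meta, mask_path = mask_path, truth_path = truth_path,
       dir = out_dir, truth = truth)
}

# write an array as NIfTI-1 with an isotropic affine
write_nifti_vol <- function(arr, path, voxel_size_mm, tr = NULL) {
  img <- RNifti::asNifti(arr)
  pix <- c(rep(voxel_size_mm, 3), if (length(dim(arr)) == 4L) tr %||% 1)
  img <- RNifti::asNifti(img, list(pixdim = c(1, pix,
    rep(1, 7 - length(pix)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort directory back into memory
#'
#' @param dir directory written by [generate_cohort()]
#' @return list with `metadata`, `mask` (3-D array), `dir`
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("no metadata.tsv in ", dir)
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  mask <- as.array(RNifti::readNifti(file.path(dir, "mask.nii.gz")))
  list(metadata = meta, mask = mask, dir = dir)
}
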