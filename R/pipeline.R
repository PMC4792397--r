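#' Assemble a pipeline run configuration
#'
#' One object drives the whole analysis: cohort location, output
#' location, per-stage parameters and a single global seed from which
#' every stochastic stage derives its own stream (so stages can be
#' rerun in isolation and still reproduce).
#'
#' @param cohort_dir directory holding the cohort (volumes, mask.nii.gz,
#'   metadata.tsv, motion tables)
#' @param out_dir output directory for all artifacts
#' @param preprocess list overriding [preprocess_config()] fields
#' @param reho list: `neighborhood` (27), `fwhm_mm` (8), `edge_policy`
#' @param relieff list: `k_neighbors` (1)
#' @param classify list: `grid_from`, `grid_to`, `grid_by`, `cost`
#' @param inference list: `n_permutations`, `voxel_p`, `alpha`, `n_sim`,
#'   `run_permutation`, `run_correlation`
#' @param seed global seed
#' @return a list of class `run_config`
#' @export
run_config <- function(cohort_dir, out_dir,
                       preprocess = list(), reho = list(),
                       relieff = list(), classify = list(),
                       inference = list(), seed = 1L) {
  defaults <- list(
    cohort_dir = cohort_dir, out_dir = out_dir,
    preprocess = list(n_discard = 10L, band_low_hz = 0.01,
                      band_high_hz = 0.08, detrend = TRUE,
                      max_translation_mm = 3.0, max_rotation_deg = 3.0),
    reho = list(neighborhood = 27L, fwhm_mm = 8, edge_policy = "available"),
    relieff = list(k_neighbors = 1L),
    classify = list(grid_from = 50L, grid_to = 5000L, grid_by = 50L,
                    cost = 1),
    inference = list(n_permutations = 200L, voxel_p = 0.01, alpha = 0.05,
                     n_sim = 500L, run_permutation = TRUE,
                     run_correlation = TRUE),
    seed = as.integer(seed)
  )
  cfg <- defaults
  cfg$preprocess <- utils::modifyList(cfg$preprocess, preprocess)
  cfg$reho <- utils::modifyList(cfg$reho, reho)
  cfg$relieff <- utils::modifyList(cfg$relieff, relieff)
  cfg$classify <- utils::modifyList(cfg$classify, classify)
  cfg$inference <- utils::modifyList(cfg$inference, inference)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Expects top-level keys `cohort_dir`, `out_dir`, `seed` and optional
#' sections `preprocess`, `reho`, `relieff`, `classify`, `inference`
#' mirroring the arguments of [run_config()].
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cohort_dir) || is.null(y$out_dir)) {
    stop("config must name cohort_dir and out_dir")
  }
  run_config(
    cohort_dir = y$cohort_dir, out_dir = y$out_dir,
    preprocess = y$preprocess %||% list(), reho = y$reho %||% list(),
    relieff = y$relieff %||% list(), classify = y$classify %||% list(),
    inference = y$inference %||% list(), seed = y$seed %||% 1L
  )
}

# deterministic per-stage seed derivation from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, permutation = 211L, cluster = 307L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the complete ReHo-MVPA pipeline
#'
#' Executes: cohort loading, motion QC (subjects over the limits are
#' excluded and logged), temporal preprocessing, ReHo computation with
#' whole-brain-mean normalization and Gaussian smoothing, feature-table
#' assembly, nested LOOCV over the feature grid, the consensus
#' discriminative map, margin–PHES correlation, and (optionally) the
#' permutation test and the cluster-corrected voxelwise ReHo–PHES
#' correlation within the discriminative map. All intermediate artifacts
#' are written under `out_dir` so each stage can be inspected
#' independently; `report.json` summarizes every stage. Identical config
#' and seed reproduce identical numbers.
#'
#' @param config a `run_config`
#' @param verbose print stage progress (default TRUE)
#' @return the run report (list), invisibly also written as JSON
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (!file.exists(file.path(config$cohort_dir, "mask.nii.gz"))) {
    stop("mask.nii.gz not found in cohort_dir — validate paths before running")
  }
  cohort <- read_cohort(config$cohort_dir)
  meta <- cohort$metadata
  mask <- cohort$mask
  vox_mm <- RNifti::pixdim(
    RNifti::readNifti(file.path(config$cohort_dir, "mask.nii.gz")))[1]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  pp <- config$preprocess
  ppc <- preprocess_config(pp$n_discard, pp$band_low_hz, pp$band_high_hz,
                           pp$detrend, pp$max_translation_mm,
                           pp$max_rotation_deg)

  # motion QC gate
  excluded <- list()
  keep <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    mpath <- file.path(config$cohort_dir, meta$motion[i])
    if (!file.exists(mpath)) { keep[i] <- TRUE; next }
    qc <- motion_qc(utils::read.table(mpath), pp$max_translation_mm,
                    pp$max_rotation_deg)
    keep[i] <- qc$pass
    if (!qc$pass) {
      excluded[[meta$subject_id[i]]] <- list(
        reason = "motion", offending = qc$offending,
        col_max = as.list(qc$col_max))
      say("excluding %s: motion over limit (%s)", meta$subject_id[i],
          paste(qc$offending, collapse = ", "))
    }
  }
  meta <- meta[keep, , drop = FALSE]
  if (nrow(meta) < 4L) stop("fewer than 4 subjects pass motion QC")

  # preprocessing + ReHo per subject
  say("computing ReHo maps for %d subjects", nrow(meta))
  tr <- NULL
  maps <- vector("list", nrow(meta))
  reho_dir <- file.path(config$out_dir, "reho")
  dir.create(reho_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(meta))) {
    img <- RNifti::readNifti(file.path(config$cohort_dir, meta$volume[i]))
    tr <- RNifti::pixdim(img)[4]
    vol <- preprocess_volume(as.array(img), mask, tr, ppc)
    m <- reho_volume(vol, mask, config$reho$neighborhood,
                     config$reho$edge_policy)
    m <- normalize_reho(m)
    m <- smooth_volume(m, config$reho$fwhm_mm, voxel_size_mm = vox_mm)
    maps[[i]] <- m
    write_nifti_vol(m$data,
                    file.path(reho_dir, paste0(meta$subject_id[i],
                                               "_reho.nii.gz")),
                    vox_mm)
  }

  table <- build_feature_table(maps, meta$group, meta$subject_id)
  write_feature_table(table, file.path(config$out_dir, "features.tsv"))

  # nested LOOCV over the feature grid
  cl <- config$classify
  grid <- feature_grid(cl$grid_from, min(cl$grid_to, ncol(table$matrix)),
                       cl$grid_by)
  say("LOOCV over %d grid points", length(grid))
  cv <- loocv_curve(table, grid, cost = cl$cost,
                    k_neighbors = config$relieff$k_neighbors)
  utils::write.table(cv$curve, file.path(config$out_dir, "curve.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  wmap <- discriminative_map(cv, table)
  write_nifti_vol(wmap$data, file.path(config$out_dir, "weight_map.nii.gz"),
                  vox_mm)

  # margin vs PHES at the optimal feature count
  pf <- cv$per_fold[cv$per_fold$n_features == cv$optimal_n, ]
  pf <- pf[match(meta$subject_id, pf$subject), ]
  margin_cor <- pearson_r(pf$margin, meta$phes)

  report <- list(
    seed = config$seed,
    n_subjects = nrow(meta),
    n_excluded = length(excluded),
    excluded = excluded,
    n_features = ncol(table$matrix),
    grid = grid,
    optimal_n = cv$optimal_n,
    max_accuracy = max(cv$curve$accuracy),
    metrics_at_optimal = as.list(
      cv$curve[cv$curve$n_features == cv$optimal_n,
               c("accuracy", "sensitivity", "specificity")]),
    margin_phes_r = margin_cor$r,
    margin_phes_p = margin_cor$p,
    artifacts = list(curve = "curve.tsv", features = "features.tsv",
                     weight_map = "weight_map.nii.gz")
  )

  inf <- config$inference
  if (isTRUE(inf$run_permutation)) {
    say("permutation test (%d permutations)", inf$n_permutations)
    perm <- permutation_test(table, cv$optimal_n,
                             n_permutations = inf$n_permutations,
                             cost = cl$cost,
                             k_neighbors = config$relieff$k_neighbors,
                             seed = stage_seed(config$seed, "permutation"))
    utils::write.table(
      data.frame(null_accuracy = perm$null_distribution),
      file.path(config$out_dir, "null_distribution.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    report$permutation <- list(observed = perm$observed,
                               p_value = perm$p_value,
                               n_permutations = perm$n_permutations)
    null_dist <- perm$null_distribution
  }
  if (isTRUE(inf$run_correlation)) {
    say("voxelwise ReHo-PHES correlation in the discriminative map")
    amask <- array(0L, table$dim3)
    amask[wmap$support] <- 1L
    mhe_rows <- which(table$labels == 1L)
    cmap <- tryCatch(
      voxelwise_correlation(
        table$matrix[mhe_rows, , drop = FALSE], table$voxel_index,
        meta$phes[mhe_rows], table$dim3, analysis_mask = amask,
        covariates = cbind(meta$age, meta$education)[mhe_rows, ],
        voxel_p = inf$voxel_p, alpha = inf$alpha, n_sim = inf$n_sim,
        fwhm_mm = config$reho$fwhm_mm,
        seed = stage_seed(config$seed, "cluster")),
      error = function(e) e)
    if (inherits(cmap, "error")) {
      say("correlation stage skipped: %s", conditionMessage(cmap))
      report$correlation <- list(skipped = conditionMessage(cmap))
    } else {
      report$correlation <- list(
        cluster_threshold = cmap$cluster_threshold,
        n_surviving_clusters = length(cmap$clusters),
        largest_cluster = if (length(cmap$clusters)) {
          length(cmap$clusters[[1]])
        } else 0L)
    }
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  extras <- list(cv = cv, table = table, wmap = wmap, metadata = meta)
  if (exists("null_dist", inherits = FALSE)) {
    extras$null_distribution <- null_dist
  }
  invisible(structure(c(report, extras), class = "run_report"))
}

# persist the feature table with its voxel coordinates
write_feature_table <- function(table, path) {
  hdr <- data.frame(feature_id = seq_along(table$voxel_index),
                    voxel_index = table$voxel_index)
  utils::write.table(hdr, sub("\\.tsv$", "_voxels.tsv", path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  df <- data.frame(subject_id = table$subject_ids, label = table$labels,
                   table$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render the standard report figures
#'
#' Writes three PNG figures from a pipeline report: the
#' accuracy/sensitivity/specificity curve over the feature grid, the
#' margin-versus-score scatter with a least-squares line, and (when the
#' permutation stage ran) the null-accuracy histogram with the observed
#' generalization rate marked.
#'
#' @param report a `run_report` from [run_pipeline()]
#' @param out_dir output directory (default the report's artifacts dir)
#' @return character vector of files written
#' @export
make_figures <- function(report, out_dir = ".") {
  stopifnot(inherits(report, "run_report"))
  cv <- report$cv
  if (is.null(cv) || nrow(cv$curve) == 0L) stop("report has empty curves")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  f <- file.path(out_dir, "accuracy_curve.png")
  grDevices::png(f, width = 900, height = 600)
  graphics::matplot(cv$curve$n_features,
                    cv$curve[, c("accuracy", "sensitivity", "specificity")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "number of input features", ylab = "percent",
                    ylim = c(0, 100))
  graphics::legend("bottomright",
                   legend = c("accuracy", "sensitivity", "specificity"),
                   col = c("black", "firebrick", "steelblue"), lty = 1,
                   lwd = 2, bty = "n")
  grDevices::dev.off()
  files <- c(files, f)

  pf <- cv$per_fold[cv$per_fold$n_features == cv$optimal_n, ]
  pf <- pf[match(report$metadata$subject_id, pf$subject), ]
  f <- file.path(out_dir, "margin_scatter.png")
  grDevices::png(f, width = 700, height = 600)
  graphics::plot(report$metadata$phes, pf$margin, pch = 19,
                 xlab = "PHES score", ylab = "test margin")
  graphics::abline(stats::lm(pf$margin ~ report$metadata$phes),
                   col = "firebrick", lwd = 2)
  grDevices::dev.off()
  files <- c(files, f)

  if (!is.null(report$permutation) && !is.null(report$null_distribution)) {
    nd <- report$null_distribution
    f <- file.path(out_dir, "null_histogram.png")
    grDevices::png(f, width = 700, height = 600)
    graphics::hist(nd, breaks = 20, col = "grey80",
                   xlab = "null generalization rate (%)",
                   xlim = range(c(nd, report$permutation$observed)),
                   main = "")
    graphics::abline(v = report$permutation$observed, col = "firebrick",
                     lwd = 2)
    grDevices::dev.off()
    files <- c(files, f)
  } else {
    message("permutation stage absent; null histogram skipped")
  }
  files
}
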