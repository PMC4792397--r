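# Shared fixture builders: cohorts are always generated in code at test
# time, never stored.

# spec for a small two-cluster cohort on a compact grid
small_cohort_spec <- function(n_a = 10, n_b = 10, strength = 0.9,
                              seed = 1, grid = c(12, 12, 12),
                              n_timepoints = 60, n_discard = 10,
                              clusters = NULL) {
  if (is.null(clusters)) {
    clusters <- list(
      effect_cluster(c(4, 4, 4), 2, +1, strength),
      effect_cluster(c(9, 9, 9), 2, -1, strength)
    )
  }
  cohort_spec(
    n_group_a = n_a, n_group_b = n_b, grid_shape = grid,
    n_timepoints = n_timepoints, n_discard = n_discard,
    effect_clusters = clusters, seed = seed
  )
}

# run generator -> preprocess -> ReHo -> feature table fully in memory
cohort_feature_table <- function(spec, fwhm_mm = 0) {
  set.seed(spec$seed)
  mask <- cohort_mask(spec)
  n <- spec$n_group_a + spec$n_group_b
  groups <- rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b))
  scale_i <- pmin(pmax(rnorm(n, 1, spec$effect_scale_sd), 0), 2)
  cm <- spec$covariate_model
  phes <- round(ifelse(groups == "A", cm$mean_a, cm$mean_b) +
                  cm$slope * (scale_i - 1) + rnorm(n, 0, cm$noise_sd))
  cfg <- preprocess_config(n_discard = spec$n_discard)
  maps <- vector("list", n)
  truth <- NULL
  for (i in seq_len(n)) {
    sub <- generate_subject_volume(spec, groups[i], scale_i[i])
    truth <- sub$truth
    vol <- preprocess_volume(sub$data, mask, spec$tr_seconds, cfg)
    m <- normalize_reho(reho_volume(vol, mask))
    if (fwhm_mm > 0) m <- smooth_volume(m, fwhm_mm, spec$voxel_size_mm)
    maps[[i]] <- m
  }
  tbl <- build_feature_table(maps, ifelse(groups == "A", "MHE", "NHE"))
  list(table = tbl, truth = truth, mask = mask, phes = phes,
       effect_scale = scale_i)
}

# feature table of pure Gaussian noise (exchangeable labels)
noise_feature_table <- function(n_per_class = 8, n_features = 40,
                                seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  feature_table(
    matrix(rnorm(n * n_features), n, n_features),
    seq_len(n_features),
    rep(c(1L, -1L), each = n_per_class),
    dim3 = c(n_features, 1, 1)
  )
}
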