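test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_group_a = 1), "n_group_a")
  expect_error(cohort_spec(grid_shape = c(8, 12, 12)), "grid_shape")
  expect_error(cohort_spec(n_timepoints = 10, n_discard = 10), "exceed")
  expect_error(
    cohort_spec(grid_shape = c(12, 12, 12),
                effect_clusters = list(effect_cluster(c(1, 6, 6), 2))),
    "exceeds the grid")
  expect_error(effect_cluster(c(5, 5, 5), radius_voxels = 0.5), "radius")
  expect_error(effect_cluster(c(5, 5, 5), strength = 1.2), "strength")
})

test_that("zero strength gives near-uncorrelated voxel series", {
  spec <- small_cohort_spec(strength = 0, n_timepoints = 120, n_discard = 0)
  set.seed(1)
  sub <- generate_subject_volume(spec, "A", 1)
  flat <- matrix(sub$data, ncol = 120)
  set.seed(2)
  pick <- matrix(sample(nrow(flat), 400), ncol = 2)
  rs <- vapply(seq_len(200), function(i) {
    cor(flat[pick[i, 1], ], flat[pick[i, 2], ])
  }, numeric(1))
  expect_gte(mean(abs(rs) < 3 / sqrt(120)), 0.95)
})

test_that("full-strength clusters give identical in-cluster series and KCC 1", {
  spec <- cohort_spec(
    n_group_a = 2, n_group_b = 2, grid_shape = c(12, 12, 12),
    n_timepoints = 40, n_discard = 0,
    effect_clusters = list(effect_cluster(c(6, 6, 6), 2, 1, 1)), seed = 3)
  set.seed(3)
  sub <- generate_subject_volume(spec, "A", 1)
  vox <- which(sub$truth == 1L)
  flat <- matrix(sub$data, ncol = 40)
  base <- flat[vox[1], ]
  for (v in vox[-1]) {
    expect_equal(cor(flat[v, ], base), 1, tolerance = 1e-12)
  }
  block <- t(flat[vox, ])
  expect_equal(compute_kcc(block), 1)
})

test_that("positive clusters elevate group-A ReHo over background", {
  # Monte-Carlo over seeds: within each effect-group subject, in-cluster
  # ReHo exceeds the out-of-cluster mean
  wins <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    spec <- small_cohort_spec(
      n_a = 2, n_b = 2, seed = seed,
      clusters = list(effect_cluster(c(6, 6, 6), 2, 1, 0.8)))
    set.seed(seed)
    sub <- generate_subject_volume(spec, "A", 1)
    mask <- cohort_mask(spec)
    vol <- preprocess_volume(sub$data, mask,
                             spec$tr_seconds,
                             preprocess_config(n_discard = spec$n_discard))
    m <- reho_volume(vol, mask)
    inside <- sub$truth == 1L & mask == 1L
    outside <- sub$truth == 0L & mask == 1L
    if (mean(m$data[inside]) > mean(m$data[outside])) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("generated cohorts are byte-identical under one seed", {
  spec <- small_cohort_spec(n_a = 2, n_b = 2, seed = 7,
                            n_timepoints = 20, n_discard = 0)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("cohort metadata matches its cohort_spec and couples PHES to effect size", {
  spec <- cohort_spec(
    n_group_a = 16, n_group_b = 19, grid_shape = c(9, 9, 9),
    n_timepoints = 12, n_discard = 2, seed = 11)
  d <- withr::local_tempdir()
  co <- generate_cohort(spec, d)
  meta <- read.table(file.path(d, "metadata.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(meta), 35)
  expect_equal(sum(meta$group == "MHE"), 16)
  expect_equal(sum(meta$group == "NHE"), 19)
  expect_true(all(meta$phes == round(meta$phes)))
  # MHE-like group centered well below the unimpaired group
  expect_lt(mean(meta$phes[meta$group == "MHE"]),
            mean(meta$phes[meta$group == "NHE"]) - 3)
  # negative slope: larger implanted effect, worse score
  ct <- cor.test(co$metadata$phes, co$metadata$effect_scale)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
  # ground-truth mask equals the implanted voxel set
  truth <- as.array(RNifti::readNifti(co$truth_path))
  expect_identical(which(truth != 0), integer(0))  # no clusters configured
})

test_that("truth mask equals the implanted voxel set exactly", {
  spec <- small_cohort_spec(n_a = 2, n_b = 2, seed = 9)
  set.seed(9)
  sub <- generate_subject_volume(spec, "A", 1)
  expected_pos <- cluster_voxels(spec$effect_clusters[[1]], spec$grid_shape)
  expected_neg <- cluster_voxels(spec$effect_clusters[[2]], spec$grid_shape)
  expect_setequal(which(sub$truth == 1L), expected_pos)
  expect_setequal(which(sub$truth == -1L), expected_neg)
})

test_that("null cohorts give downstream LOOCV accuracy near chance", {
  fx <- cohort_feature_table(
    small_cohort_spec(n_a = 8, n_b = 8, strength = 0, seed = 13,
                      clusters = list()))
  cv <- loocv_curve(fx$table, grid = 40)
  band <- qbinom(c(0.025, 0.975), 16, 0.5) / 16 * 100
  expect_gte(cv$curve$accuracy, band[1])
  expect_lte(cv$curve$accuracy, band[2])
})
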