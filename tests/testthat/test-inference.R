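test_that("permutation p-value follows the add-one rule and honors ties", {
  # strong-effect table: observed accuracy beats every null
  fx <- cohort_feature_table(small_cohort_spec(n_a = 6, n_b = 6, seed = 2))
  perm <- permutation_test(fx$table, n_features = 20, n_permutations = 19,
                           seed = 10)
  expect_equal(perm$observed, 100)
  expect_gt(perm$p_value, 0)
  expect_equal(perm$p_value,
               (sum(perm$null_distribution >= 100) + 1) / 20)
  # a null equal to the observed statistic counts in the numerator
  fake_null <- c(rep(40, 18), 100)
  expect_equal((sum(fake_null >= 100) + 1) / 20, 2 / 20)
})

test_that("permutation test is seed-reproducible", {
  tbl <- noise_feature_table(n_per_class = 5, n_features = 30, seed = 9)
  p1 <- permutation_test(tbl, 10, n_permutations = 15, seed = 77)
  p2 <- permutation_test(tbl, 10, n_permutations = 15, seed = 77)
  expect_identical(p1$null_distribution, p2$null_distribution)
  expect_identical(p1$p_value, p2$p_value)
})

test_that("Pearson correlation matches closed forms, with and without covariates", {
  x <- c(1, 4, 9)
  expect_equal(pearson_r(x, -2 * x)$r, -1)
  # closed form on 3 points: r = cov / (sd sd)
  y <- c(2, 1, 7)
  expect_equal(pearson_r(x, y)$r, cor(x, y))
  expect_equal(pearson_r(x, y)$p,
               cor.test(x, y)$p.value, tolerance = 1e-12)
  # shared covariate induces raw correlation that partialling removes
  set.seed(31)
  z <- rnorm(200)
  a <- z + rnorm(200)
  b <- z + rnorm(200)
  expect_gt(abs(pearson_r(a, b)$r), 0.3)
  expect_lt(abs(pearson_r(a, b, covariates = cbind(z))$r), 0.2)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_r(rnorm(3), rnorm(3), covariates = cbind(rnorm(3))),
               "too few")
})

test_that("null correlations reject at the analytic two-sided rate", {
  set.seed(55)
  crit <- 0.334  # |r| above this is p < 0.05 two-sided at n = 35
  rejections <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    r <- pearson_r(rnorm(35), rnorm(35))
    rejections <- rejections + (abs(r$r) > crit)
  }
  expect_gt(rejections / n_rep, 0.05 - 0.03)
  expect_lt(rejections / n_rep, 0.05 + 0.03)
})

test_that("Monte-Carlo cluster threshold behaves like AlphaSim", {
  mask <- array(0L, c(14, 14, 14))
  mask[2:13, 2:13, 2:13] <- 1L
  expect_equal(montecarlo_cluster_threshold(mask, alpha = 1), 1L)
  thr0 <- montecarlo_cluster_threshold(mask, voxel_p = 0.01, fwhm_mm = 0,
                                       n_sim = 300, seed = 4)
  # independence oracle: iid Bernoulli fields, flood-fill components
  set.seed(4)
  idx <- which(mask == 1)
  max_sizes <- integer(300)
  for (s in 1:300) {
    supra <- idx[runif(length(idx)) < 0.01]
    max_sizes[s] <- max_component_oracle(supra, dim(mask), 26)
  }
  oracle <- 1L
  while (mean(max_sizes >= oracle) > 0.05) oracle <- oracle + 1L
  expect_lte(abs(thr0 - oracle), 2)
  # threshold grows with smoothness
  thr8 <- montecarlo_cluster_threshold(mask, fwhm_mm = 8, n_sim = 200,
                                       seed = 4)
  thr12 <- montecarlo_cluster_threshold(mask, fwhm_mm = 12, n_sim = 200,
                                        seed = 4)
  expect_lte(thr0, thr8)
  expect_lte(thr8, thr12)
  # determinism under a fixed seed
  expect_identical(thr8, montecarlo_cluster_threshold(mask, fwhm_mm = 8,
                                                      n_sim = 200, seed = 4))
})

test_that("voxelwise correlation finds a driven voxel and respects the mask", {
  set.seed(12)
  dim3 <- c(9, 9, 9)
  n <- 20
  stack <- matrix(rnorm(n * 50), n, 50)
  vox <- sample(prod(dim3), 50)
  score <- stack[, 17]  # score IS one voxel's values
  cm <- voxelwise_correlation(stack, vox, score, dim3,
                              cluster_threshold = 1, sidedness = "two")
  expect_equal(cm$r[vox[17]], 1, tolerance = 1e-12)
  expect_true(all(is.na(cm$r[setdiff(seq_len(prod(dim3)), vox)])))
  expect_error(
    voxelwise_correlation(stack[1:4, ], vox, score[1:4], dim3,
                          covariates = cbind(rnorm(4), rnorm(4)),
                          cluster_threshold = 1),
    "covariates")
})

test_that("implanted score-coupled effects yield surviving clusters", {
  found <- 0
  n_rep <- 10
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    dim3 <- c(10, 10, 10)
    mask <- array(1L, dim3)
    n <- 20
    p <- prod(dim3)
    stack <- matrix(rnorm(n * p), n, p)
    score <- rnorm(n)
    truth <- cluster_voxels(effect_cluster(c(5, 5, 5), 2, 1, 1), dim3)
    for (v in truth) stack[, v] <- score + rnorm(n, sd = 0.4)
    cm <- voxelwise_correlation(stack, seq_len(p), score, dim3,
                                voxel_p = 0.01, cluster_threshold = 5)
    hit <- any(vapply(cm$clusters,
                      function(cl) length(intersect(cl, truth)) > 0,
                      logical(1)))
    if (hit) found <- found + 1
  }
  expect_gte(found / n_rep, 0.8)
})

test_that("the integer diagnostic cutoff sits strictly below mean - 2 sd", {
  expect_identical(mhe_cutoff(-0.36, 2.04), -5L)
  expect_identical(mhe_cutoff(0, 1), -3L)
  expect_identical(mhe_cutoff(10, 2.5), 4L)
  expect_error(mhe_cutoff(0, 0), "positive")
})
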