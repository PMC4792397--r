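test_that("Kendall's W hits its analytic extremes", {
  up <- 1:4
  expect_equal(compute_kcc(cbind(up, 2 * up, up + 10)), 1)
  expect_equal(compute_kcc(cbind(1:4, 4:1)), 0)
  expect_error(compute_kcc(matrix(1, 2, 3)), "3 timepoints")
  expect_error(compute_kcc(matrix(1:5, 5, 1)), "2 series")
})

test_that("Kendall's W matches the brute-force oracle on random blocks", {
  set.seed(42)
  worst <- 0
  for (i in 1:300) {
    n <- sample(3:30, 1)
    K <- sample(2:27, 1)
    block <- matrix(rnorm(n * K), n, K)
    if (i %% 3 == 0) block[sample(n * K, n)] <- 0  # induce ties
    for (tc in c(FALSE, TRUE)) {
      worst <- max(worst, abs(compute_kcc(block, tc) - kcc_oracle(block, tc)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("W is invariant under strictly increasing per-series transforms", {
  set.seed(7)
  for (i in 1:20) {
    block <- matrix(rnorm(15 * 8), 15, 8)
    w0 <- compute_kcc(block)
    block[, 3] <- exp(block[, 3])
    block[, 5] <- 2 * block[, 5] + 100
    block[, 8] <- atan(block[, 8])
    expect_equal(compute_kcc(block), w0, tolerance = 1e-12)
  }
})

test_that("reho_volume agrees voxel-by-voxel with compute_kcc", {
  set.seed(9)
  vol <- array(rnorm(9 * 9 * 9 * 20), c(9, 9, 9, 20))
  mask <- array(0L, c(9, 9, 9))
  mask[2:8, 2:8, 2:8] <- 1L
  map <- reho_volume(vol, mask, 27)
  # interior voxel: full 27-neighborhood
  nb <- as.matrix(expand.grid(4:6, 4:6, 4:6))
  block <- t(apply(nb, 1, function(cc) vol[cc[1], cc[2], cc[3], ]))
  expect_equal(map$data[5, 5, 5], compute_kcc(t(block)), tolerance = 1e-12)
  # edge voxel under "available": neighbors clipped to the mask
  nb2 <- as.matrix(expand.grid(2:3, 2:3, 2:3))
  block2 <- t(apply(nb2, 1, function(cc) vol[cc[1], cc[2], cc[3], ]))
  expect_equal(map$data[2, 2, 2], compute_kcc(t(block2)), tolerance = 1e-12)
  # "skip" drops voxels with incomplete neighborhoods
  skip <- reho_volume(vol, mask, 27, edge_policy = "skip")
  expect_equal(skip$data[2, 2, 2], 0)
  expect_gt(skip$data[5, 5, 5], 0)
})

test_that("identical series give a ReHo map of ones; lone voxels drop out", {
  base <- sin(seq(0, 6, length.out = 20))
  vol <- array(rep(base, each = 9 * 9 * 9), c(9, 9, 9, 20))
  mask <- array(1L, c(9, 9, 9))
  map <- reho_volume(vol, mask)
  expect_true(all(abs(map$data[map$support] - 1) < 1e-12))
  lone <- array(0L, c(9, 9, 9))
  lone[5, 5, 5] <- 1L
  expect_length(reho_volume(vol, lone, edge_policy = "skip")$support, 0)
  expect_error(reho_volume(vol, array(0L, c(9, 9, 9))), "empty")
})

test_that("normalization rescales to unit in-mask mean", {
  set.seed(2)
  vol <- array(rnorm(9^3 * 15), c(9, 9, 9, 15))
  mask <- array(1L, c(9, 9, 9))
  map <- reho_volume(vol, mask)
  norm <- normalize_reho(map)
  expect_equal(mean(norm$data[norm$support]), 1, tolerance = 1e-9)
  # hand-checkable two-voxel case
  toy <- map
  toy$support <- c(1L, 2L)
  toy$data[] <- 0
  toy$data[1:2] <- c(0.2, 0.6)
  expect_equal(normalize_reho(toy)$data[1:2], c(0.5, 1.5))
  zero <- map
  zero$data[] <- 0
  expect_error(normalize_reho(zero), "positive")
})

test_that("Gaussian smoothing matches the sampled separable kernel", {
  dim3 <- c(21, 21, 21)
  delta <- array(0, dim3)
  delta[11, 11, 11] <- 1
  map <- structure(list(data = delta, support = seq_len(prod(dim3)),
                        normalized = TRUE, smoothed_fwhm_mm = NA),
                   class = "reho_map")
  fwhm <- 8; vox <- 3
  sm <- smooth_volume(map, fwhm, vox)
  sigma <- (fwhm / vox) / (2 * sqrt(2 * log(2)))
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, -1, 1), c(0, 3, -2))) {
    expected <- k1[r + 1 + off[1]] * k1[r + 1 + off[2]] * k1[r + 1 + off[3]]
    expect_equal(sm$data[11 + off[1], 11 + off[2], 11 + off[3]], expected,
                 tolerance = 1e-6)
  }
  # fwhm = 0 is the identity; constants are preserved in the interior
  expect_equal(smooth_volume(map, 0, vox)$data, delta)
  const <- map; const$data[] <- 2.5
  smc <- smooth_volume(const, fwhm, vox)
  expect_equal(smc$data[11, 11, 11], 2.5, tolerance = 1e-9)
  expect_error(smooth_volume(map, -1, vox), "nonnegative")
})

test_that("null ReHo concentrates near its null mean as series lengthen", {
  set.seed(21)
  interior_w <- function(nt) {
    vol <- array(rnorm(9^3 * nt), c(9, 9, 9, nt))
    mask <- array(1L, c(9, 9, 9))
    m <- reho_volume(vol, mask)
    m$data[2:8, 2:8, 2:8]  # full 27-neighborhoods only
  }
  w_short <- interior_w(10)
  w_long <- interior_w(60)
  # null mean of W over K rankings is about 1/K; wide tolerance
  expect_gt(mean(w_long), 0.5 / 27)
  expect_lt(mean(w_long), 2.5 / 27)
  # longer series concentrate W more tightly around the null mean
  expect_lt(sd(w_long), sd(w_short))
})
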