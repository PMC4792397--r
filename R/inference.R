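#' Permutation test of the cross-validated generalization rate
#'
#' Tests whether the classifier learned a real label–data relationship:
#' the observed statistic is the LOOCV total accuracy (generalization
#' rate) at a fixed feature count, and the null distribution is built by
#' shuffling the class labels and rerunning the complete nested
#' cross-validation — including the within-fold ReliefF ranking — for
#' each permutation. The p-value uses the add-one estimator
#' \deqn{p = \frac{\#\{\mathrm{null} \ge \mathrm{observed}\} + 1}
#'            {n_{\mathrm{perm}} + 1},}
#' which can never be exactly zero.
#'
#' @param table a `feature_table`
#' @param n_features feature count at which the statistic is evaluated
#' @param n_permutations number of label permutations (default 1000;
#'   the full-scale convention is 10000)
#' @param cost SVM cost
#' @param k_neighbors ReliefF neighbor count
#' @param seed RNG seed for the permutations
#' @return object of class `permutation_result`: list with `observed`
#'   (accuracy %), `null_distribution` (numeric vector, %),
#'   `n_permutations`, `p_value`
#' @export
permutation_test <- function(table, n_features, n_permutations = 1000L,
                             cost = 1, k_neighbors = 1L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), n_permutations >= 1)
  if (n_features > ncol(table$matrix)) {
    stop("n_features exceeds the feature count")
  }
  gr <- function(tbl) {
    cv <- loocv_curve(tbl, grid = n_features, cost = cost,
                      k_neighbors = k_neighbors)
    cv$curve$accuracy[1]
  }
  observed <- gr(table)
  set.seed(seed)
  null_dist <- vapply(seq_len(n_permutations), function(i) {
    perm <- sample(table$labels)
    while (length(unique(perm)) < 2L) perm <- sample(table$labels)
    gr(feature_table(table$matrix, table$voxel_index, perm,
                     table$subject_ids, table$dim3))
  }, numeric(1))
  p <- (sum(null_dist >= observed) + 1) / (n_permutations + 1)
  structure(
    list(observed = observed, null_distribution = null_dist,
         n_permutations = as.integer(n_permutations), p_value = p),
    class = "permutation_result"
  )
}

#' Pearson correlation, optionally partial to covariates
#'
#' With covariates, both variables are residualized against an intercept
#' plus the covariate columns by least squares and the correlation of
#' the residuals is returned (classical partial correlation); the
#' two-sided p-value comes from the t transform with the residual
#' degrees of freedom reduced by the number of covariates.
#'
#' @param x,y equal-length numeric vectors
#' @param covariates optional numeric matrix (one row per observation)
#' @return list with `r`, `p`, `df`
#' @export
pearson_r <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < 3L + q) stop("too few observations for the requested model")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input")
  }
  if (q > 0) {
    Z <- cbind(1, as.matrix(covariates))
    H <- Z %*% solve(crossprod(Z), t(Z))
    x <- x - drop(H %*% x)
    y <- y - drop(H %*% y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero residual variance after covariate adjustment")
    }
  }
  r <- stats::cor(x, y)
  df <- n - 2L - q
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum size (in voxels) a contiguous suprathreshold
#' cluster must reach so that, under smooth Gaussian noise restricted to
#' the mask, the family-wise probability of observing any cluster that
#' large is at most `alpha`. Each simulation draws independent standard
#' normal noise on the full grid, smooths it to `fwhm_mm`,
#' restandardizes within the mask, thresholds at the normal quantile for
#' `voxel_p` (one- or two-sided), labels connected components at the
#' chosen connectivity, and records the maximum cluster size. The
#' threshold is the smallest s with
#' `mean(max cluster size >= s) <= alpha`.
#'
#' @param mask 3-D binary array
#' @param voxel_p per-voxel threshold (default 0.01)
#' @param alpha family-wise level (default 0.05); `alpha >= 1` returns 1
#' @param n_sim simulations (default 1000; the full-scale convention is
#'   5000)
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8)
#' @param voxel_size_mm voxel edge in mm
#' @param connectivity 6, 18 or 26 (default 26)
#' @param sidedness "one" or "two"
#' @param seed RNG seed
#' @return integer minimum cluster size
#' @export
montecarlo_cluster_threshold <- function(mask, voxel_p = 0.01, alpha = 0.05,
                                         n_sim = 1000L, fwhm_mm = 8,
                                         voxel_size_mm = 3,
                                         connectivity = 26,
                                         sidedness = c("one", "two"),
                                         seed = 1L) {
  sidedness <- match.arg(sidedness)
  stopifnot(voxel_p > 0, voxel_p < 1, n_sim >= 100)
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("mask is empty")
  if (alpha >= 1) return(1L)
  zthr <- if (sidedness == "one") stats::qnorm(1 - voxel_p) else
    stats::qnorm(1 - voxel_p / 2)
  d <- dim(mask)
  set.seed(seed)
  max_sizes <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (fwhm_mm > 0) {
      noise <- gaussian_smooth_3d(noise, fwhm_mm, voxel_size_mm)
    }
    v <- noise[idx]
    v <- (v - mean(v)) / stats::sd(v)
    supra <- if (sidedness == "one") v > zthr else abs(v) > zthr
    if (!any(supra)) next
    comps <- connected_components(idx[supra], d, connectivity)
    max_sizes[s] <- length(comps[[1]])
  }
  # smallest s such that P(max >= s) <= alpha
  for (s in seq_len(max(max_sizes) + 1L)) {
    if (mean(max_sizes >= s) <= alpha) return(as.integer(s))
  }
  as.integer(max(max_sizes) + 1L)
}

#' Voxelwise correlation map with cluster-extent correction
#'
#' Correlates each voxel of a subjects-by-voxels value stack with a
#' per-subject score (partial to covariates if given), restricted to an
#' analysis mask — typically the discriminative-map support. Voxels
#' with p below `voxel_p` (at the chosen sidedness) form candidate
#' clusters; clusters at least as large as the Monte-Carlo threshold
#' survive.
#'
#' @param stack subjects x voxels numeric matrix, columns aligned with
#'   `voxel_index`
#' @param voxel_index linear grid indices of the stack's columns
#' @param score per-subject score (e.g. PHES)
#' @param dim3 grid dimensions
#' @param analysis_mask optional 3-D binary array restricting the tested
#'   voxels (must be a subset of the stack's voxels)
#' @param covariates optional matrix (e.g. age, education)
#' @param voxel_p per-voxel threshold (default 0.01)
#' @param cluster_threshold minimum surviving cluster size; computed
#'   with [montecarlo_cluster_threshold()] on the analysis mask when NULL
#' @param sidedness "one" (positive correlations, default) or "two"
#' @param connectivity cluster connectivity (default 26)
#' @param ... passed to [montecarlo_cluster_threshold()]
#' @return object of class `correlation_map`: list with `r` and `p`
#'   (3-D arrays, NA off-mask), `clusters` (list of linear-index
#'   vectors), `cluster_threshold`, `tested` (linear indices)
#' @export
voxelwise_correlation <- function(stack, voxel_index, score, dim3,
                                  analysis_mask = NULL, covariates = NULL,
                                  voxel_p = 0.01, cluster_threshold = NULL,
                                  sidedness = c("one", "two"),
                                  connectivity = 26, ...) {
  sidedness <- match.arg(sidedness)
  stack <- as.matrix(stack)
  n <- nrow(stack)
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < q + 3L) stop("fewer subjects than covariates + 3")
  cols <- seq_along(voxel_index)
  if (!is.null(analysis_mask)) {
    keep_idx <- mask_indices(analysis_mask)
    cols <- which(voxel_index %in% keep_idx)
    if (length(cols) == 0L) stop("analysis mask shares no voxels with stack")
  }
  Y <- stack[, cols, drop = FALSE]
  x <- score
  if (q > 0) {
    Z <- cbind(1, as.matrix(covariates))
    H <- Z %*% solve(crossprod(Z), t(Z))
    x <- x - drop(H %*% x)
    Y <- Y - H %*% Y
  } else {
    x <- x - mean(x)
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sx <- sqrt(sum(x^2))
  sy <- sqrt(colSums(Y^2))
  r <- as.numeric(crossprod(Y, x)) / (sx * sy)
  r[!is.finite(r)] <- 0
  df <- n - 2L - q
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- if (sidedness == "one") stats::pt(-tval, df) else
    2 * stats::pt(-abs(tval), df)
  supra <- p < voxel_p
  tested_idx <- voxel_index[cols]
  if (is.null(cluster_threshold)) {
    m <- array(0L, dim3)
    m[tested_idx] <- 1L
    cluster_threshold <- montecarlo_cluster_threshold(
      m, voxel_p = voxel_p, sidedness = sidedness,
      connectivity = connectivity, ...)
  }
  comps <- connected_components(tested_idx[supra], dim3, connectivity)
  clusters <- comps[lengths(comps) >= cluster_threshold]
  rmap <- pmap <- array(NA_real_, dim3)
  rmap[tested_idx] <- r
  pmap[tested_idx] <- p
  structure(
    list(r = rmap, p = pmap, clusters = clusters,
         cluster_threshold = as.integer(cluster_threshold),
         tested = tested_idx),
    class = "correlation_map"
  )
}

#' Integer diagnostic cutoff two standard deviations below the norm
#'
#' The impairment rule for an integer-valued psychometric score:
#' diagnosis when the score falls at least two standard deviations below
#' the normative mean. Because scores are integers, the usable cutoff is
#' the largest integer strictly below `mean - 2 * sd`; diagnosis is
#' `score <= cutoff`.
#'
#' @param normative_mean,normative_sd normative sample statistics
#'   (`normative_sd > 0`)
#' @return integer cutoff
#' @export
mhe_cutoff <- function(normative_mean, normative_sd) {
  if (normative_sd <= 0) stop("normative_sd must be positive")
  x <- normative_mean - 2 * normative_sd
  as.integer(ceiling(x - 1))
}
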