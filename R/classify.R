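#' Train a soft-margin linear SVM
#'
#' Fits a maximal-margin linear classifier with hinge loss and cost
#' parameter C, and returns the primal hyperplane so that the decision
#' value is `d(x) = w . x + b` with `d > 0` predicting class +1 (MHE).
#' Features are not rescaled internally: the caller controls scaling.
#'
#' @param X samples x features numeric matrix
#' @param y +1 / -1 labels, both classes present
#' @param cost soft-margin cost C (default 1)
#' @return list with `w` (feature weights), `b` (bias) and `model`
#' @export
train_linear_svm <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- encode_labels(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  # e1071 orients decision values so the first training label is the
  # positive class; order rows so that +1 comes first
  ord <- order(-y)
  fit <- e1071::svm(X[ord, , drop = FALSE], factor(y[ord], levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- unname(drop(t(fit$coefs) %*% fit$SV))
  b <- -fit$rho
  list(w = w, b = b, model = fit)
}

#' Signed decision values of a linear SVM
#' @param svm_fit result of [train_linear_svm()]
#' @param X samples x features matrix
#' @return numeric decision values `w . x + b`
#' @export
svm_decision <- function(svm_fit, X) {
  drop(as.matrix(X) %*% svm_fit$w + svm_fit$b)
}

#' Classification metrics from a confusion table
#'
#' MHE (+1) is the positive class: sensitivity is the fraction of MHE
#' subjects detected, specificity the fraction of NHE subjects correctly
#' ruled out. Values are percentages; `round1` gives the conventional
#' one-decimal reporting.
#'
#' @param tp,fn,tn,fp confusion counts (true/false positives/negatives)
#' @param round1 round to one decimal (default TRUE)
#' @return named numeric vector: accuracy, sensitivity, specificity (%)
#' @export
confusion_metrics <- function(tp, fn, tn, fp, round1 = TRUE) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn < 1 || tn + fp < 1) stop("each class needs at least one subject")
  out <- c(
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp)
  )
  # report-style rounding: halves round up (13/16 -> 81.3), unlike the
  # round-half-even convention of round()
  if (round1) floor(out * 10 + 0.5) / 10 else out
}

#' Default incremental feature grid
#' @param from,to,by grid bounds and step (defaults 50, 5000, 50)
#' @return integer vector
#' @export
feature_grid <- function(from = 50L, to = 5000L, by = 50L) {
  as.integer(seq(from, to, by))
}

#' Nested leave-one-out cross-validated accuracy curve
#'
#' For each left-out subject, features are ranked with ReliefF on the
#' remaining subjects only (no test-set leakage); for every feature
#' count n on the grid the top-n training features enter a linear SVM
#' and the held-out subject is predicted, recording the predicted label
#' and its geometric margin (decision value / ||w||). Accuracy,
#' sensitivity and specificity are aggregated per grid point and the
#' optimal feature count is the smallest n attaining the maximum
#' accuracy.
#'
#' @param table a `feature_table`
#' @param grid increasing feature counts (default [feature_grid()]);
#'   entries above the feature count are dropped with a warning
#' @param cost SVM cost parameter
#' @param k_neighbors ReliefF near-neighbor count
#' @param ranker ranking function `(table) -> feature_ranking`; defaults
#'   to ReliefF. Exposed so the ranking stage can be instrumented or
#'   replaced.
#' @param rank_on_all rank once on all subjects instead of within each
#'   fold. This leaks test information into feature selection and is
#'   provided for comparison only.
#' @return object of class `cv_result`: list with `grid`, `curve`
#'   (data frame: n_features, accuracy, sensitivity, specificity in %),
#'   `per_fold` (data frame: subject, grid point, true/predicted label,
#'   margin, decision value), `optimal_n`, `fold_orders` (per-fold
#'   ranked feature ids), `cost`
#' @export
loocv_curve <- function(table, grid = feature_grid(), cost = 1,
                        k_neighbors = 1L, ranker = NULL,
                        rank_on_all = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$matrix)
  y <- table$labels
  if (n < 4L || min(table(y)) < 2L) {
    stop("need at least 4 subjects and 2 per class")
  }
  p <- ncol(table$matrix)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid > p)) {
    warning(sprintf("dropping %d grid points above the feature count (%d)",
                    sum(grid > p), p))
    grid <- grid[grid <= p]
  }
  if (length(grid) == 0L) stop("empty feature grid")
  if (is.null(ranker)) {
    ranker <- function(tbl) {
      rank_features(relieff_weights(tbl, k_neighbors = k_neighbors))
    }
  }
  global_order <- if (rank_on_all) ranker(table)$order
  fold_orders <- vector("list", n)
  ng <- length(grid)
  pred <- margin <- dec <- matrix(0, n, ng)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    sub <- feature_table(table$matrix[train, , drop = FALSE],
                         table$voxel_index, y[train],
                         table$subject_ids[train], table$dim3)
    ord <- if (rank_on_all) global_order else ranker(sub)$order
    fold_orders[[i]] <- ord
    for (g in seq_len(ng)) {
      feats <- ord[seq_len(grid[g])]
      fit <- train_linear_svm(table$matrix[train, feats, drop = FALSE],
                              y[train], cost = cost)
      d <- svm_decision(fit, table$matrix[i, feats, drop = FALSE])
      dec[i, g] <- d
      wn <- sqrt(sum(fit$w^2))
      margin[i, g] <- if (wn > 0) d / wn else 0
      pred[i, g] <- if (d >= 0) 1 else -1
    }
  }
  per_fold <- data.frame(
    subject = rep(table$subject_ids, ng),
    fold = rep(seq_len(n), ng),
    n_features = rep(grid, each = n),
    true = rep(y, ng),
    predicted = as.integer(pred), margin = as.numeric(margin),
    decision = as.numeric(dec)
  )
  tp <- colSums(pred == 1 & y == 1)
  fn <- colSums(pred == -1 & y == 1)
  tn <- colSums(pred == -1 & y == -1)
  fp <- colSums(pred == 1 & y == -1)
  curve <- data.frame(
    n_features = grid,
    t(vapply(seq_len(ng), function(g) {
      confusion_metrics(tp[g], fn[g], tn[g], fp[g])
    }, numeric(3)))
  )
  optimal_n <- curve$n_features[which.max(curve$accuracy)]
  structure(
    list(grid = grid, curve = curve, per_fold = per_fold,
         optimal_n = optimal_n, fold_orders = fold_orders, cost = cost),
    class = "cv_result"
  )
}

#' Discriminative weight map from a cross-validated model
#'
#' Projects the linear-SVM weight vector at the optimal feature count
#' back onto the voxel grid. Positive weights mark voxels whose (higher)
#' ReHo pushes a subject toward the MHE class. `mode = "single_fold"`
#' refits on one fold's training set using that fold's ranking (the
#' per-fold maps are typically very similar, so one fold can represent
#' the final map); `mode = "consensus"` (default) averages the per-fold
#' weight maps voxelwise over the union of their supports.
#'
#' @param cv a `cv_result`
#' @param table the `feature_table` used to produce it
#' @param mode "consensus" or "single_fold"
#' @param n_features feature count to use (default `cv$optimal_n`)
#' @param fold fold index for `single_fold` (default 1)
#' @return object of class `weight_map`: list with `data` (3-D array, 0
#'   off-support), `support` (linear indices), `mode`, `n_features`
#' @export
discriminative_map <- function(cv, table, mode = c("consensus", "single_fold"),
                               n_features = NULL, fold = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cv, "cv_result"), inherits(table, "feature_table"))
  n_features <- as.integer(n_features %||% cv$optimal_n)
  if (length(n_features) != 1L || is.na(n_features)) {
    stop("optimal_n missing from cv result")
  }
  n <- nrow(table$matrix)
  y <- table$labels
  fold_w <- function(i) {
    train <- setdiff(seq_len(n), i)
    feats <- cv$fold_orders[[i]][seq_len(n_features)]
    fit <- train_linear_svm(table$matrix[train, feats, drop = FALSE],
                            y[train], cost = cv$cost)
    list(feats = feats, w = fit$w)
  }
  if (is.null(table$dim3)) stop("feature table lacks grid dimensions")
  acc <- numeric(prod(table$dim3))
  cnt <- numeric(prod(table$dim3))
  folds <- if (mode == "single_fold") fold else seq_len(n)
  for (i in folds) {
    fw <- fold_w(i)
    vox <- table$voxel_index[fw$feats]
    acc[vox] <- acc[vox] + fw$w
    cnt[vox] <- cnt[vox] + 1
  }
  support <- which(cnt > 0)
  acc[support] <- acc[support] / cnt[support]
  structure(
    list(data = array(acc, table$dim3), support = support, mode = mode,
         n_features = n_features),
    class = "weight_map"
  )
}
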