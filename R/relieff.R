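#' Build a subjects-by-voxels feature table from ReHo maps
#'
#' Stacks per-subject ReHo maps over the in-mask voxels into the matrix
#' the classifier consumes, keeping the mapping from feature columns
#' back to grid coordinates.
#'
#' @param maps list of `reho_map` objects (one per subject), all on the
#'   same grid with identical support
#' @param labels vector of +1 / -1 (or "MHE" / "NHE") per subject; MHE
#'   codes as +1
#' @param subject_ids optional character vector
#' @return object of class `feature_table`: list with `matrix`
#'   (subjects x features), `voxel_index` (linear grid indices per
#'   feature), `coords` (features x 3), `labels` (+1/-1 integer),
#'   `subject_ids`, `dim3`
#' @export
build_feature_table <- function(maps, labels, subject_ids = NULL) {
  stopifnot(length(maps) == length(labels), length(maps) >= 2)
  labels <- encode_labels(labels)
  support <- maps[[1]]$support
  dim3 <- dim(maps[[1]]$data)
  mat <- t(vapply(maps, function(m) {
    if (!identical(m$support, support)) stop("maps have differing support")
    m$data[support]
  }, numeric(length(support))))
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub-%03d", seq_along(maps))
  }
  feature_table(mat, support, labels, subject_ids, dim3)
}

#' Construct a feature table from a plain matrix
#'
#' @param matrix subjects x features numeric matrix, no missing values
#' @param voxel_index linear grid index per feature (bijection onto the
#'   analysis mask)
#' @param labels +1 / -1 per subject, both classes present
#' @param subject_ids character vector
#' @param dim3 grid dimensions
#' @return a `feature_table`
#' @export
feature_table <- function(matrix, voxel_index, labels,
                          subject_ids = NULL, dim3 = NULL) {
  matrix <- as.matrix(matrix)
  labels <- encode_labels(labels)
  if (anyNA(matrix)) stop("feature table must not contain missing values")
  if (length(voxel_index) != ncol(matrix)) {
    stop("voxel_index length must equal the number of features")
  }
  if (anyDuplicated(voxel_index)) stop("voxel_index must be a bijection")
  if (length(labels) != nrow(matrix)) stop("one label per subject required")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub-%03d", seq_len(nrow(matrix)))
  }
  structure(
    list(matrix = matrix, voxel_index = as.integer(voxel_index),
         coords = if (!is.null(dim3)) index_to_coord(voxel_index, dim3),
         labels = labels, subject_ids = subject_ids, dim3 = dim3),
    class = "feature_table"
  )
}

encode_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("MHE", "NHE"))) {
      stop("character labels must be 'MHE' or 'NHE'")
    }
    labels <- ifelse(labels == "MHE", 1L, -1L)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1 or MHE/NHE")
  labels
}

#' ReliefF feature weights
#'
#' Weights each feature by how well it separates samples from their
#' nearest other-class neighbors (near-misses) relative to their nearest
#' same-class neighbors (near-hits). For each visited sample x, the k
#' nearest hits and k nearest misses are found by Euclidean distance on
#' min-max scaled features, and every feature weight is updated by
#' \deqn{W_f \leftarrow W_f - \mathrm{diff}(f, x, \mathrm{hit}) / (m k)
#'       + \mathrm{diff}(f, x, \mathrm{miss}) / (m k)}
#' with \eqn{\mathrm{diff}(f, a, b) = |a_f - b_f| / (\max_f - \min_f)}
#' (0 for constant features). With `n_iterations = "all"` (the default)
#' every subject is visited exactly once in order, making the weights
#' deterministic — appropriate for cohorts of a few dozen subjects.
#'
#' @param table a `feature_table`
#' @param k_neighbors near-hits/near-misses per sample (default 1); must
#'   be below the smaller class size
#' @param n_iterations "all" (deterministic full pass) or a sample count
#' @param seed RNG seed, only used when `n_iterations` is a number
#' @return numeric vector of per-feature weights
#' @export
relieff_weights <- function(table, k_neighbors = 1L, n_iterations = "all",
                            seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$matrix
  y <- table$labels
  n <- nrow(X)
  class_sizes <- table(y)
  if (length(class_sizes) < 2L) stop("both classes must be present")
  if (k_neighbors >= min(class_sizes)) {
    stop("k_neighbors must be smaller than the smaller class size")
  }
  mn <- mx <- X[1, ]
  for (i in seq_len(n)[-1]) {
    mn <- pmin(mn, X[i, ])
    mx <- pmax(mx, X[i, ])
  }
  rng <- mx - mn
  ok <- rng > 0
  scale_div <- ifelse(ok, rng, 1)
  Xs <- (X - rep(mn, each = n)) / rep(scale_div, each = n)
  Xs[, !ok] <- 0
  # squared Euclidean distances suffice for neighbor ordering
  G <- tcrossprod(Xs)
  sq <- diag(G)
  D <- outer(sq, sq, "+") - 2 * G
  diag(D) <- Inf
  if (identical(n_iterations, "all")) {
    visit <- seq_len(n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    visit <- sample.int(n, min(as.integer(n_iterations), n))
  }
  m <- length(visit)
  # near-hit / near-miss indices for every visited sample, then one
  # vectorized weight update per neighbor rank
  hit_idx <- miss_idx <- matrix(0L, m, k_neighbors)
  same <- outer(y, y, "==")
  for (v in seq_along(visit)) {
    i <- visit[v]
    d <- D[i, ]
    hits <- which(same[i, ])
    misses <- which(!same[i, ])
    if (k_neighbors == 1L) {
      hit_idx[v, 1] <- hits[which.min(d[hits])]
      miss_idx[v, 1] <- misses[which.min(d[misses])]
    } else {
      hit_idx[v, ] <- hits[order(d[hits])][seq_len(k_neighbors)]
      miss_idx[v, ] <- misses[order(d[misses])][seq_len(k_neighbors)]
    }
  }
  W <- numeric(ncol(X))
  Xv <- Xs[visit, , drop = FALSE]
  for (k in seq_len(k_neighbors)) {
    W <- W +
      colSums(abs(Xv - Xs[miss_idx[, k], , drop = FALSE])) / (m * k_neighbors) -
      colSums(abs(Xv - Xs[hit_idx[, k], , drop = FALSE])) / (m * k_neighbors)
  }
  W
}

#' Rank features by descending weight
#'
#' Ties are broken by ascending feature (voxel) index so the ranking is
#' deterministic across runs.
#'
#' @param weights per-feature weights
#' @param top_n stored default selection size (default 5000, capped at
#'   the feature count)
#' @return object of class `feature_ranking`: list with `weights`,
#'   `order` (feature ids, best first) and `top_n`
#' @export
rank_features <- function(weights, top_n = 5000L) {
  ord <- order(-weights, seq_along(weights))
  structure(
    list(weights = weights, order = ord,
         top_n = min(as.integer(top_n), length(weights))),
    class = "feature_ranking"
  )
}

#' Select the top-n ranked features
#'
#' @param ranking a `feature_ranking`
#' @param n number of features to keep (<= feature count)
#' @return integer vector of feature ids, best first
#' @export
select_top_features <- function(ranking, n) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (n > length(ranking$order)) {
    stop(sprintf("requested %d features but only %d exist", n,
                 length(ranking$order)))
  }
  ranking$order[seq_len(n)]
}

#' Write a feature ranking as TSV
#'
#' Columns: feature_id, x, y, z, weight, rank.
#'
#' @param ranking a `feature_ranking`
#' @param table the `feature_table` the ranking refers to
#' @param path output path
#' @export
write_ranking <- function(ranking, table, path) {
  ord <- ranking$order
  df <- data.frame(
    feature_id = ord,
    x = table$coords[ord, 1], y = table$coords[ord, 2],
    z = table$coords[ord, 3],
    weight = ranking$weights[ord], rank = seq_along(ord)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
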