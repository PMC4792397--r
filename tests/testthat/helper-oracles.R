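# Independent oracles, coded straight from the defining formulas with
# plain loops; deliberately share no code with the package internals.

# Kendall's W by direct enumeration of rank sums
kcc_oracle <- function(mat, tie_correction = FALSE) {
  n <- nrow(mat)
  K <- ncol(mat)
  ranks <- matrix(0, n, K)
  for (j in seq_len(K)) ranks[, j] <- rank(mat[, j])
  R <- numeric(n)
  for (t in seq_len(n)) R[t] <- sum(ranks[t, ])
  Rbar <- K * (n + 1) / 2
  S <- sum((R - Rbar)^2)
  denom <- K^2 * (n^3 - n)
  if (tie_correction) {
    Tsum <- 0
    for (j in seq_len(K)) {
      for (tt in table(ranks[, j])) Tsum <- Tsum + (tt^3 - tt)
    }
    denom <- denom - K * Tsum
  }
  12 * S / denom
}

# connected-component max size by breadth-first flood fill
max_component_oracle <- function(idx, dim3, connectivity = 26) {
  if (length(idx) == 0) return(0L)
  inset <- array(FALSE, dim3)
  inset[idx] <- TRUE
  seen <- array(FALSE, dim3)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(offs != 0) <= 2, ]
  best <- 0L
  coords <- arrayInd(idx, dim3)
  for (s in seq_along(idx)) {
    if (seen[idx[s]]) next
    queue <- list(coords[s, ])
    seen[idx[s]] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      c0 <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        c1 <- c0 + offs[k, ]
        if (any(c1 < 1) || any(c1 > dim3)) next
        lin <- c1[1] + (c1[2] - 1) * dim3[1] + (c1[3] - 1) * dim3[1] * dim3[2]
        if (inset[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue[[length(queue) + 1]] <- c1
        }
      }
    }
    best <- max(best, size)
  }
  best
}

# soft-margin linear SVM via the dual QP (kernlab interior-point solver)
svm_dual_oracle <- function(X, y, C) {
  n <- nrow(X)
  Q <- (y %*% t(y)) * (X %*% t(X))
  sol <- kernlab::ipop(
    c = matrix(-1, n, 1), H = Q,
    A = matrix(y, 1, n), b = 0, r = 0,
    l = matrix(0, n, 1), u = matrix(C, n, 1)
  )
  alpha <- kernlab::primal(sol)
  w <- drop(t(X) %*% (alpha * y))
  on_margin <- which(alpha > 1e-6 * C & alpha < C * (1 - 1e-6))
  b <- mean(y[on_margin] - X[on_margin, , drop = FALSE] %*% w)
  list(w = w, b = b, alpha = alpha)
}
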