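# PCA dimensionality reduction ahead of the sparse multi-set CCA.

#' Principal component reduction of a feature block
#'
#' Computes the top-K principal components by singular value decomposition of
#' the centered matrix (via [stats::prcomp]), with a deterministic sign
#' convention: each component is flipped so its largest-magnitude loading is
#' positive, making downstream weights reproducible across runs and
#' platforms.
#'
#' @param x Numeric matrix, participants x variables (already residualized
#'   and, if desired, z-scored).
#' @param k Number of components, `k <= min(n - 1, p)`.
#' @return Object of class `pc_model`: `scores` (n x k), `loadings` (p x k),
#'   `variance_explained` (fraction per retained component, relative to the
#'   total variance of `x`), `cumulative_ve`, `k`, `center`.
#' @export
reduce_pca <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (k < 1 || k > min(n - 1, p))
    stopf("k must lie in [1, min(n - 1, p)] = [1, %d]", min(n - 1, p))
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stopf("input has no variance (all columns constant)")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve_all <- pr$sdev^2 / sum(pr$sdev^2)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sco <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    jmax <- which.max(abs(rot[, j]))
    if (rot[jmax, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  out <- list(scores = sco, loadings = rot,
              variance_explained = ve_all[seq_len(k)],
              cumulative_ve = cumsum(ve_all)[k],
              k = k, center = pr$center)
  class(out) <- "pc_model"
  out
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("PCA reduction: %d components, %.1f%% variance explained\n",
              x$k, 100 * x$cumulative_ve))
  invisible(x)
}

#' @export
predict.pc_model <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  sweep(nd, 2, object$center) %*% object$loadings
}
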