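# Permutation significance test for the fitted multi-set association.

#' Permutation test of the sum of canonical correlations
#'
#' Refits the sparse multi-set CCA on row-shuffled data to build a null
#' distribution of the sum of pairwise canonical correlations. Each replicate
#' independently permutes the participant rows of every set except the
#' reference set (under exchangeability this is equivalent to shuffling all
#' sets). Penalties stay fixed at their observed-data values; set
#' `reselect = TRUE` to re-run penalty selection inside every replicate for
#' sensitivity analysis.
#'
#' Two p-values are reported: the plain proportion of permuted sums at or
#' above the observed sum, and the add-one variant
#' `(#\{>=\} + 1) / (n_perm + 1)`.
#'
#' @param sets List of feature-score matrices (participants x components).
#' @param penalty Penalty fraction(s) selected on the observed data.
#' @param n_perm Number of permutations (>= 1; the reference analysis used
#'   1000).
#' @param seed Integer seed for the permutation stream.
#' @param reference Index of the set whose rows are held fixed (default 1,
#'   the games set).
#' @param reselect Re-run permutation penalty selection per replicate
#'   (default FALSE); `grid` and `n_perm_select` control that inner search.
#' @param max_iter,tol Convergence controls for every fit.
#' @param grid,n_perm_select Penalty grid and inner permutation count used
#'   when `reselect = TRUE`.
#' @return Object of class `smcca_permtest`: observed sum of correlations,
#'   the permuted values, both p-values, `n_perm` and `seed`.
#' @export
permutation_test <- function(sets, penalty, n_perm = 1000, seed = 1,
                             reference = 1, reselect = FALSE,
                             max_iter = 200, tol = 1e-6,
                             grid = seq(0.1, 0.9, length.out = 10),
                             n_perm_select = 25) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  if (is.null(penalty)) stopf("penalties must be selected before testing")
  sets <- lapply(sets, as.matrix)
  K <- length(sets)
  n <- nrow(sets[[1]])
  dims <- vapply(sets, ncol, integer(1))
  Xs <- lapply(seq_len(K), function(i) standardize_columns(sets[[i]],
                                                           sprintf("set %d", i)))
  Cobs <- crossprod_table(Xs)
  w0 <- lapply(seq_len(K), function(i) leading_weight(Cobs[[i]][[i]]))
  obs_fit <- smcca_core(Cobs, penalty_bounds(penalty, dims), w0,
                        max_iter = max_iter, tol = tol)
  observed <- obs_fit$sum_cor

  permuted <- numeric(n_perm)
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    Xp <- Xs
    for (i in setdiff(seq_len(K), reference))
      Xp[[i]] <- Xs[[i]][sample.int(n), , drop = FALSE]
    pen_b <- penalty
    if (reselect) {
      sel <- select_penalties(Xp, grid = grid, n_perm = n_perm_select,
                              seed = stage_seed(seed, sprintf("reselect%d", b)),
                              max_iter = max_iter, tol = tol)
      pen_b <- sel$penalty
    }
    fit <- smcca_core(crossprod_table(Xp), penalty_bounds(pen_b, dims), w0,
                      max_iter = max_iter, tol = tol)
    permuted[b] <- fit$sum_cor
  }
  n_ge <- sum(permuted >= observed)
  out <- list(observed = observed, permuted = permuted,
              p_value = n_ge / n_perm,
              p_value_add_one = (n_ge + 1) / (n_perm + 1),
              n_perm = n_perm, seed = seed, reference = reference)
  class(out) <- "smcca_permtest"
  out
}

#' @export
print.smcca_permtest <- function(x, ...) {
  cat(sprintf("Permutation test of the sum of canonical correlations\n"))
  cat(sprintf("  observed: %.3f; null mean %.3f (sd %.3f) over %d permutations\n",
              x$observed, mean(x$permuted), stats::sd(x$permuted), x$n_perm))
  cat(sprintf("  p = %.4g (proportion at or above); add-one p = %.4g\n",
              x$p_value, x$p_value_add_one))
  invisible(x)
}
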