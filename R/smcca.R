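# Sparse multiple (multi-set) canonical correlation analysis: block
# coordinate ascent on the sum of pairwise between-set covariances under
# unit-L2 and lasso (L1) constraints on each weight vector, with
# permutation-based penalty selection.

#' Soft-thresholding operator
#'
#' Elementwise `sign(a) * max(|a| - delta, 0)`, the proximal operator of the
#' L1 penalty used inside the constrained weight update.
#'
#' @param a Numeric vector.
#' @param delta Nonnegative threshold.
#' @return Numeric vector of the same length.
#' @export
soft_threshold <- function(a, delta) {
  if (length(delta) != 1 || is.na(delta) || delta < 0)
    stopf("delta must be a single nonnegative number")
  sign(a) * pmax(abs(a) - delta, 0)
}

#' L1-constrained unit-norm weight update
#'
#' Solves `max_w w'a` subject to `||w||_2 <= 1`, `||w||_1 <= c`: the
#' solution is the soft-thresholded, L2-normalized `a` with the smallest
#' threshold `delta` satisfying the L1 bound. The L1 norm of the normalized
#' soft-thresholded vector is piecewise smooth in `delta` with knots at the
#' sorted magnitudes of `a`, so `delta` is found exactly by locating the
#' crossing interval and solving its quadratic (a bisection fallback guards
#' degenerate intervals). When the bound is unattainable for the sign
#' pattern of `a` (tied leading entries), the nearest-feasible weight is
#' returned and the L1 slack recorded.
#'
#' @param a Nonzero numeric vector.
#' @param c L1 bound, in `[1, sqrt(length(a))]`.
#' @return Unit-L2 weight vector with attributes `delta` and `slack`.
#' @export
l1_constrained_update <- function(a, c) {
  a <- as.numeric(a)
  p <- length(a)
  if (all(a == 0)) stopf("zero vector")
  if (length(c) != 1 || c < 1 - 1e-12 || c > sqrt(p) + 1e-12)
    stopf("c must lie in [1, sqrt(p)]")
  aa <- abs(a)
  l2a <- sqrt(sum(aa * aa))
  if (sum(aa) / l2a <= c + 1e-10)
    return(structure(a / l2a, delta = 0, slack = 0))
  b <- sort(aa, decreasing = TRUE)
  lead <- aa >= b[1] * (1 - 1e-12)
  ntied <- sum(lead)
  if (c <= sqrt(ntied) + 1e-10) {
    # minimum attainable L1 is sqrt(#tied leaders): nearest-feasible weight
    w <- numeric(p)
    w[lead] <- sign(a[lead]) / sqrt(ntied)
    return(structure(w, delta = b[1] * (1 - 1e-9),
                     slack = max(0, sqrt(ntied) - c)))
  }
  S <- cumsum(b)
  Q <- cumsum(b * b)
  k_seq <- seq_len(p)
  d_left <- c(b[-1], 0)
  l2v <- sqrt(pmax(Q - 2 * S * d_left + k_seq * d_left^2, 0))
  fv <- ifelse(l2v > 0, (S - k_seq * d_left) / l2v, 1)
  k <- match(TRUE, fv > c + 1e-12)      # smallest support size that violates
  d <- NA_real_
  if (!is.na(k)) {
    Sk <- S[k]; Qk <- Q[k]
    disc <- (k - c^2) * (k * Qk - Sk^2)
    if (k > c^2 && disc >= 0) {
      d <- Sk / k - c * sqrt(disc) / (k * (k - c^2))
      d <- min(max(d, d_left[k]), b[k])
    }
  }
  shrink <- function(d) {
    s <- aa - d
    s[s < 0] <- 0
    n2 <- sqrt(sum(s * s))
    if (n2 == 0) NULL else sign(a) * s / n2
  }
  w <- if (is.na(d)) NULL else shrink(d)
  if (is.null(w) || sum(abs(w)) > c + 1e-8) {
    lo <- 0
    hi <- b[1]
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      wm <- shrink(mid)
      if (is.null(wm) || sum(abs(wm)) <= c) hi <- mid else lo <- mid
      if (hi - lo < 1e-12 * b[1]) break
    }
    d <- hi
    w <- shrink(hi)
    if (is.null(w)) {
      d <- lo
      w <- shrink(lo)
    }
  }
  structure(w, delta = d, slack = max(0, sum(abs(w)) - c))
}

# penalty fractions -> per-set L1 bounds c_i in [1, sqrt(p_i)]
penalty_bounds <- function(penalty, dims) {
  K <- length(dims)
  if (length(penalty) == 1) penalty <- rep(penalty, K)
  if (length(penalty) != K) stopf("one penalty (or one per set) required")
  if (any(penalty <= 0) || any(penalty > 1))
    stopf("penalty fractions must lie in (0, 1]")
  pmin(pmax(penalty * sqrt(dims), 1), sqrt(dims))
}

# deterministic leading right singular vector of a set (from its Gram matrix)
leading_weight <- function(Cii) {
  v <- eigen(Cii, symmetric = TRUE)$vectors[, 1]
  jmax <- which.max(abs(v))
  if (v[jmax] < 0) v <- -v
  v
}

# Block-coordinate ascent given the full K x K crossproduct table
# (Call[[i]][[j]] = X_i' X_j, including i = j). Everything the iterations and
# the canonical correlations need lives in p-space, which keeps permutation
# refits cheap.
smcca_core <- function(Call, c_bounds, w_init, max_iter = 200, tol = 1e-6) {
  K <- length(c_bounds)
  w <- w_init
  objective <- function(w) {
    s <- 0
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
      s <- s + drop(crossprod(w[[i]], Call[[i]][[j]] %*% w[[j]]))
    s
  }
  trace <- objective(w)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (i in seq_len(K)) {
      a <- 0
      for (j in seq_len(K)) if (j != i)
        a <- a + Call[[i]][[j]] %*% w[[j]]
      a <- as.numeric(a)
      if (max(abs(a)) < 1e-300) next
      wi <- l1_constrained_update(a, c_bounds[i])
      attributes(wi) <- NULL
      w[[i]] <- wi
    }
    obj <- objective(w)
    trace <- c(trace, obj)
    if (abs(obj - trace[length(trace) - 1]) <= tol * max(1, abs(obj))) {
      converged <- TRUE
      break
    }
  }
  cors <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    vi <- drop(crossprod(w[[i]], Call[[i]][[i]] %*% w[[i]]))
    vj <- drop(crossprod(w[[j]], Call[[j]][[j]] %*% w[[j]]))
    cov <- drop(crossprod(w[[i]], Call[[i]][[j]] %*% w[[j]]))
    cors[i, j] <- if (vi < 1e-300 || vj < 1e-300) 0 else cov / sqrt(vi * vj)
  }
  sum_cor <- sum(cors[upper.tri(cors)])
  list(w = w, trace = trace, iterations = iter, converged = converged,
       cors = cors, sum_cor = sum_cor)
}

crossprod_table <- function(Xs) {
  K <- length(Xs)
  Call <- vector("list", K)
  for (i in seq_len(K)) {
    Call[[i]] <- vector("list", K)
    for (j in seq_len(K)) Call[[i]][[j]] <- crossprod(Xs[[i]], Xs[[j]])
  }
  Call
}

#' Sparse multiple canonical correlation analysis
#'
#' Fits K sparse weight vectors, one per feature set, maximizing the sum of
#' pairwise between-set covariances of the canonical variates `u_i = X_i w_i`
#' under `||w_i||_2 <= 1` and `||w_i||_1 <= c_i`, using block-coordinate
#' ascent with the identity within-set covariance convention of the
#' penalized multi-set formulation. Initialization is the deterministic
#' leading right singular vector of each set, so the fit needs no random
#' seed. Additional components are obtained by projecting each set onto the
#' orthogonal complement of its earlier variates and refitting.
#'
#' @param sets List of >= 2 numeric matrices sharing the participant rows.
#' @param penalty Lasso penalty as a fraction of `sqrt(p_i)` (scalar shared
#'   across sets, or one per set); the per-set bound is
#'   `c_i = penalty * sqrt(p_i)` clamped into `[1, sqrt(p_i)]`.
#' @param n_components Number of canonical components (default 1).
#' @param standardize Column-standardize each set first (default TRUE).
#' @param max_iter,tol Convergence controls: stop when the relative change of
#'   the objective falls below `tol` (default 1e-6, at most 200 sweeps).
#' @param orient Optional participant-level reference vector; all weight
#'   vectors are sign-flipped together so the first set's variate correlates
#'   positively with it (used to orient the games variate toward
#'   prosociality). Defaults to making the largest first-set weight positive.
#' @return Object of class `smcca` with per-set weight matrices, variates,
#'   pairwise canonical correlations and their sum, penalties, and the
#'   objective trace (non-decreasing by construction).
#' @export
smcca <- function(sets, penalty = 0.5, n_components = 1, standardize = TRUE,
                  max_iter = 200, tol = 1e-6, orient = NULL) {
  if (!is.list(sets) || length(sets) < 2) stopf("need a list of >= 2 sets")
  K <- length(sets)
  sets <- lapply(sets, as.matrix)
  n <- nrow(sets[[1]])
  if (any(vapply(sets, nrow, integer(1)) != n))
    stopf("all sets must share the participant rows")
  if (any(vapply(sets, anyNA, logical(1)))) stopf("missing values in sets")
  dims <- vapply(sets, ncol, integer(1))
  if (n_components > min(dims)) stopf("too many components")
  centers <- lapply(sets, colMeans)
  sds <- lapply(sets, function(x) apply(x, 2, stats::sd))
  if (standardize) {
    Xs <- lapply(seq_len(K), function(i) standardize_columns(sets[[i]],
                                                             sprintf("set %d", i)))
  } else {
    Xs <- lapply(sets, scale, scale = FALSE)
  }
  c_bounds <- penalty_bounds(penalty, dims)

  weights <- lapply(dims, function(p) matrix(0, p, n_components))
  variates <- lapply(seq_len(K), function(i) matrix(0, n, n_components))
  sum_cor <- numeric(n_components)
  cor_pairs <- vector("list", n_components)
  traces <- vector("list", n_components)
  iters <- integer(n_components)
  conv <- logical(n_components)
  Xw <- Xs
  for (comp in seq_len(n_components)) {
    Call <- crossprod_table(Xw)
    w0 <- lapply(seq_len(K), function(i) leading_weight(Call[[i]][[i]]))
    fit <- smcca_core(Call, c_bounds, w0, max_iter = max_iter, tol = tol)
    u <- lapply(seq_len(K), function(i) drop(Xw[[i]] %*% fit$w[[i]]))
    s <- if (!is.null(orient) && comp == 1) {
      cv <- stats::cov(u[[1]], orient)
      if (is.na(cv) || cv == 0) 1 else sign(cv)
    } else {
      w1 <- fit$w[[1]]
      sg <- sign(w1[which.max(abs(w1))])
      if (sg == 0) 1 else sg
    }
    for (i in seq_len(K)) {
      weights[[i]][, comp] <- s * fit$w[[i]]
      variates[[i]][, comp] <- s * u[[i]]
    }
    sum_cor[comp] <- fit$sum_cor
    cor_pairs[[comp]] <- fit$cors
    traces[[comp]] <- fit$trace
    iters[comp] <- fit$iterations
    conv[comp] <- fit$converged
    if (comp < n_components) {
      # deflate: project each set onto the complement of its variate
      Xw <- lapply(seq_len(K), function(i) {
        ui <- variates[[i]][, comp]
        den <- sum(ui^2)
        if (den < 1e-300) Xw[[i]]
        else Xw[[i]] - outer(ui, drop(crossprod(Xw[[i]], ui)) / den)
      })
    }
  }
  out <- list(weights = weights, variates = variates, sum_cor = sum_cor,
              cor_pairs = cor_pairs, penalty = penalty, c_bounds = c_bounds,
              objective_trace = traces, iterations = iters, converged = conv,
              dims = dims, n = n, n_components = n_components,
              standardize = standardize, centers = centers, sds = sds,
              set_names = names(sets) %||% paste0("set", seq_len(K)))
  class(out) <- "smcca"
  out
}

#' @export
print.smcca <- function(x, ...) {
  K <- length(x$dims)
  cat(sprintf("Sparse multiple CCA: %d sets (%s), n = %d\n", K,
              paste(sprintf("%s[%d]", x$set_names, x$dims), collapse = ", "),
              x$n))
  cat(sprintf("  penalty fraction(s): %s; L1 bounds: %s\n",
              paste(format(x$penalty, digits = 3), collapse = ", "),
              paste(format(x$c_bounds, digits = 3), collapse = ", ")))
  for (comp in seq_len(x$n_components)) {
    cp <- x$cor_pairs[[comp]]
    cat(sprintf("  component %d: sum of pairwise correlations = %.3f (%s)\n",
                comp, x$sum_cor[comp],
                paste(sprintf("rho(%d,%d)=%.2f",
                              which(upper.tri(cp), arr.ind = TRUE)[, 1],
                              which(upper.tri(cp), arr.ind = TRUE)[, 2],
                              cp[upper.tri(cp)]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.smcca <- function(object, ...) {
  nz <- vapply(object$weights, function(w) sum(w[, 1] != 0), integer(1))
  out <- list(fit = object, nonzero = nz,
              final_objective = vapply(object$objective_trace,
                                       function(tr) tr[length(tr)], numeric(1)))
  class(out) <- "summary.smcca"
  out
}

#' @export
print.summary.smcca <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  nonzero weights per set (component 1): %s\n",
              paste(x$nonzero, collapse = ", ")))
  cat(sprintf("  converged: %s after %s sweeps; final objective %s\n",
              paste(x$fit$converged, collapse = ", "),
              paste(x$fit$iterations, collapse = ", "),
              paste(format(x$final_objective, digits = 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.smcca <- function(object, set = NULL, ...) {
  if (is.null(set)) object$weights else object$weights[[set]]
}

#' @export
predict.smcca <- function(object, newdata, ...) {
  if (!is.list(newdata) || length(newdata) != length(object$dims))
    stopf("newdata must be a list with one matrix per set")
  lapply(seq_along(newdata), function(i) {
    x <- sweep(as.matrix(newdata[[i]]), 2, object$centers[[i]])
    if (object$standardize) x <- sweep(x, 2, object$sds[[i]], "/")
    x %*% object$weights[[i]]
  })
}

#' @export
plot.smcca <- function(x, component = 1, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  tr <- x$objective_trace[[component]]
  graphics::plot(seq_along(tr) - 1, tr, type = "b", xlab = "sweep",
                 ylab = "objective", main = "Block-ascent objective")
  w1 <- x$weights[[1]][, component]
  graphics::barplot(w1, main = sprintf("%s weights", x$set_names[1]),
                    ylab = "weight", border = NA)
  invisible(x)
}

#' Permutation-based penalty selection
#'
#' For each candidate penalty fraction, fits the model on the observed sets
#' and on `n_perm` row-permuted versions (each set permuted independently
#' under a fixed seed stream), converts the mean pairwise canonical
#' correlation to a Fisher z, and selects the fraction maximizing the
#' standardized gap `(z_obs - mean(z_perm)) / sd(z_perm)`.
#'
#' @param sets List of feature-score matrices.
#' @param grid Candidate penalty fractions of `sqrt(p_i)` (default 10 values
#'   equally spaced on 0.1-0.9, shared across sets).
#' @param n_perm Number of permutations (>= 2; the reference analysis used
#'   1000).
#' @param seed Integer seed for the permutation stream.
#' @param ... Passed to the fitting core (`max_iter`, `tol`).
#' @return List with `penalty` (selected fraction), `statistic`, and a
#'   diagnostics `table` over the whole grid.
#' @export
select_penalties <- function(sets, grid = seq(0.1, 0.9, length.out = 10),
                             n_perm = 1000, seed = 1, max_iter = 200,
                             tol = 1e-6) {
  if (length(grid) < 1) stopf("empty penalty grid")
  if (n_perm < 2) stopf("n_perm must be >= 2")
  sets <- lapply(sets, as.matrix)
  K <- length(sets)
  n <- nrow(sets[[1]])
  dims <- vapply(sets, ncol, integer(1))
  Xs <- lapply(seq_len(K), function(i) standardize_columns(sets[[i]],
                                                           sprintf("set %d", i)))
  n_pairs <- K * (K - 1) / 2
  fisher_z <- function(sum_cor)
    atanh(clamp(sum_cor / n_pairs, -1 + 1e-12, 1 - 1e-12))

  Cobs <- crossprod_table(Xs)
  w0 <- lapply(seq_len(K), function(i) leading_weight(Cobs[[i]][[i]]))
  obs <- vapply(grid, function(fr) {
    fit <- smcca_core(Cobs, penalty_bounds(fr, dims), w0,
                      max_iter = max_iter, tol = tol)
    fit$sum_cor
  }, numeric(1))
  z_obs <- fisher_z(obs)

  z_perm <- matrix(NA_real_, length(grid), n_perm)
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    Xp <- lapply(Xs, function(x) x[sample.int(n), , drop = FALSE])
    Cb <- crossprod_table(Xp)
    for (g in seq_along(grid)) {
      fit <- smcca_core(Cb, penalty_bounds(grid[g], dims), w0,
                        max_iter = max_iter, tol = tol)
      z_perm[g, b] <- fisher_z(fit$sum_cor)
    }
  }
  mu <- rowMeans(z_perm)
  sdv <- apply(z_perm, 1, stats::sd)
  stat <- (z_obs - mu) / pmax(sdv, 1e-8)
  best <- which.max(stat)
  list(penalty = grid[best], statistic = stat[best],
       table = data.frame(penalty = grid, sum_cor = obs, z_obs = z_obs,
                          mean_z_perm = mu, sd_z_perm = sdv, statistic = stat),
       n_perm = n_perm, seed = seed)
}
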