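# Sparse multi-set CCA: the constrained update, the block-ascent fit, the
# SVD oracle for two sets, and permutation-based penalty selection.

test_that("soft thresholding follows its definition", {
  expect_equal(soft_threshold(c(3, -3), 1), c(2, -2))
  expect_equal(soft_threshold(0.5, 1), 0)
  a <- c(-2.5, 0.1, 4)
  expect_equal(soft_threshold(a, 0), a)
  expect_error(soft_threshold(a, -1), "nonnegative")
})

test_that("the L1-constrained update finds the smallest feasible threshold", {
  # loose bound: constraint inactive
  w <- l1_constrained_update(c(3, 1), sqrt(2))
  expect_equal(as.numeric(w), c(3, 1) / sqrt(10))
  expect_equal(attr(w, "delta"), 0)
  # tight bound: only the leading coordinate survives
  w2 <- l1_constrained_update(c(3, 1), 1)
  expect_equal(as.numeric(w2), c(1, 0), tolerance = 1e-6)
  expect_equal(sum(abs(w2)), 1, tolerance = 1e-6)
  # tied entries: bound unattainable, nearest-feasible with recorded slack
  w3 <- l1_constrained_update(c(1, 1), 1)
  expect_equal(as.numeric(w3), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-6)
  expect_equal(attr(w3, "slack"), sqrt(2) - 1, tolerance = 1e-6)
  expect_error(l1_constrained_update(c(0, 0), 1), "zero vector")
  expect_error(l1_constrained_update(c(1, 2), 3), "sqrt")
  # unit L2 norm always
  set.seed(3)
  for (rep in 1:20) {
    a <- rnorm(12)
    cc <- runif(1, 1, sqrt(12))
    expect_equal(sum(l1_constrained_update(a, cc)^2), 1, tolerance = 1e-9)
  }
})

test_that("degenerate multi-set fits reach their analytic optima", {
  set.seed(1)
  x <- matrix(rnorm(30), 30, 1)
  fit <- smcca(list(x, x), penalty = 1)
  expect_equal(fit$sum_cor, 1, tolerance = 1e-9)
  y <- matrix(rnorm(30 * 3), 30, 3)
  fit3 <- smcca(list(y, y, y), penalty = 1)
  expect_equal(fit3$sum_cor, 3, tolerance = 1e-6)
})

test_that("with two sets and loose penalties the fit matches the SVD oracle", {
  set.seed(21)
  for (rep in 1:10) {
    X1 <- scale(matrix(rnorm(50 * 6), 50, 6))
    X2 <- scale(matrix(rnorm(50 * 8), 50, 8))
    fit <- smcca(list(X1, X2), penalty = 1, tol = 1e-10, max_iter = 500)
    sv <- svd(crossprod(X1, X2))
    expect_gte(abs(sum(fit$weights[[1]][, 1] * sv$u[, 1])), 0.99)
    expect_gte(abs(sum(fit$weights[[2]][, 1] * sv$v[, 1])), 0.99)
  }
})

test_that("the block-ascent objective never decreases", {
  set.seed(8)
  for (rep in 1:10) {
    sets <- lapply(c(5, 7, 6), function(p) matrix(rnorm(40 * p), 40, p))
    fit <- smcca(sets, penalty = runif(1, 0.3, 0.9))
    expect_true(all(diff(fit$objective_trace[[1]]) >= -1e-8))
  }
})

test_that("weights respect the unit-norm and lasso constraints", {
  set.seed(12)
  sets <- lapply(c(10, 12), function(p) matrix(rnorm(60 * p), 60, p))
  fit <- smcca(sets, penalty = 0.4)
  for (i in 1:2) {
    w <- fit$weights[[i]][, 1]
    expect_lte(sum(w^2), 1 + 1e-8)
    expect_lte(sum(abs(w)), fit$c_bounds[i] + 1e-6)
  }
})

test_that("an identical row permutation of all sets leaves the fit unchanged", {
  set.seed(31)
  sets <- lapply(c(6, 5, 7), function(p) matrix(rnorm(45 * p), 45, p))
  fit <- smcca(sets, penalty = 0.6)
  perm <- sample(45)
  fitp <- smcca(lapply(sets, function(x) x[perm, ]), penalty = 0.6)
  expect_equal(fitp$sum_cor, fit$sum_cor, tolerance = 1e-8)
  expect_equal(fitp$weights, fit$weights, tolerance = 1e-6)
})

test_that("permuting one set alone destroys a planted association", {
  set.seed(17)
  n <- 120
  theta <- rnorm(n)
  mk <- function() theta %*% t(runif(6, 0.5, 1)) + matrix(rnorm(n * 6), n, 6)
  # two sets: breaking one removes every cross-set pair
  pair <- list(mk(), mk())
  obs2 <- smcca(pair, penalty = 0.8)$sum_cor
  perm2 <- vapply(1:20, function(b) {
    p2 <- pair
    p2[[2]] <- p2[[2]][sample(n), ]
    smcca(p2, penalty = 0.8)$sum_cor
  }, numeric(1))
  expect_gt(obs2, 0.7)
  expect_lt(mean(abs(perm2)), 0.3)
  # three sets: the pairs not involving the shuffled set survive, so the sum
  # drops but stays clear of zero
  sets <- list(mk(), mk(), mk())
  obs3 <- smcca(sets, penalty = 0.8)$sum_cor
  perm3 <- vapply(1:20, function(b) {
    s2 <- sets
    s2[[2]] <- s2[[2]][sample(n), ]
    smcca(s2, penalty = 0.8)$sum_cor
  }, numeric(1))
  expect_gt(obs3, max(perm3))
})

test_that("multiple components deflate and stay correlated in order", {
  set.seed(41)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  mk <- function() cbind(f1 + 0.3 * rnorm(n), f1 + 0.3 * rnorm(n),
                         0.6 * f2 + 0.4 * rnorm(n), 0.6 * f2 + 0.4 * rnorm(n),
                         matrix(rnorm(n * 2), n, 2))
  fit <- smcca(list(mk(), mk()), penalty = 1, n_components = 2)
  expect_gt(fit$sum_cor[1], fit$sum_cor[2])
  expect_gt(fit$sum_cor[2], 0.2)
})

test_that("penalty selection handles trivial grids and rejects bad input", {
  set.seed(6)
  sets <- lapply(c(5, 6), function(p) matrix(rnorm(40 * p), 40, p))
  sel <- select_penalties(sets, grid = 0.5, n_perm = 10, seed = 2)
  expect_equal(sel$penalty, 0.5)
  expect_equal(nrow(sel$table), 1)
  expect_error(select_penalties(sets, grid = numeric(0)), "empty")
  expect_error(select_penalties(sets, grid = 0.5, n_perm = 1), "n_perm")
})

test_that("pure-noise sets give a near-null selection statistic", {
  set.seed(14)
  stats <- vapply(1:8, function(r) {
    sets <- lapply(c(5, 5, 5), function(p) matrix(rnorm(60 * p), 60, p))
    sel <- select_penalties(sets, grid = c(0.3, 0.6, 0.9), n_perm = 50,
                            seed = r)
    sel$statistic
  }, numeric(1))
  expect_gte(sum(abs(stats) <= 3), 7)
})

test_that("penalty selection recovers a planted sparse support", {
  set.seed(25)
  n <- 217
  theta <- rnorm(n)
  supp <- 1:4
  mk <- function() {
    x <- matrix(rnorm(n * 16), n, 16)
    x[, supp] <- x[, supp] + theta %*% t(c(1.5, 1.2, 1.0, 0.8))
    x
  }
  sets <- list(mk(), mk(), mk())
  sel <- select_penalties(sets, grid = seq(0.1, 0.9, length.out = 5),
                          n_perm = 30, seed = 3)
  fit <- smcca(sets, penalty = sel$penalty)
  for (i in 1:3) {
    est <- which(fit$weights[[i]][, 1] != 0)
    jac <- length(intersect(est, supp)) / length(union(est, supp))
    expect_gte(jac, 0.5)
  }
})

test_that("smcca methods expose the fit", {
  set.seed(2)
  sets <- list(g = matrix(rnorm(40 * 5), 40, 5), b = matrix(rnorm(40 * 6), 40, 6))
  fit <- smcca(sets, penalty = 0.7)
  expect_s3_class(fit, "smcca")
  expect_output(print(fit), "Sparse multiple CCA")
  expect_output(print(summary(fit)), "nonzero")
  expect_length(coef(fit), 2)
  pr <- predict(fit, sets)
  expect_equal(pr[[1]][, 1], fit$variates[[1]][, 1], tolerance = 1e-8)
})

test_that("the closed-form update agrees with a bisection oracle", {
  set.seed(77)
  for (rep in 1:60) {
    p <- sample(2:25, 1)
    a <- rnorm(p)
    if (rep %% 4 == 0) a[1:2] <- max(abs(a)) * c(1, 1)  # force ties
    cc <- runif(1, 1, sqrt(p))
    w <- l1_constrained_update(a, cc)
    expect_equal(as.numeric(w), oracle_l1_update(a, cc), tolerance = 1e-5)
    expect_equal(sum(w^2), 1, tolerance = 1e-9)
  }
})
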