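# Connectivity construction, cost-efficiency thresholding and nodal graph
# measures, checked against hand computations and the brute-force oracle.

test_that("Pearson connectivity matches hand computation", {
  ts <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1), d = c(1, 2, 4))
  cm <- correlation_matrix(ts)
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_equal(cm["a", "d"], 3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_error(correlation_matrix(ts[1:2, ]), "3 time points")
  expect_error(correlation_matrix(cbind(ts, e = c(2, 2, 2))), "constant")
})

test_that("tractography normalization divides rows and symmetrizes", {
  counts <- rbind(c(0, 10, 0, 10), c(20, 0, 0, 0), c(0, 40, 0, 0), c(0, 0, 0, 0))
  m <- normalize_tractography(counts, c(1000, 1000, 1000, 1000))
  expect_equal(m[1, 2], (10 / 1000 + 20 / 1000) / 2)
  expect_equal(m[2, 3], (0 + 40 / 1000) / 2)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_equal(normalize_tractography(matrix(0, 3, 3), rep(5, 3)),
               matrix(0, 3, 3))
  # declared symmetrization rule on an asymmetric pair
  a <- matrix(0, 3, 3); a[1, 2] <- 20; a[2, 1] <- 40
  expect_equal(normalize_tractography(a, rep(1000, 3))[1, 2], 0.03)
  expect_error(normalize_tractography(counts, c(0, 1, 1, 1)), "waytotal")
  expect_error(normalize_tractography(-counts, rep(1, 4)), "negative")
})

test_that("cost-efficiency threshold agrees with brute force on a 3-node chain", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[2, 3] <- w[3, 2] <- 0.8
  # brute force over both candidate thresholds
  ce_of <- function(A) {
    D <- oracle_distances(A)
    inv <- 1 / D; diag(inv) <- 0
    sum(inv) / 6 - sum(A) / 2 / 3
  }
  A_top <- (w >= 0.9) * 1
  A_both <- (w >= 0.8) * 1
  expect_lt(ce_of(A_top), ce_of(A_both))
  r <- threshold_cost_efficiency(w)
  expect_equal(r$threshold, 0.8)
  expect_equal(unname(r$adjacency), A_both)
  expect_equal(r$cost_efficiency, ce_of(A_both), tolerance = 1e-12)
  # degenerate candidate set: complete graph with equal weights
  w2 <- matrix(0.5, 4, 4); diag(w2) <- 0
  r2 <- threshold_cost_efficiency(w2)
  expect_equal(r2$threshold, 0.5)
  expect_equal(r2$cost, 1)
  expect_error(threshold_cost_efficiency(matrix(0, 4, 4)), "all-zero")
})

test_that("threshold choice is invariant to monotone weight transformations", {
  set.seed(42)
  for (rep in 1:10) {
    w <- matrix(0, 8, 8)
    w[upper.tri(w)] <- rnorm(28)
    w <- w + t(w)
    r1 <- threshold_cost_efficiency(w)
    w2 <- sign(w) * abs(w)^1.7           # monotone on magnitudes
    r2 <- threshold_cost_efficiency(w2)
    expect_equal(r1$adjacency, r2$adjacency)
    r3 <- threshold_cost_efficiency(w, candidates = "grid", n_grid = 10)
    r4 <- threshold_cost_efficiency(w2, candidates = "grid", n_grid = 10)
    expect_equal(r3$adjacency, r4$adjacency)
  }
})

test_that("nodal measures match hand-enumerated examples", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(tri), rep(1, 3))
  expect_equal(local_efficiency(tri), rep(1, 3))
  star3 <- matrix(0, 4, 4); star3[1, 2:4] <- 1; star3 <- star3 + t(star3)
  expect_equal(clustering_coefficient(star3, 1), 0)
  # 4-node graph {12, 13, 14, 23}: node 1 has 3 neighbors and 1 triangle
  g4 <- matrix(0, 4, 4)
  g4[1, 2] <- g4[1, 3] <- g4[1, 4] <- g4[2, 3] <- 1
  g4 <- g4 + t(g4)
  expect_equal(clustering_coefficient(g4, 1), 1 / 3)
  # star plus edge {2,3}: center neighbor subgraph has one of three pairs linked
  s4 <- star3; s4[2, 3] <- s4[3, 2] <- 1
  expect_equal(local_efficiency(s4, 1), 1 / 3)
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  expect_equal(local_efficiency(p3, 2), 0)
  expect_equal(as.numeric(nodal_path_length(p3, 1)), 1.5)
  expect_equal(as.numeric(nodal_path_length(p3, 2)), 1)
  c4 <- matrix(0, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  c4 <- c4 + t(c4)
  expect_equal(as.numeric(nodal_path_length(c4)), rep(4 / 3, 4))
  expect_equal(betweenness_centrality(p3, 2), 1)
  expect_equal(betweenness_centrality(p3, 1), 0)
  star4 <- matrix(0, 5, 5); star4[1, 2:5] <- 1; star4 <- star4 + t(star4)
  expect_equal(betweenness_centrality(star4, 1), 6)
  expect_error(clustering_coefficient(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("isolated nodes are flagged in nodal path length", {
  a <- matrix(0, 4, 4); a[1, 2] <- a[2, 1] <- 1
  L <- nodal_path_length(a)
  expect_true(is.na(L[3]) && is.na(L[4]))
  expect_equal(as.numeric(L[1]), 1)
  expect_equal(attr(L, "n_unreachable")[1], 2)
})

test_that("all five measures agree exactly with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(4:11, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.7))
    expect_equal(clustering_coefficient(A), oracle_clustering(A))
    expect_equal(local_efficiency(A), oracle_local_efficiency(A))
    expect_equal(as.numeric(nodal_path_length(A)), oracle_path_length(A))
    expect_equal(unname(rowSums(A)), colSums(A != 0) + 0)
    expect_equal(betweenness_centrality(A), oracle_betweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("measures stay in range and efficiency is edge-monotone", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(5:10, 1)
    A <- random_adjacency(n, 0.4)
    expect_true(all(clustering_coefficient(A) >= 0 & clustering_coefficient(A) <= 1))
    expect_true(all(local_efficiency(A) >= 0 & local_efficiency(A) <= 1))
    eg <- global_efficiency_from_distances(graph_distances(A))
    # add one absent edge
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    A2 <- A; A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1
    eg2 <- global_efficiency_from_distances(graph_distances(A2))
    expect_gte(eg2, eg)
    expect_true(all(rowSums(A2) >= rowSums(A)))
  }
})

test_that("homotopic interhemispheric values are extracted by pair", {
  lab <- c("L_A", "L_B", "R_A", "R_B")
  w <- matrix(0, 4, 4, dimnames = list(lab, lab))
  w[1, 3] <- w[3, 1] <- 0.7
  w[2, 4] <- w[4, 2] <- -0.2
  ih <- interhemispheric_connectivity(w)
  expect_equal(ih, c(A = 0.7, B = -0.2))
  expect_equal(unname(interhemispheric_connectivity(diag(4) * 0, lab)),
               c(0, 0))
  expect_error(interhemispheric_connectivity(w, c("L_A", "L_B", "R_A", "R_C")),
               "unpaired")
})

test_that("the nodal metric driver returns complete tables", {
  set.seed(5)
  w <- matrix(0, 10, 10)
  w[upper.tri(w)] <- runif(45)
  w <- w + t(w)
  met <- nodal_metrics(w, candidates = "grid", n_grid = 15)
  expect_equal(nrow(met), 10)
  expect_named(met, c("node", "degree", "clustering", "local_efficiency",
                      "path_length", "betweenness"))
  expect_false(anyNA(met))
  expect_true(attr(met, "cost") > 0 && attr(met, "cost") <= 1)
})
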