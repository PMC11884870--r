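# Independent brute-force graph oracle: queue-based BFS distances, explicit
# triangle counting, and betweenness by shortest-path enumeration. Kept free
# of any package internals so it can certify them.

oracle_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in which(A[u, ] != 0)) {
      if (!is.finite(d[v])) {
        d[v] <- d[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  d
}

oracle_distances <- function(A) {
  t(vapply(seq_len(nrow(A)), function(s) oracle_bfs(A, s),
           numeric(nrow(A))))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] != 0) links <- links + 1
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    D <- oracle_distances(A[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  vapply(seq_len(nrow(A)), function(i) {
    d <- D[i, -i]
    fin <- is.finite(d)
    if (!any(fin)) NA_real_ else mean(d[fin])
  }, numeric(1))
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (v in order(D[s, ])) {
      if (v == s || !is.finite(D[s, v])) next
      preds <- which(A[v, ] != 0 & D[s, ] == D[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t0 in (s + 1):n) {
        if (s == i || t0 == i || !is.finite(D[s, t0])) next
        if (is.finite(D[s, i]) && is.finite(D[i, t0]) &&
            D[s, i] + D[i, t0] == D[s, t0]) {
          b[i] <- b[i] + sigma[s, i] * sigma[i, t0] / sigma[s, t0]
        }
      }
    }
  }
  b
}

random_adjacency <- function(n, prob) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, prob)
  A + t(A)
}

# independent bisection oracle for the L1-constrained unit-norm update
oracle_l1_update <- function(a, c) {
  unit <- function(v) {
    n2 <- sqrt(sum(v^2))
    if (n2 == 0) NULL else v / n2
  }
  st <- function(a, d) sign(a) * pmax(abs(a) - d, 0)
  w0 <- unit(st(a, 0))
  if (sum(abs(w0)) <= c + 1e-10) return(w0)
  lo <- 0; hi <- max(abs(a))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    wm <- unit(st(a, mid))
    if (is.null(wm) || sum(abs(wm)) <= c) hi <- mid else lo <- mid
  }
  w <- unit(st(a, hi))
  if (is.null(w)) w <- unit(st(a, lo))
  w
}
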