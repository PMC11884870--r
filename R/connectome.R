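# Connectivity matrices, cost-efficiency thresholding and nodal graph
# measures (segregation, integration, centrality) plus homotopic
# interhemispheric connectivity.

check_symmetric <- function(adj, what = "adjacency", tol = 1e-10) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stopf("%s must be a square matrix", what)
  if (max(abs(adj - t(adj))) > tol)
    stopf("%s must be symmetric", what)
  invisible(adj)
}

#' Pearson functional connectivity matrix
#'
#' @param time_series Numeric matrix, time points x nodes (>= 3 time points,
#'   no constant series).
#' @return Symmetric node x node Pearson correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(time_series) {
  ts <- as.matrix(time_series)
  if (nrow(ts) < 3) stopf("need at least 3 time points")
  if (anyNA(ts)) stopf("time series contain missing values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) stopf("constant node series")
  stats::cor(ts)
}

#' Waytotal normalization and symmetrization of a tractography matrix
#'
#' Divides each row of the streamline-count matrix by the corresponding
#' waytotal, then symmetrizes as (M + t(M))/2 for graph analysis. The
#' diagonal is zeroed.
#'
#' @param counts Nonnegative node x node streamline counts.
#' @param waytotal Positive per-row totals.
#' @return Symmetric normalized connectivity matrix.
#' @export
normalize_tractography <- function(counts, waytotal) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("negative streamline counts")
  if (length(waytotal) != nrow(counts)) stopf("one waytotal per row required")
  if (any(waytotal <= 0)) stopf("zero or negative waytotal")
  m <- counts / waytotal
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- dimnames(counts)
  m
}

# All-pairs shortest-path hop distances of a binary graph. Dense matrix-power
# BFS for small graphs (fast in-R for the threshold sweep); igraph for large.
graph_distances <- function(adj) {
  n <- nrow(adj)
  A <- (adj != 0) * 1
  diag(A) <- 0
  if (n > 128) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             diag = FALSE)
    return(igraph::distances(g))
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  k <- 0L
  repeat {
    k <- k + 1L
    nxt <- ((reach %*% A) > 0) | reach
    new <- nxt & !reach
    if (!any(new)) break
    D[new] <- k
    reach <- nxt
    if (k >= n) break
  }
  D
}

global_efficiency_from_distances <- function(D) {
  n <- nrow(D)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Binarize a connectivity matrix at the maximal global cost efficiency
#'
#' Sweeps candidate thresholds over the (absolute) edge weights; for each
#' threshold the network is binarized, its cost kappa (edge density) and
#' global efficiency E_glob (mean inverse shortest-path length over ordered
#' node pairs, with 1/Inf = 0) are computed, and the threshold maximizing
#' cost efficiency CE = E_glob - kappa is returned. Ties are broken toward
#' lower cost. The selection is invariant to monotone transformations of the
#' weights.
#'
#' @param w Symmetric weight matrix (diagonal ignored), >= 3 nodes.
#' @param candidates `"unique"` sweeps every distinct edge-weight magnitude;
#'   `"grid"` sweeps `n_grid` order-statistic quantiles of the magnitudes (a
#'   cost-grid sweep, used for large networks).
#' @param n_grid Number of grid candidates when `candidates = "grid"`.
#' @param positive_only If TRUE, only positive weights are considered edges;
#'   by default negative correlations count by magnitude.
#' @return List with `adjacency` (binary matrix), `threshold`, `cost`,
#'   `global_efficiency`, `cost_efficiency`, and the full candidate `table`.
#' @export
threshold_cost_efficiency <- function(w, candidates = c("unique", "grid"),
                                      n_grid = 50, positive_only = FALSE) {
  candidates <- match.arg(candidates)
  check_symmetric(w, "weight matrix")
  n <- nrow(w)
  if (n < 3) stopf("need at least 3 nodes")
  mag <- if (positive_only) pmax(w, 0) else abs(w)
  diag(mag) <- 0
  vals <- mag[upper.tri(mag)]
  vals <- vals[vals > 0]
  if (length(vals) == 0) stopf("all-zero connectivity matrix")
  thr <- sort(unique(vals), decreasing = TRUE)
  if (candidates == "grid" && length(thr) > n_grid) {
    thr <- sort(unique(stats::quantile(vals, probs = seq(0, 1, length.out = n_grid),
                                       type = 1, names = FALSE)),
                decreasing = TRUE)
  }
  n_pairs <- n * (n - 1) / 2
  best <- NULL
  tab <- matrix(NA_real_, length(thr), 4,
                dimnames = list(NULL, c("threshold", "cost", "e_glob", "ce")))
  for (j in seq_along(thr)) {
    A <- (mag >= thr[j]) * 1
    cost <- sum(A[upper.tri(A)]) / n_pairs
    eg <- global_efficiency_from_distances(graph_distances(A))
    ce <- eg - cost
    tab[j, ] <- c(thr[j], cost, eg, ce)
    # descending thresholds: strict improvement keeps the lowest-cost optimum
    if (is.null(best) || ce > best$cost_efficiency + 1e-12) {
      best <- list(adjacency = A, threshold = thr[j], cost = cost,
                   global_efficiency = eg, cost_efficiency = ce)
    }
  }
  dimnames(best$adjacency) <- dimnames(w)
  best$table <- as.data.frame(tab)
  best
}

binary_adj <- function(adj, what) {
  check_symmetric(adj, what)
  A <- (adj != 0) * 1
  diag(A) <- 0
  A
}

#' Nodal clustering coefficient
#'
#' C_i = 2 t_i / (k_i (k_i - 1)) where t_i is the number of triangles through
#' node i; 0 for nodes with degree < 2.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param node Optional node index; all nodes when NULL.
#' @return Numeric vector (or scalar) in [0, 1].
#' @export
clustering_coefficient <- function(adj, node = NULL) {
  A <- binary_adj(adj, "adjacency")
  k <- rowSums(A)
  closed <- diag(A %*% A %*% A)        # = 2 * triangles per node
  C <- ifelse(k < 2, 0, closed / (k * (k - 1)))
  if (is.null(node)) C else C[node]
}

#' Nodal local efficiency
#'
#' Efficiency of the subgraph induced by a node's neighbors: the mean over
#' neighbor pairs of the inverse shortest-path distance within that subgraph
#' (1/Inf = 0); 0 for nodes with degree < 2.
#'
#' @inheritParams clustering_coefficient
#' @return Numeric vector (or scalar) in [0, 1].
#' @export
local_efficiency <- function(adj, node = NULL) {
  A <- binary_adj(adj, "adjacency")
  nodes <- if (is.null(node)) seq_len(nrow(A)) else node
  out <- vapply(nodes, function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency_from_distances(graph_distances(A[nb, nb, drop = FALSE]))
  }, numeric(1))
  if (is.null(node)) out else unname(out)
}

#' Nodal path length
#'
#' Mean shortest-path hop distance from a node to all other reachable nodes.
#' Unreachable targets are excluded; the number of unreachable targets is
#' recorded in the `"n_unreachable"` attribute, and a fully isolated node
#' yields NA.
#'
#' @inheritParams clustering_coefficient
#' @param method `"arithmetic"` (mean distance, default) or `"harmonic"`
#'   (inverse of the node's efficiency, defined for disconnected targets).
#' @return Numeric vector (or scalar) >= 1, with attribute `n_unreachable`.
#' @export
nodal_path_length <- function(adj, node = NULL,
                              method = c("arithmetic", "harmonic")) {
  method <- match.arg(method)
  A <- binary_adj(adj, "adjacency")
  D <- graph_distances(A)
  n <- nrow(A)
  nodes <- if (is.null(node)) seq_len(n) else node
  unreach <- integer(length(nodes))
  L <- vapply(seq_along(nodes), function(ix) {
    d <- D[nodes[ix], -nodes[ix]]
    fin <- is.finite(d)
    unreach[ix] <<- sum(!fin)
    if (!any(fin)) return(NA_real_)
    if (method == "arithmetic") mean(d[fin]) else 1 / mean(1 / d)
  }, numeric(1))
  structure(if (is.null(node)) L else unname(L), n_unreachable = unreach)
}

#' Nodal betweenness centrality
#'
#' Unnormalized betweenness: the sum over node pairs (s, t) of the fraction
#' of shortest s-t paths passing through the node. Computed with igraph.
#'
#' @inheritParams clustering_coefficient
#' @return Nonnegative numeric vector (or scalar).
#' @export
betweenness_centrality <- function(adj, node = NULL) {
  A <- binary_adj(adj, "adjacency")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  b <- as.numeric(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
  if (is.null(node)) b else b[node]
}

#' All five nodal graph measures at the cost-efficiency-optimal threshold
#'
#' Binarizes a weighted connectivity matrix at the threshold maximizing
#' global cost efficiency and computes segregation (clustering coefficient,
#' local efficiency), integration (nodal path length) and centrality (degree,
#' betweenness) for every node. Isolated-node path lengths (NA) are replaced
#' by the largest finite nodal path length in the graph so that downstream
#' feature tables are complete; the substitution count is recorded.
#'
#' @param w Symmetric weight matrix.
#' @inheritParams threshold_cost_efficiency
#' @return data.frame with columns `node`, `degree`, `clustering`,
#'   `local_efficiency`, `path_length`, `betweenness`; attributes
#'   `threshold`, `cost`, `global_efficiency`, `n_path_imputed`.
#' @export
nodal_metrics <- function(w, candidates = c("unique", "grid"), n_grid = 50,
                          positive_only = FALSE) {
  th <- threshold_cost_efficiency(w, candidates = candidates, n_grid = n_grid,
                                  positive_only = positive_only)
  A <- th$adjacency
  L <- nodal_path_length(A)
  n_imp <- sum(is.na(L))
  if (n_imp > 0) {
    worst <- if (all(is.na(L))) nrow(A) - 1 else max(L, na.rm = TRUE)
    L[is.na(L)] <- worst
  }
  out <- data.frame(
    node = colnames(A) %||% seq_len(nrow(A)),
    degree = rowSums(A),
    clustering = clustering_coefficient(A),
    local_efficiency = local_efficiency(A),
    path_length = as.numeric(L),
    betweenness = betweenness_centrality(A),
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- th$threshold
  attr(out, "cost") <- th$cost
  attr(out, "global_efficiency") <- th$global_efficiency
  attr(out, "n_path_imputed") <- n_imp
  out
}

#' Homotopic pair table from hemisphere-prefixed labels
#' @param labels Parcel labels with L_/R_ prefixes.
#' @return data.frame with columns `pair`, `left`, `right` (indices).
#' @export
homotopic_pairs <- function(labels) {
  left <- grep("^L_", labels)
  right <- grep("^R_", labels)
  if (length(left) == 0 || length(left) + length(right) != length(labels))
    stopf("labels must all carry L_/R_ prefixes")
  suffix <- sub("^L_", "", labels[left])
  ridx <- match(paste0("R_", suffix), labels)
  if (anyNA(ridx))
    stopf("unpaired parcel label(s): %s",
          paste(suffix[is.na(ridx)], collapse = ", "))
  data.frame(pair = suffix, left = left, right = ridx,
             stringsAsFactors = FALSE)
}

#' Homotopic interhemispheric connectivity values
#'
#' Extracts, for every homotopic parcel pair, the weighted connectivity entry
#' between the left and right instance of the parcel (the pre-threshold
#' matrix for functional data; the symmetrized normalized matrix for
#' structural data).
#'
#' @param w Weighted connectivity matrix with hemisphere-labelled dimnames
#'   (or supply `labels`).
#' @param labels Optional parcel labels overriding `dimnames(w)`.
#' @return Named numeric vector, one value per homotopic pair.
#' @export
interhemispheric_connectivity <- function(w, labels = NULL) {
  labels <- labels %||% rownames(w)
  if (is.null(labels)) stopf("parcel labels are required")
  hp <- homotopic_pairs(labels)
  stats::setNames(w[cbind(hp$left, hp$right)], hp$pair)
}

#' Connectome-derived feature tables for a whole study
#'
#' Runs cost-efficiency thresholding and nodal graph measures on every
#' participant's functional matrix and waytotal-normalized structural matrix,
#' and extracts homotopic interhemispheric values from the weighted matrices.
#'
#' @param study A `synthetic_study` (or a list with the same `matrices` and
#'   `labels` fields).
#' @inheritParams threshold_cost_efficiency
#' @return List with `metrics_f`, `metrics_s` (participants x 5*regions, in
#'   measure-major order), `ih_f`, `ih_s` (participants x pairs).
#' @export
connectome_features <- function(study, candidates = c("unique", "grid"),
                                n_grid = 50, positive_only = FALSE) {
  candidates <- match.arg(candidates)
  fun <- study$matrices$functional
  cnt <- study$matrices$structural_counts
  wt <- study$matrices$waytotal
  if (is.null(fun) || is.null(cnt) || is.null(wt))
    stopf("study lacks connectivity matrices for one or both modalities")
  n <- length(fun)
  labels <- study$labels
  R <- length(labels)
  hp <- homotopic_pairs(labels)
  metrics_f <- matrix(0, n, 5 * R)
  metrics_s <- matrix(0, n, 5 * R)
  ih_f <- matrix(0, n, nrow(hp))
  ih_s <- matrix(0, n, nrow(hp))
  pack <- function(met) c(met$clustering, met$local_efficiency,
                          met$path_length, met$degree, met$betweenness)
  for (i in seq_len(n)) {
    Wf <- fun[[i]]
    ih_f[i, ] <- Wf[cbind(hp$left, hp$right)]
    Wg <- Wf; diag(Wg) <- 0
    metrics_f[i, ] <- pack(nodal_metrics(Wg, candidates = candidates,
                                         n_grid = n_grid,
                                         positive_only = positive_only))
    Ws <- normalize_tractography(cnt[[i]], wt[i, ])
    ih_s[i, ] <- Ws[cbind(hp$left, hp$right)]
    metrics_s[i, ] <- pack(nodal_metrics(Ws, candidates = candidates,
                                         n_grid = n_grid))
  }
  list(metrics_f = metrics_f, metrics_s = metrics_s, ih_f = ih_f, ih_s = ih_s)
}
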