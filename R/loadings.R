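# Canonical cross-loadings: correlations of the original residualized
# variables with the other sets' canonical variates, with per-metric-class
# summaries, top-fraction region maps and the myelin-thickness loading
# correlation.

#' Canonical cross-loadings of variables on a variate
#'
#' Pearson correlation of each (residualized) variable with the designated
#' canonical variate of another set. Constant columns give an undefined
#' loading: they are returned as NA, flagged, and excluded from summaries.
#'
#' @param x Participants x variables matrix.
#' @param variate Participant-level canonical variate (non-constant).
#' @return Named numeric vector of loadings in [-1, 1] (NA where undefined),
#'   with attribute `flagged` naming excluded columns.
#' @export
cross_loadings <- function(x, variate) {
  x <- as.matrix(x)
  if (length(variate) != nrow(x)) stopf("variate length must match rows")
  if (stats::sd(variate) == 0) stopf("variate is constant")
  sds <- apply(x, 2, stats::sd)
  out <- rep(NA_real_, ncol(x))
  ok <- sds > 0
  out[ok] <- as.numeric(stats::cor(x[, ok, drop = FALSE], variate))
  names(out) <- colnames(x)
  structure(out, flagged = colnames(x)[!ok])
}

#' Summary of loadings within one metric class
#'
#' Mean loading across the class's regions, its normal-approximation 95%
#' confidence interval (mean +/- 1.96 sd / sqrt(m)), and the percentage of
#' regions with positive and negative loadings (exact zeros count as
#' positive).
#'
#' @param loadings Numeric vector of regional loadings (length >= 2; NAs
#'   dropped).
#' @return List with `mean`, `ci` (length 2), `pct_positive`,
#'   `pct_negative`, `n`, and `degenerate` (TRUE when all loadings are
#'   identical, giving a zero-width interval).
#' @export
summarize_metric_class <- function(loadings) {
  loadings <- loadings[!is.na(loadings)]
  m <- length(loadings)
  if (m < 2) stopf("need at least 2 regions")
  mu <- mean(loadings)
  se <- stats::sd(loadings) / sqrt(m)
  list(mean = mu, ci = c(mu - 1.96 * se, mu + 1.96 * se),
       pct_positive = 100 * mean(loadings >= 0),
       pct_negative = 100 * mean(loadings < 0),
       n = m, degenerate = se == 0)
}

#' Top-fraction region map
#'
#' Regions whose loading, in the metric's dominant sign direction, ranks in
#' the top `ceiling(fraction * m)`. The dominant direction is the sign of
#' the mean loading.
#'
#' @param loadings Named numeric vector of regional loadings.
#' @param fraction Fraction in (0, 1] (default 0.30).
#' @return Character vector of selected region names (indices when unnamed).
#' @export
top_fraction_map <- function(loadings, fraction = 0.30) {
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 || fraction > 1)
    stopf("fraction must lie in (0, 1]")
  loadings <- loadings[!is.na(loadings)]
  m <- length(loadings)
  k <- ceiling(fraction * m)
  dir <- sign(mean(loadings))
  if (dir == 0) dir <- 1
  ranked <- order(dir * loadings, decreasing = TRUE)
  sel <- ranked[seq_len(k)]
  nm <- names(loadings) %||% as.character(seq_len(m))
  nm[sel]
}

#' Correlation between two loading maps with a Fisher-z interval
#'
#' Pearson correlation of two regional loading vectors over the same regions
#' with its 95% confidence interval from the Fisher z-transform with m - 3
#' degrees of freedom (used for the myelin-thickness loading comparison).
#'
#' @param loadings_a,loadings_b Equal-length non-constant numeric vectors.
#' @return List with `r`, `ci` (length 2), `n`.
#' @export
loading_correlation <- function(loadings_a, loadings_b) {
  ok <- !is.na(loadings_a) & !is.na(loadings_b)
  a <- loadings_a[ok]; b <- loadings_b[ok]
  m <- length(a)
  if (length(b) != m || m < 4) stopf("need >= 4 paired regions")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("constant loading vector")
  r <- stats::cor(a, b)
  z <- atanh(clamp(r, -1 + 1e-15, 1 - 1e-15))
  hw <- 1.96 / sqrt(m - 3)
  list(r = r, ci = tanh(c(z - hw, z + hw)), n = m)
}

#' Full cross-loading report for an assembled analysis
#'
#' Loads every brain variable against the games-set canonical variate, and
#' every game variable against each brain-set variate (averaged across the
#' brain sets, per-set values retained). Produces per-metric-class summaries,
#' top-fraction region maps and the myelin-thickness loading correlation.
#'
#' @param blocks Named list of residualized `feature_set` objects:
#'   `games` plus the three brain blocks.
#' @param variates Named list of participant-level canonical variates, one
#'   per block (same names as `blocks`).
#' @param fraction Top-map fraction (default 0.30).
#' @return Object of class `cross_loading_report`: per-variable loading
#'   table, `class_summary` data.frame, `top_maps`, and
#'   `myelin_thickness_cor`.
#' @export
cross_loading_report <- function(blocks, variates, fraction = 0.30) {
  stopifnot("games" %in% names(blocks))
  brain_names <- setdiff(names(blocks), "games")
  u_games <- variates[["games"]]

  tabs <- list()
  for (bn in brain_names) {
    ld <- cross_loadings(blocks[[bn]]$x, u_games)
    tabs[[bn]] <- cbind(blocks[[bn]]$meta,
                        data.frame(loading = as.numeric(ld), block = bn))
  }
  # game variables against each brain variate, averaged
  per_set <- sapply(brain_names, function(bn)
    as.numeric(cross_loadings(blocks$games$x, variates[[bn]])))
  game_tab <- cbind(blocks$games$meta,
                    data.frame(loading = rowMeans(per_set), block = "games"))
  game_per_set <- data.frame(variable = blocks$games$meta$column, per_set)

  brain_tab <- do.call(rbind, tabs)
  rownames(brain_tab) <- NULL

  # per-metric-class summaries; subcortical splits into its subclasses
  cls <- ifelse(brain_tab$class == "subcortical",
                brain_tab$subclass, brain_tab$class)
  classes <- unique(cls)
  summ <- lapply(classes, function(cl) {
    s <- summarize_metric_class(brain_tab$loading[cls == cl])
    data.frame(class = cl, mean = s$mean, ci_lo = s$ci[1], ci_hi = s$ci[2],
               pct_positive = s$pct_positive, pct_negative = s$pct_negative,
               n = s$n)
  })
  class_summary <- do.call(rbind, summ)

  top_maps <- lapply(stats::setNames(classes, classes), function(cl) {
    ld <- stats::setNames(brain_tab$loading[cls == cl],
                          brain_tab$region[cls == cl])
    if (sum(!is.na(ld)) < 2) return(character(0))
    top_fraction_map(ld, fraction)
  })

  myl <- brain_tab[brain_tab$class == "myelin", ]
  thk <- brain_tab[brain_tab$class == "thickness", ]
  mt <- NULL
  if (nrow(myl) >= 4 && nrow(thk) >= 4) {
    thk_ld <- thk$loading[match(myl$region, thk$region)]
    mt <- loading_correlation(myl$loading, thk_ld)
  }
  out <- list(brain = brain_tab, games = game_tab,
              games_per_set = game_per_set, class_summary = class_summary,
              top_maps = top_maps, myelin_thickness_cor = mt,
              fraction = fraction)
  class(out) <- "cross_loading_report"
  out
}

#' @export
print.cross_loading_report <- function(x, ...) {
  cat("Canonical cross-loading report\n")
  cs <- x$class_summary
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-22s mean %+.3f (95%% CI %+.3f to %+.3f), %3.0f%% positive (m=%d)\n",
                cs$class[i], cs$mean[i], cs$ci_lo[i], cs$ci_hi[i],
                cs$pct_positive[i], cs$n[i]))
  if (!is.null(x$myelin_thickness_cor))
    cat(sprintf("  myelin-thickness loading correlation r = %+.3f (95%% CI %+.3f to %+.3f)\n",
                x$myelin_thickness_cor$r, x$myelin_thickness_cor$ci[1],
                x$myelin_thickness_cor$ci[2]))
  invisible(x)
}
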