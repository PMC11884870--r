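# Internal helpers shared across the pipeline.

# Derive a per-stage seed from a master seed so stages can be re-run in
# isolation. Kept strictly below 2^31.
stage_seed <- function(master, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 100003L
  (abs(as.integer(master)) %% 1000003L) * 1009L + h
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# z-score a vector; constant input is an error at the call sites that use it
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

# column-standardize a matrix (mean 0, sd 1); constant columns are an error
standardize_columns <- function(x, what = "matrix") {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    bad <- colnames(x)[!is.finite(sds) | sds == 0]
    stop(sprintf("constant column(s) in %s: %s", what,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
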