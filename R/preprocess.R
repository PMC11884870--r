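# Confound residualization and assembly of the four analysis blocks.

#' Residualize variables on confounds
#'
#' Replaces each column of `x` by its least-squares residual on an intercept
#' plus the confound columns. Residuals are exactly orthogonal to every
#' confound and have mean zero.
#'
#' @param x Numeric matrix or data.frame, participants x variables.
#' @param confounds Numeric matrix or data.frame, participants x confounds.
#' @return Matrix of residuals with the same dimensions and column names as
#'   `x`.
#' @export
residualize <- function(x, confounds) {
  x <- as.matrix(x)
  cmat <- as.matrix(confounds)
  if (nrow(x) != nrow(cmat)) stopf("x and confounds must share rows")
  if (anyNA(x) || anyNA(cmat)) stopf("missing values are not allowed")
  design <- cbind(intercept = 1, cmat)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stopf("confound matrix is rank-deficient (rank %d < %d columns)",
          qrd$rank, ncol(design))
  res <- qr.resid(qrd, x)
  dimnames(res) <- dimnames(x)
  res
}

#' Build a confound design from the covariate table
#'
#' Behavioral variables are adjusted for age and sex; brain variables
#' additionally for handedness, intracranial volume and transmitter reference
#' amplitude. Extended mode strictly augments the base set with education,
#' income, IQ and go/no-go false alarms.
#'
#' @param covariates Covariate data.frame (columns `age`, `sex`,
#'   `handedness`, `icv`, `transmit`, and for extended mode `education`,
#'   `income`, `iq`, `gng_false_alarms`).
#' @param target `"behavior"` or `"brain"`.
#' @param mode `"base"` or `"extended"`.
#' @return Numeric matrix of confounds.
#' @export
confound_matrix <- function(covariates, target = c("behavior", "brain"),
                            mode = c("base", "extended")) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  need <- c("age", "sex")
  if (target == "brain") need <- c(need, "handedness", "icv", "transmit")
  if (mode == "extended")
    need <- c(need, "education", "income", "iq", "gng_false_alarms")
  missing_cols <- setdiff(need, colnames(covariates))
  if (length(missing_cols))
    stopf("covariates lack column(s): %s", paste(missing_cols, collapse = ", "))
  out <- as.matrix(covariates[, need, drop = FALSE])
  if (anyNA(out)) stopf("missing covariate values (complete cases required)")
  storage.mode(out) <- "double"
  out
}

new_feature_set <- function(block, x, meta) {
  stopifnot(ncol(x) == nrow(meta))
  colnames(x) <- meta$column
  structure(list(block = block, x = x, meta = meta), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set '%s': %d participants x %d variables (%s)\n",
              x$block, nrow(x$x), ncol(x$x),
              paste(unique(x$meta$class), collapse = ", ")))
  invisible(x)
}

#' Assemble the economic-games feature block
#'
#' @param behavioral Participants x decision-variable table.
#' @param schema Variable schema with direction tags.
#' @return A `feature_set` with per-variable metadata (game, direction).
#' @export
games_block <- function(behavioral, schema) {
  x <- as.matrix(behavioral)
  if (!all(colnames(x) == schema$variable))
    stopf("behavioral columns do not match the schema")
  meta <- data.frame(column = schema$variable, class = "game",
                     region = NA_character_, hemisphere = NA_character_,
                     subclass = schema$direction, game = schema$game,
                     modality = NA_character_, stringsAsFactors = FALSE)
  new_feature_set("games", x, meta)
}

#' Assemble the three brain feature blocks
#'
#' Combines parcel-level structure (4 cortical metrics x regions + 41
#' subcortical volumes), nodal graph metrics for both connectivity modalities
#' (5 measures x regions each) and homotopic interhemispheric values (one per
#' pair per modality) into the structure, functional-connectivity and
#' structural-connectivity feature sets. With 360 cortical regions the three
#' blocks total 5441 columns.
#'
#' @param structure Participants x structure-feature matrix.
#' @param structure_meta Metadata for `structure` (columns `column`, `class`,
#'   `region`, `hemisphere`, `subclass`).
#' @param metrics_f,metrics_s Participants x (5 x regions) nodal-metric
#'   matrices for the functional and structural modality, with columns named
#'   `<measure>_<region>` for measures `clustering`, `local_efficiency`,
#'   `path_length`, `degree`, `betweenness`.
#' @param ih_f,ih_s Participants x homotopic-pair matrices of
#'   interhemispheric connectivity values.
#' @param labels Cortical parcel labels (length = number of regions).
#' @return Named list of three `feature_set` objects: `structure`,
#'   `functional_connectivity`, `structural_connectivity`.
#' @export
assemble_brain_blocks <- function(structure, structure_meta,
                                  metrics_f, metrics_s, ih_f, ih_s, labels) {
  n_regions <- length(labels)
  p <- n_regions / 2
  if (is.null(metrics_f) || is.null(metrics_s) || is.null(ih_f) || is.null(ih_s))
    stopf("both connectivity modalities are required")
  measures <- c("clustering", "local_efficiency", "path_length", "degree",
                "betweenness")
  for (nm in c("metrics_f", "metrics_s")) {
    m <- get(nm)
    if (ncol(m) != 5 * n_regions)
      stopf("%s must have 5 x %d columns, got %d", nm, n_regions, ncol(m))
  }
  if (ncol(ih_f) != p || ncol(ih_s) != p)
    stopf("interhemispheric blocks must have %d columns (one per homotopic pair)", p)
  if (ncol(structure) != nrow(structure_meta))
    stopf("structure metadata does not cover every column")
  n_cort <- sum(structure_meta$class %in% c("thickness", "myelin", "NDI", "ODI"))
  if (n_cort != 4 * n_regions)
    stopf("structure block must contain 4 cortical metrics x %d regions", n_regions)

  struct_meta <- structure_meta
  struct_meta$game <- NA_character_
  struct_meta$modality <- NA_character_
  fs_structure <- new_feature_set("structure", as.matrix(structure), struct_meta)

  conn_set <- function(metrics, ih, modality) {
    suffix <- if (modality == "functional") "f" else "s"
    cols <- c(paste0(rep(measures, each = n_regions), "_", suffix, "_",
                     rep(labels, times = 5)),
              paste0("interhemispheric_", suffix, "_",
                     sub("^L_", "", labels[seq_len(p)])))
    meta <- data.frame(
      column = cols,
      class = c(paste0(rep(measures, each = n_regions), "_", suffix),
                rep(paste0("interhemispheric_", suffix), p)),
      region = c(rep(labels, times = 5), sub("^L_", "", labels[seq_len(p)])),
      hemisphere = c(substr(rep(labels, times = 5), 1, 1), rep("LR", p)),
      subclass = NA_character_, game = NA_character_,
      modality = modality, stringsAsFactors = FALSE)
    x <- cbind(as.matrix(metrics), as.matrix(ih))
    new_feature_set(paste0(modality, "_connectivity"), x, meta)
  }
  list(structure = fs_structure,
       functional_connectivity = conn_set(metrics_f, ih_f, "functional"),
       structural_connectivity = conn_set(metrics_s, ih_s, "structural"))
}

#' Total MRI-derived feature count of a block list
#' @param blocks List of brain `feature_set` objects.
#' @return Integer total column count.
#' @export
feature_count <- function(blocks) {
  sum(vapply(blocks, function(b) ncol(b$x), integer(1)))
}
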