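# End-to-end orchestration: residualize -> connectome -> assemble -> PCA ->
# SMCCA -> permutation test -> cross-loadings -> recovery metrics.

#' Pipeline configuration
#'
#' Validates and bundles every tunable of the analysis. Defaults follow the
#' reference analysis: 30 game PCs, 60 PCs per brain set (robustness re-runs
#' at 70 and 80), a shared lasso penalty fraction, 1000 permutations, and
#' age/sex confounds for behavior plus handedness, intracranial volume and
#' transmitter amplitude for brain variables.
#'
#' @param seed Master seed; per-stage streams are derived from it.
#' @param n_pcs_games,n_pcs_brain Retained principal components (each
#'   silently capped at the block's admissible maximum).
#' @param penalty Shared penalty fraction of `sqrt(p_i)` used when
#'   `select_penalty = FALSE`.
#' @param select_penalty Run permutation-based penalty selection first.
#' @param penalty_grid,n_perm_select Grid and permutation count for
#'   selection.
#' @param n_perm Permutations for the significance test (0 skips it).
#' @param confounds `"base"` or `"extended"` (adds education, income, IQ,
#'   go/no-go false alarms).
#' @param zscore Z-score residualized columns before PCA (default TRUE).
#' @param candidates,n_grid,positive_only Cost-efficiency threshold sweep
#'   controls, see [threshold_cost_efficiency()].
#' @param fraction Top-region map fraction.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_pcs_games = 30, n_pcs_brain = 60,
                            penalty = 0.5, select_penalty = FALSE,
                            penalty_grid = seq(0.1, 0.9, length.out = 10),
                            n_perm_select = 100, n_perm = 1000,
                            confounds = c("base", "extended"), zscore = TRUE,
                            candidates = c("unique", "grid"), n_grid = 50,
                            positive_only = FALSE, fraction = 0.30) {
  confounds <- match.arg(confounds)
  candidates <- match.arg(candidates)
  stopifnot(n_pcs_games >= 1, n_pcs_brain >= 1, n_perm >= 0,
            penalty > 0, penalty <= 1, fraction > 0, fraction <= 1,
            n_grid >= 2)
  cfg <- list(seed = as.integer(seed), n_pcs_games = n_pcs_games,
              n_pcs_brain = n_pcs_brain, penalty = penalty,
              select_penalty = select_penalty, penalty_grid = penalty_grid,
              n_perm_select = n_perm_select, n_perm = n_perm,
              confounds = confounds, zscore = zscore,
              candidates = candidates, n_grid = n_grid,
              positive_only = positive_only, fraction = fraction)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  r <- as.integer(serialize(unclass(cfg), NULL, version = 2))
  sprintf("%08x", sum(r * (seq_along(r) %% 97 + 1)) %% 2147483647)
}

drop_constant <- function(fs) {
  sds <- apply(fs$x, 2, stats::sd)
  if (any(sds == 0)) {
    fs$x <- fs$x[, sds > 0, drop = FALSE]
    fs$meta <- fs$meta[sds > 0, , drop = FALSE]
    attr(fs, "dropped") <- sum(sds == 0)
  }
  fs
}

# Stages shared by the main run and the robustness re-runs: residualization,
# connectome features, block assembly.
pipeline_prepare <- function(study, config) {
  for (f in c("behavioral", "structure", "covariates"))
    if (is.null(study[[f]])) stopf("preprocess stage: study lacks '%s'", f)
  if (is.null(study$matrices$functional) ||
      is.null(study$matrices$structural_counts))
    stopf("connectome stage: connectivity matrices are missing")

  conf_beh <- confound_matrix(study$covariates, "behavior", config$confounds)
  conf_brain <- confound_matrix(study$covariates, "brain", config$confounds)

  games <- games_block(study$behavioral, study$schema)
  games <- drop_constant(games)
  games$x <- residualize(games$x, conf_beh)

  feats <- connectome_features(study, candidates = config$candidates,
                               n_grid = config$n_grid,
                               positive_only = config$positive_only)
  blocks <- assemble_brain_blocks(study$structure, study$structure_meta,
                                  feats$metrics_f, feats$metrics_s,
                                  feats$ih_f, feats$ih_s, study$labels)
  n_features <- feature_count(blocks)
  blocks <- lapply(blocks, function(b) {
    b <- drop_constant(b)
    b$x <- residualize(b$x, conf_brain)
    b
  })
  # orientation reference: prosocial-signed composite of the game residuals
  dir <- games$meta$subclass
  orient <- rowMeans(games$x[, dir == "prosocial", drop = FALSE]) -
    rowMeans(games$x[, dir == "punishment", drop = FALSE])
  list(games = games, blocks = blocks, orient = orient,
       n_brain_features = n_features)
}

pipeline_analyze <- function(prep, config, n_pcs_games = config$n_pcs_games,
                             n_pcs_brain = config$n_pcs_brain) {
  all_blocks <- c(list(games = prep$games), prep$blocks)
  n <- nrow(prep$games$x)
  pca <- lapply(names(all_blocks), function(bn) {
    x <- all_blocks[[bn]]$x
    if (config$zscore) x <- standardize_columns(x, bn)
    k_want <- if (bn == "games") n_pcs_games else n_pcs_brain
    reduce_pca(x, min(k_want, n - 1, ncol(x)))
  })
  names(pca) <- names(all_blocks)
  sets <- lapply(pca, `[[`, "scores")

  penalty <- config$penalty
  selection <- NULL
  if (config$select_penalty) {
    selection <- select_penalties(sets, grid = config$penalty_grid,
                                  n_perm = config$n_perm_select,
                                  seed = stage_seed(config$seed, "select"))
    penalty <- selection$penalty
  }
  fit <- smcca(sets, penalty = penalty, orient = prep$orient)
  variates <- lapply(fit$variates, function(v) v[, 1])
  names(variates) <- names(all_blocks)

  perm <- NULL
  if (config$n_perm > 0)
    perm <- permutation_test(sets, penalty = penalty, n_perm = config$n_perm,
                             seed = stage_seed(config$seed, "permtest"),
                             reference = 1)

  report <- cross_loading_report(all_blocks, variates,
                                 fraction = config$fraction)
  list(pca = pca, fit = fit, penalty = penalty, selection = selection,
       permutation = perm, loadings = report,
       k_used = vapply(pca, `[[`, numeric(1), "k"))
}

recovery_metrics <- function(loadings, truth) {
  cs <- loadings$class_summary
  signs <- truth$class_signs
  match_tab <- data.frame(
    class = names(signs),
    planted = as.numeric(signs),
    estimated_mean = cs$mean[match(names(signs), cs$class)])
  match_tab$sign_match <- sign(match_tab$estimated_mean) == match_tab$planted

  bt <- loadings$brain
  sig_cor <- c()
  take <- function(class_name, gamma) {
    sub <- bt[bt$class == class_name, ]
    g <- gamma[match(sub$region, names(gamma))]
    if (sum(!is.na(sub$loading)) < 4 || stats::sd(g) == 0) return(NA_real_)
    stats::cor(sub$loading, g, use = "complete.obs")
  }
  sig_cor["thickness"] <- take("thickness", truth$gamma$thickness)
  sig_cor["myelin"] <- take("myelin", truth$gamma$myelin)
  sig_cor["subcortical"] <- take("subcortical", truth$gamma$subcortical)
  sig_cor["interhemispheric_f"] <- take("interhemispheric_f",
                                        truth$gamma$interhemispheric_f)
  sig_cor["interhemispheric_s"] <- take("interhemispheric_s",
                                        truth$gamma$interhemispheric_s)
  list(sign_table = match_tab, signature_correlations = sig_cor,
       all_signs_recovered = all(match_tab$sign_match, na.rm = TRUE))
}

#' Run the full brain-behavior association pipeline
#'
#' Executes every stage in order on a study: confound residualization,
#' connectome graph metrics at the cost-efficiency-optimal threshold,
#' feature-block assembly, PCA reduction, sparse multi-set CCA (optionally
#' with permutation penalty selection), the permutation significance test,
#' and canonical cross-loading summaries. When the study carries planted
#' ground truth, recovery metrics (sign agreement per metric class and
#' correlations between estimated and planted regional signatures) are
#' added.
#'
#' @param study A `synthetic_study` or an equivalently shaped list.
#' @param config A [pipeline_config()].
#' @return Object of class `prosocca_report`. Identical seeds and inputs
#'   give identical reports.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  prep <- pipeline_prepare(study, config)
  ana <- pipeline_analyze(prep, config)
  cp <- ana$fit$cor_pairs[[1]]
  nm <- names(c(list(games = NULL), prep$blocks))
  rho <- cp[1, -1]
  names(rho) <- names(prep$blocks)
  out <- list(
    config = config, config_hash = config_hash(config),
    n = nrow(prep$games$x), n_brain_features = prep$n_brain_features,
    k_used = ana$k_used,
    variance_explained = vapply(ana$pca, `[[`, numeric(1), "cumulative_ve"),
    penalty = ana$penalty, selection = ana$selection,
    rho = rho, sum_cor = ana$fit$sum_cor[1],
    fit = ana$fit, permutation = ana$permutation,
    loadings = ana$loadings)
  if (!is.null(study$truth))
    out$recovery <- recovery_metrics(ana$loadings, study$truth)
  class(out) <- "prosocca_report"
  out
}

#' @export
print.prosocca_report <- function(x, ...) {
  cat(sprintf("Prosociality brain-marker analysis (n = %d, %d brain features, config %s)\n",
              x$n, x$n_brain_features, x$config_hash))
  cat(sprintf("  PCs retained: %s; variance explained: %s\n",
              paste(sprintf("%s=%d", names(x$k_used), x$k_used), collapse = ", "),
              paste(sprintf("%s=%.0f%%", names(x$variance_explained),
                            100 * x$variance_explained), collapse = ", ")))
  cat(sprintf("  penalty fraction %.2f; canonical correlations with games: %s (sum %.3f)\n",
              x$penalty,
              paste(sprintf("%s=%.2f", names(x$rho), x$rho), collapse = ", "),
              x$sum_cor))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p = %.4g (add-one %.4g, %d permutations)\n",
                x$permutation$p_value, x$permutation$p_value_add_one,
                x$permutation$n_perm))
  print(x$loadings)
  if (!is.null(x$recovery))
    cat(sprintf("  recovery: all planted class signs recovered: %s; median signature r = %.2f\n",
                x$recovery$all_signs_recovered,
                stats::median(x$recovery$signature_correlations, na.rm = TRUE)))
  invisible(x)
}

#' Robustness re-runs across PCA dimensionalities
#'
#' Repeats the analysis for several brain-set PC counts on the same prepared
#' blocks and summarizes the concordance (pairwise Pearson correlation) of
#' the brain cross-loading vectors across runs.
#'
#' @param study A `synthetic_study`.
#' @param config A [pipeline_config()].
#' @param k_values Brain-set PC counts (default 60, 70, 80).
#' @return List with `reports` (one per K) and a `concordance` data.frame of
#'   pairwise loading correlations.
#' @export
run_robustness <- function(study, config = pipeline_config(),
                           k_values = c(60, 70, 80)) {
  prep <- pipeline_prepare(study, config)
  runs <- lapply(k_values, function(k)
    pipeline_analyze(prep, config, n_pcs_brain = k))
  names(runs) <- paste0("K", k_values)
  load_vec <- lapply(runs, function(r) r$loadings$brain$loading)
  pairs <- utils::combn(seq_along(k_values), 2)
  concordance <- data.frame(
    k_a = k_values[pairs[1, ]], k_b = k_values[pairs[2, ]],
    r = apply(pairs, 2, function(ij)
      stats::cor(load_vec[[ij[1]]], load_vec[[ij[2]]],
                 use = "complete.obs")))
  list(reports = runs, concordance = concordance)
}

#' Write the numeric summaries of a report to JSON
#'
#' @param report A `prosocca_report`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  out <- list(
    config_hash = report$config_hash, n = report$n,
    n_brain_features = report$n_brain_features,
    k_used = as.list(report$k_used),
    variance_explained = as.list(report$variance_explained),
    penalty = report$penalty, rho = as.list(report$rho),
    sum_cor = report$sum_cor,
    p_value = report$permutation$p_value,
    p_value_add_one = report$permutation$p_value_add_one,
    class_summary = report$loadings$class_summary,
    myelin_thickness_cor = report$loadings$myelin_thickness_cor)
  if (!is.null(report$recovery))
    out$recovery <- list(
      all_signs_recovered = report$recovery$all_signs_recovered,
      signature_correlations = as.list(report$recovery$signature_correlations))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
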