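# Synthetic-study generator: a latent prosociality trait drives economic-game
# decisions, parcel-level brain structure and connectivity matrices, with
# confound effects and additive noise. Ground truth is stored for recovery
# tests.

aseg_bilateral <- c("Lateral-Ventricle", "Inf-Lat-Vent",
                    "Cerebellum-White-Matter", "Cerebellum-Cortex",
                    "Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
                    "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC",
                    "vessel", "choroid-plexus")
aseg_midline <- c("3rd-Ventricle", "4th-Ventricle", "5th-Ventricle",
                  "Brain-Stem", "CSF", "Optic-Chiasm", "WM-hypointensities",
                  "non-WM-hypointensities", "CC_Posterior", "CC_Mid_Posterior",
                  "CC_Central", "CC_Mid_Anterior", "CC_Anterior")

#' Subcortical, ventricular and callosal structure names
#'
#' 41 FreeSurfer aseg-style structure labels: 14 bilateral structures and 13
#' midline structures including the five corpus callosum subregions.
#' @return Character vector of length 41.
#' @export
subcortical_names <- function() {
  c(paste0("Left-", aseg_bilateral), paste0("Right-", aseg_bilateral),
    aseg_midline)
}

subcortical_subclass <- function(names) {
  ventricles <- c("Left-Lateral-Ventricle", "Right-Lateral-Ventricle",
                  "Left-Inf-Lat-Vent", "Right-Inf-Lat-Vent",
                  "3rd-Ventricle", "4th-Ventricle", "5th-Ventricle")
  limbic <- as.vector(outer(c("Left-", "Right-"),
                            c("Accumbens-area", "Amygdala", "Hippocampus",
                              "Pallidum"), paste0))
  ifelse(names %in% ventricles, "ventricle",
         ifelse(grepl("^CC_", names), "corpus_callosum",
                ifelse(names %in% limbic, "limbic", "other")))
}

subcortical_base_volume <- function(names) {
  base <- c("Lateral-Ventricle" = 7000, "Inf-Lat-Vent" = 300,
            "Cerebellum-White-Matter" = 14000, "Cerebellum-Cortex" = 50000,
            "Thalamus-Proper" = 7500, "Caudate" = 3500, "Putamen" = 5000,
            "Pallidum" = 1800, "Hippocampus" = 4200, "Amygdala" = 1600,
            "Accumbens-area" = 600, "VentralDC" = 4000, "vessel" = 60,
            "choroid-plexus" = 700, "3rd-Ventricle" = 1000,
            "4th-Ventricle" = 1500, "5th-Ventricle" = 60,
            "Brain-Stem" = 20000, "CSF" = 1000, "Optic-Chiasm" = 200,
            "WM-hypointensities" = 2000, "non-WM-hypointensities" = 200,
            "CC_Posterior" = 900, "CC_Mid_Posterior" = 450,
            "CC_Central" = 450, "CC_Mid_Anterior" = 450, "CC_Anterior" = 800)
  unname(base[sub("^(Left|Right)-", "", names)])
}

#' Cortical parcel labels
#'
#' Indexed parcel labels with the L_/R_ hemisphere prefix convention, ordered
#' left hemisphere first so that parcel `i` and parcel `i + n/2` are a
#' homotopic pair.
#' @param n_regions Even number of cortical parcels (default 360).
#' @return Character vector of length `n_regions`.
#' @export
region_labels <- function(n_regions = 360) {
  if (n_regions %% 2 != 0 || n_regions < 4)
    stopf("n_regions must be even and >= 4")
  p <- n_regions / 2
  nm <- sprintf("P%03d", seq_len(p))
  c(paste0("L_", nm), paste0("R_", nm))
}

# value mapping from the latent propensity to the declared legal range
map_to_range <- function(latent, type, lo, hi, inc) {
  if (type == "binary") return(as.numeric(latent > 0))
  mid <- (lo + hi) / 2
  raw <- mid + (hi - lo) / 4 * latent
  clamp(round(raw / inc) * inc, lo, hi)
}

#' Simulate a complete synthetic study
#'
#' Generates a full study: behavioral decisions in the fifteen economic games,
#' cortical and subcortical structure, and per-participant functional and
#' structural connectivity matrices, all driven by a standardized latent
#' prosociality trait `theta` together with confound effects and additive
#' Gaussian noise. The planted directions mirror the reported brain-behavior
#' associations: prosocial decisions, cortical thickness, homotopic
#' interhemispheric connectivity, corpus callosum and limbic volumes load
#' positively on the trait; punishment/aggression decisions, T1w/T2w myelin
#' and ventricular volumes load negatively. Connectivity planting works
#' through a rewiring axis on the network skeleton: long-range shortcut
#' edges strengthen log-linearly with `theta` while a count-matched set of
#' redundant short-range edges fades, and homotopic edges strengthen with
#' `theta`, so that cost-efficiency-thresholded graphs of high-`theta`
#' participants are more integrative (shorter nodal path lengths) with
#' stronger interhemispheric connectivity.
#'
#' @param n Number of participants (default 217, the analyzed sample size).
#' @param n_regions Even number of cortical parcels (default 360).
#' @param snr Effect-size multiplier on all planted `theta` effects
#'   (default 1); 0 gives a null study.
#' @param noise Multiplier on all participant-level noise terms (default 1);
#'   0 gives noiseless expectations, used to check generator monotonicity.
#' @param seed Integer seed; identical seeds give identical studies.
#' @param schema Decision-variable schema, see [default_variable_schema()].
#' @param n_modules Number of mirrored functional modules (default 4).
#' @param theta Optional latent trait vector (length `n`); drawn N(0,1) and
#'   standardized exactly when NULL.
#' @return An object of class `synthetic_study`: list with `behavioral`
#'   (data.frame), `structure` (matrix) and `structure_meta`, `covariates`,
#'   `matrices` (functional matrices, structural streamline counts and
#'   waytotals), `labels`, `truth` (all planted parameters) and `seed`.
#' @export
simulate_study <- function(n = 217, n_regions = 360, snr = 1, noise = 1,
                           seed = 1L, schema = default_variable_schema(),
                           n_modules = 4, theta = NULL) {
  if (n < 4) stopf("n must be >= 4")
  if (snr < 0 || noise < 0) stopf("snr and noise must be non-negative")
  labels <- region_labels(n_regions)
  p <- n_regions / 2
  set.seed(as.integer(seed))

  ## ---- planted design (independent of participants) ----
  nv <- nrow(schema)
  dir_sign <- c(prosocial = 1, punishment = -1, other = 0)[schema$direction]
  beta <- snr * dir_sign * stats::runif(nv, 0.5, 1)
  names(beta) <- schema$variable
  beh_age <- stats::runif(nv, -0.2, 0.2)
  beh_sex <- stats::runif(nv, -0.3, 0.3)

  cort_metrics <- c("thickness", "myelin", "NDI", "ODI")
  cort_base <- list(thickness = stats::runif(n_regions, 2.2, 3.2),
                    myelin    = stats::runif(n_regions, 1.3, 1.8),
                    NDI       = stats::runif(n_regions, 0.30, 0.45),
                    ODI       = stats::runif(n_regions, 0.35, 0.55))
  cort_scale <- c(thickness = 0.12, myelin = 0.08, NDI = 0.03, ODI = 0.03)
  gamma_cort <- list(
    thickness =  snr * stats::runif(n_regions, 0.3, 0.8),
    myelin    = -snr * stats::runif(n_regions, 0.3, 0.8),
    NDI       = 0 * stats::runif(n_regions),
    ODI       = 0 * stats::runif(n_regions))
  cort_conf <- list(
    age  = c(thickness = stats::runif(1, -0.4, -0.1),
             myelin = stats::runif(1, -0.2, 0.2),
             NDI = stats::runif(1, -0.2, 0.2),
             ODI = stats::runif(1, -0.2, 0.2)),
    sex  = stats::setNames(stats::runif(4, -0.2, 0.2), cort_metrics),
    icv  = stats::setNames(stats::runif(4, -0.1, 0.1), cort_metrics),
    tx   = c(thickness = 0, myelin = stats::runif(1, 0.2, 0.4), NDI = 0, ODI = 0),
    hand = stats::setNames(stats::runif(4, -0.05, 0.05), cort_metrics))

  sc_names <- subcortical_names()
  sc_sub <- subcortical_subclass(sc_names)
  sc_base <- subcortical_base_volume(sc_names)
  gamma_sc <- numeric(length(sc_names))
  gamma_sc[sc_sub == "limbic"] <- snr * stats::runif(sum(sc_sub == "limbic"), 0.2, 0.5)
  gamma_sc[sc_sub == "ventricle"] <- -snr * stats::runif(sum(sc_sub == "ventricle"), 0.4, 0.8)
  gamma_sc[sc_sub == "corpus_callosum"] <- snr * stats::runif(sum(sc_sub == "corpus_callosum"), 0.3, 0.6)
  names(gamma_sc) <- sc_names

  ## connectivity skeleton (modules mirrored across hemispheres)
  module_pair <- sort(rep(seq_len(n_modules), length.out = p))
  module_node <- c(module_pair, module_pair)
  ut <- upper.tri(matrix(0, n_regions, n_regions))
  same_module <- outer(module_node, module_node, "==")
  homotopic <- matrix(FALSE, n_regions, n_regions)
  homotopic[cbind(seq_len(p), seq_len(p) + p)] <- TRUE
  homotopic <- homotopic | t(homotopic)
  within_m <- same_module & !homotopic
  between_m <- !same_module & !homotopic
  # short-range filler: node pairs in cyclically adjacent modules within one
  # hemisphere; long-range: everything else between modules
  hemi_node <- rep(c("L", "R"), each = p)
  adj_mod <- (abs(outer(module_node, module_node, "-")) %% n_modules) %in%
    c(1, n_modules - 1)
  same_hemi <- outer(hemi_node, hemi_node, "==")
  shortrange <- between_m & adj_mod & same_hemi
  longrange <- between_m & !shortrange
  long_idx <- which(longrange & ut)
  n_short <- max(1L, round(0.20 * length(long_idx)))
  n_core <- max(1L, round(0.12 * length(long_idx)))
  # the fading short-range filler set is count-matched to the shortcut set
  # so the total strong-edge budget stays flat across theta
  short_range_idx <- which(shortrange & ut)
  n_fill <- min(length(short_range_idx), n_short)
  fill_idx <- sample(short_range_idx, n_fill)
  filler <- matrix(FALSE, n_regions, n_regions)
  filler[fill_idx] <- TRUE
  filler <- filler | t(filler)
  shortrange_stable <- shortrange & !filler
  pick <- sample(long_idx, n_short + n_core)
  shortcut <- matrix(FALSE, n_regions, n_regions)
  shortcut[pick[seq_len(n_short)]] <- TRUE
  shortcut <- shortcut | t(shortcut)
  corebridge <- matrix(FALSE, n_regions, n_regions)
  corebridge[pick[n_short + seq_len(n_core)]] <- TRUE
  corebridge <- corebridge | t(corebridge)

  sym_fill <- function(mask_ut_idx, values, m) {
    m[mask_ut_idx] <- values
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  # The latent trait acts as a rewiring axis on the thresholded topology:
  # long-range shortcut edges strengthen log-linearly with theta while the
  # redundant short-range filler fades, so high-theta networks are
  # integrative (shorter nodal path length) and low-theta networks spend
  # their connection budget on short-range redundancy. Homotopic edges
  # strengthen with theta (interhemispheric planting). All theta effects are
  # multiplicative, so magnitude-based thresholding never flips their sign,
  # and edge noise is proportional to the edge baseline, leaving no
  # reservoir of spurious long-range edges. Stable core bridges keep every
  # network connected.
  Bf <- matrix(0.01, n_regions, n_regions)
  Bf[shortrange_stable] <- 0.04
  Bf[within_m] <- 0.28; Bf[filler] <- 0.16; Bf[shortcut] <- 0.16
  Bf[corebridge] <- 0.24; Bf[homotopic] <- 0.30
  diag(Bf) <- 1
  hom_ut <- which(homotopic & ut)
  short_ut <- which(shortcut & ut)
  within_ut <- which(within_m & ut)
  filler_ut <- which(filler & ut)
  # shortcut gains are capped inside the structured weight band (they
  # rank-swap with the fading filler instead of floating above the band,
  # which would let the threshold optimum shave edges elsewhere)
  Tf <- matrix(0, n_regions, n_regions)        # log-scale theta slopes
  s_hom_f <- snr * 0.15 * stats::runif(p, 0.6, 1.4)
  Tf <- sym_fill(hom_ut, s_hom_f, Tf)
  Tf <- sym_fill(short_ut, snr * 0.35 * stats::runif(length(short_ut), 0.6, 1.4), Tf)
  Tf <- sym_fill(within_ut, snr * 0.05 * stats::runif(length(within_ut), 0.6, 1.4), Tf)
  Tf <- sym_fill(filler_ut, -snr * 0.50 * stats::runif(length(filler_ut), 0.6, 1.4), Tf)

  # structural streamline rates with the same rewiring axis
  Ls <- matrix(1.5, n_regions, n_regions)
  Ls[shortrange_stable] <- 4
  Ls[within_m] <- 50; Ls[filler] <- 18; Ls[shortcut] <- 18
  Ls[corebridge] <- 40; Ls[homotopic] <- 60
  diag(Ls) <- 0
  Gs <- matrix(0, n_regions, n_regions)
  g_hom_s <- snr * 0.15 * stats::runif(p, 0.6, 1.4)
  Gs <- sym_fill(hom_ut, g_hom_s, Gs)
  Gs <- sym_fill(short_ut, snr * 0.45 * stats::runif(length(short_ut), 0.6, 1.4), Gs)
  Gs <- sym_fill(within_ut, snr * 0.05 * stats::runif(length(within_ut), 0.6, 1.4), Gs)
  Gs <- sym_fill(filler_ut, -snr * 0.50 * stats::runif(length(filler_ut), 0.6, 1.4), Gs)

  ## ---- participants ----
  age <- sample(20:60, n, replace = TRUE)
  sex <- stats::rbinom(n, 1, 0.5)
  handedness <- stats::rbinom(n, 1, 0.9)
  icv <- stats::rnorm(n, 1.45e6, 1.3e5) + 1.2e5 * sex
  transmit <- stats::rnorm(n, 250, 15)
  education <- stats::rbinom(n, 1, 0.5)
  income <- sample(1:7, n, replace = TRUE)
  iq <- round(stats::rnorm(n, 100, 15))
  gng_fa <- stats::rpois(n, 5)
  covariates <- data.frame(age = age, sex = sex, handedness = handedness,
                           icv = icv, transmit = transmit,
                           education = education, income = income, iq = iq,
                           gng_false_alarms = gng_fa)
  age_z <- (age - 40) / 12
  icv_z <- (icv - 1.5e6) / 1.5e5
  tx_z <- (transmit - 250) / 15

  if (is.null(theta)) {
    theta <- as.numeric(scale(stats::rnorm(n)))
  } else {
    if (length(theta) != n) stopf("theta must have length n")
    theta <- as.numeric(theta)
  }

  ## behavioral table
  beh <- matrix(0, n, nv, dimnames = list(NULL, schema$variable))
  for (v in seq_len(nv)) {
    latent <- beta[v] * theta + beh_age[v] * age_z +
      beh_sex[v] * (sex - 0.5) + noise * stats::rnorm(n)
    beh[, v] <- map_to_range(latent, schema$type[v], schema$lo[v],
                             schema$hi[v], schema$increment[v])
  }
  behavioral <- as.data.frame(beh)

  ## structure block
  n_sc <- length(sc_names)
  structure_mat <- matrix(0, n, 4 * n_regions + n_sc)
  cols <- character(4 * n_regions + n_sc)
  meta_class <- character(4 * n_regions + n_sc)
  meta_region <- character(4 * n_regions + n_sc)
  k <- 0
  for (m in cort_metrics) {
    conf <- cort_conf$age[m] * age_z + cort_conf$sex[m] * (sex - 0.5) +
      cort_conf$icv[m] * icv_z + cort_conf$tx[m] * tx_z +
      cort_conf$hand[m] * (handedness - 0.5)
    eff <- outer(theta, gamma_cort[[m]]) + conf +
      noise * matrix(stats::rnorm(n * n_regions), n, n_regions)
    structure_mat[, k + seq_len(n_regions)] <-
      rep(cort_base[[m]], each = n) + cort_scale[m] * eff
    cols[k + seq_len(n_regions)] <- paste0(m, "_", labels)
    meta_class[k + seq_len(n_regions)] <- m
    meta_region[k + seq_len(n_regions)] <- labels
    k <- k + n_regions
  }
  sc_age <- stats::runif(1, -0.3, -0.1)
  sc_sex <- stats::runif(1, -0.2, 0.2)
  eff_sc <- outer(theta, gamma_sc) + 0.4 * icv_z + sc_age * age_z +
    sc_sex * (sex - 0.5) + noise * matrix(stats::rnorm(n * n_sc), n, n_sc)
  structure_mat[, k + seq_len(n_sc)] <- rep(sc_base, each = n) *
    (1 + 0.15 * eff_sc)
  cols[k + seq_len(n_sc)] <- paste0("vol_", sc_names)
  meta_class[k + seq_len(n_sc)] <- "subcortical"
  meta_region[k + seq_len(n_sc)] <- sc_names
  colnames(structure_mat) <- cols
  hemi <- ifelse(grepl("^L_|^Left-", meta_region), "L",
                 ifelse(grepl("^R_|^Right-", meta_region), "R", "M"))
  structure_meta <- data.frame(
    column = cols, class = meta_class, region = meta_region,
    hemisphere = hemi,
    subclass = ifelse(meta_class == "subcortical",
                      subcortical_subclass(meta_region), NA_character_),
    stringsAsFactors = FALSE)

  ## connectivity matrices
  functional <- vector("list", n)
  counts <- vector("list", n)
  waytotal <- matrix(0, n, n_regions)
  for (i in seq_len(n)) {
    E <- matrix(0, n_regions, n_regions)
    E[ut] <- stats::rnorm(sum(ut))
    E <- E + t(E)
    W <- Bf * exp(theta[i] * Tf) * exp(noise * 0.15 * E)
    diag(W) <- 1
    W <- clamp(W, -0.999, 0.999)
    diag(W) <- 1
    dimnames(W) <- list(labels, labels)
    functional[[i]] <- W

    lam <- Ls * exp(theta[i] * Gs)
    Ci <- matrix(stats::rpois(n_regions * n_regions, lam), n_regions)
    diag(Ci) <- 0
    dimnames(Ci) <- list(labels, labels)
    counts[[i]] <- Ci
    waytotal[i, ] <- rowSums(Ci) + stats::rpois(n_regions, 200) + 1
  }
  colnames(waytotal) <- labels

  truth <- list(
    theta = theta, beta = beta,
    confound_effects = list(behavior_age = beh_age, behavior_sex = beh_sex,
                            cortical = cort_conf,
                            subcortical = c(age = sc_age, sex = sc_sex, icv = 0.4)),
    gamma = list(thickness = stats::setNames(gamma_cort$thickness, labels),
                 myelin = stats::setNames(gamma_cort$myelin, labels),
                 NDI = stats::setNames(gamma_cort$NDI, labels),
                 ODI = stats::setNames(gamma_cort$ODI, labels),
                 subcortical = gamma_sc,
                 # per-pair log-scale homotopic theta slopes
                 interhemispheric_f = stats::setNames(
                   s_hom_f, sub("^L_", "", labels[seq_len(p)])),
                 interhemispheric_s = stats::setNames(
                   g_hom_s, sub("^L_", "", labels[seq_len(p)]))),
    class_signs = c(thickness = 1, myelin = -1,
                    interhemispheric_f = 1, interhemispheric_s = 1,
                    path_length_f = -1, path_length_s = -1,
                    ventricle = -1, corpus_callosum = 1, limbic = 1),
    modules = stats::setNames(module_node, labels),
    shortcut_edges = which(shortcut & ut),
    snr = snr, noise = noise)

  out <- list(behavioral = behavioral, structure = structure_mat,
              structure_meta = structure_meta, covariates = covariates,
              matrices = list(functional = functional,
                              structural_counts = counts,
                              waytotal = waytotal),
              labels = labels, schema = schema, truth = truth,
              seed = as.integer(seed), n = n, n_regions = n_regions)
  class(out) <- "synthetic_study"
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic prosociality study: %d participants, %d cortical parcels\n",
              x$n, x$n_regions))
  cat(sprintf("  behavioral variables: %d (%d prosocial, %d punishment, %d other)\n",
              ncol(x$behavioral), sum(x$schema$direction == "prosocial"),
              sum(x$schema$direction == "punishment"),
              sum(x$schema$direction == "other")))
  cat(sprintf("  structure features: %d; matrices: %d functional + %d structural\n",
              ncol(x$structure), length(x$matrices$functional),
              length(x$matrices$structural_counts)))
  cat(sprintf("  planted SNR %.2f, noise %.2f, seed %d\n",
              x$truth$snr, x$truth$noise, x$seed))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `behavioral.tsv`, `structure.tsv`, `covariates.tsv`,
#' per-participant connectivity matrices as dense TSV, and `truth.json`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(study$behavioral, "behavioral.tsv")
  wt(as.data.frame(study$structure), "structure.tsv")
  wt(study$covariates, "covariates.tsv")
  wt(study$structure_meta, "structure_meta.tsv")
  mdir <- file.path(dir, "matrices")
  dir.create(mdir, showWarnings = FALSE)
  for (i in seq_len(study$n)) {
    utils::write.table(study$matrices$functional[[i]],
                       file.path(mdir, sprintf("functional_%03d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(study$matrices$structural_counts[[i]],
                       file.path(mdir, sprintf("counts_%03d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(study$matrices$waytotal, file.path(mdir, "waytotal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
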