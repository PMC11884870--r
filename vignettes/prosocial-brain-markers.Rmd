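---
title: "Linking economic-game behavior to multimodal brain features with sparse multi-set CCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking economic-game behavior to multimodal brain features with sparse multi-set CCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosocca)
```

## The analysis problem

Individual differences in prosocial behavior — giving, cooperating,
trusting, punishing defectors — can be measured with incentivized economic
games, and a large multimodal MRI protocol yields thousands of candidate
brain features per person: cortical thickness, T1w/T2w myelin proxies,
neurite density and orientation dispersion for 360 parcels, 41 subcortical
and ventricular volumes, and graph-theoretical summaries of functional and
tractography-based structural connectivity. With hundreds of behavioral
variables and thousands of brain variables, variable-by-variable testing is
both underpowered and uninterpretable. `prosocca` implements a data-driven
alternative: find one latent axis per variable set such that the axes
covary maximally across sets, then read off which original variables load
on them.

## The model

Let $X_1, \dots, X_K$ be $K$ participant-aligned variable sets (here
$K = 4$: games, cortical/subcortical structure, functional-connectivity
metrics, structural-connectivity metrics), each column-standardized. The
sparse multi-set canonical correlation model finds weight vectors $w_i$
maximizing the sum of pairwise between-set covariances

$$\max_{w_1,\dots,w_K} \sum_{i<j} w_i^\top X_i^\top X_j\, w_j
\quad \text{s.t.}\quad \lVert w_i\rVert_2 \le 1,\ \lVert w_i\rVert_1 \le c_i,$$

the penalized multi-set formulation that treats the within-set covariance
as the identity (classical whitened CCA is deliberately out of scope; with
$p \gg n$ its whitening is ill-posed and the diagonal convention is what
the penalized-matrix-decomposition family of methods uses). `smcca()`
solves this by block-coordinate ascent: for each set in turn,
$a_i = X_i^\top \sum_{j\ne i} X_j w_j$ is soft-thresholded with the
smallest threshold that brings the normalized weight inside its L1 bound
(`l1_constrained_update()`, solved in closed form on the sorted magnitudes
of $a_i$). Each block step exactly maximizes its subproblem, so the
objective is non-decreasing across sweeps — the fit stores the trace and
the test suite asserts the monotonicity. Initialization is the leading
right singular vector of each set, making the deterministic path fully
reproducible without a seed. With $K = 2$ and inactive penalties the
stationary point is the leading singular-vector pair of $X_1^\top X_2$,
which the tests use as an independent oracle.

Associated machinery follows the same two-stage design as the reference
analysis family:

* **Penalty selection** (`select_penalties()`): for each candidate penalty
  fraction of $\sqrt{p_i}$, the observed sum of canonical correlations is
  compared with its distribution over row-permuted data via a Fisher-z
  gap statistic; the fraction with the largest standardized gap wins. The
  Fisher transform is applied to the *mean* pairwise correlation rather
  than the raw sum: for $K > 2$ the sum can exceed 1, where $\tanh^{-1}$
  is undefined; dividing by the number of pairs is a monotone rescaling
  that changes nothing for $K = 2$ and keeps the statistic finite for all
  $K$.
* **Significance** (`permutation_test()`): with penalties frozen, each
  replicate re-fits after independently permuting the participant rows of
  every set except the games set (under exchangeability this is
  equivalent to shuffling all sets, and holding one set fixed is the
  cleaner description of "break the linkage"). Both the plain proportion
  $\#\{\rho^{perm} \ge \rho^{obs}\}/B$ and the add-one variant
  $(\#+1)/(B+1)$ are reported; the add-one version is the one with exact
  finite-sample calibration and is what the calibration test checks.
* **Cross-loadings** (`cross_loadings()`, `cross_loading_report()`):
  interpretation uses correlations of the *original residualized
  variables* (not PC scores) with the other side's canonical variate —
  brain variables against the games variate, game variables against each
  brain variate averaged across the three brain sets (per-set values are
  retained). Class summaries use the normal approximation
  $\bar r \pm 1.96\,\mathrm{sd}(r)/\sqrt{m}$ over the $m$ regions of a
  metric class; exact zeros count as positive so the two percentages sum
  to 100.

## The pipeline around the model

`run_pipeline()` executes the full chain:

1. **Residualization** (`residualize()`): every variable is replaced by
   its least-squares residual on an intercept plus confounds — age and sex
   for behavior; additionally handedness, intracranial volume and
   transmitter reference amplitude for brain variables. Extended mode
   *adds* education (undergraduate-degree indicator), income (the printed
   1–7 ordinal treated as numeric), IQ and go/no-go false alarms; it never
   replaces the base set. Missing covariates are an error — the analysis
   is complete-case by design, no imputation.
2. **Connectome metrics** (`connectome_features()`): functional matrices
   are used as-is (Pearson edges, diagonal zeroed); structural
   streamline-count matrices are divided row-wise by their waytotals and
   symmetrized as $(M + M^\top)/2$. Each matrix is binarized at the
   threshold maximizing global cost efficiency
   $E_{glob} - \kappa$ (`threshold_cost_efficiency()`), where
   $E_{glob}$ is the mean inverse shortest-path length over ordered pairs
   ($1/\infty = 0$) and $\kappa$ the edge density. Candidate thresholds
   are every distinct weight magnitude, or an order-statistic quantile
   grid for large networks — both choices are invariant to monotone
   transformations of the weights, and ties in cost efficiency resolve
   toward lower cost. Thresholding uses absolute weights by default
   (negative correlations count by magnitude; a positive-only flag
   exists). On the binarized graph five nodal measures are computed:
   clustering coefficient, local efficiency, arithmetic-mean nodal path
   length (a harmonic option exists; the two conventions differ only for
   disconnected targets, which the arithmetic version excludes and
   flags), degree, and unnormalized betweenness (delegated to igraph;
   everything is certified against a brute-force BFS/path-enumeration
   oracle in the tests). Isolated-node path lengths are imputed with the
   graph's largest finite nodal path length so feature tables stay
   complete; the substitution count is recorded. Homotopic
   interhemispheric connectivity is the weighted (pre-threshold) matrix
   entry between the left and right instance of each parcel — the
   same-parcel pairing is what completes the 5,441-column enumeration
   (4 cortical metrics × 360 + 41 volumes + per modality 5 measures × 360
   + 180 homotopic pairs).
3. **Reduction** (`reduce_pca()`): residualized columns are z-scored
   (mixed units — mm, ratios, graph indices — are not comparable
   otherwise; exposed as a flag because the reference description is
   silent on it) and reduced by SVD-based PCA with a deterministic sign
   convention (largest-magnitude loading positive). Defaults are 30
   components for games and 60 per brain set, with robustness re-runs at
   70 and 80 (`run_robustness()`), capped at the admissible
   $\min(n-1, p)$.
4. **Fit, test, load, report**, as above. The games variate is oriented so
   that the prosocial-tagged variable cluster loads positively (the sign
   of a canonical variate is otherwise arbitrary); the reference direction
   is the prosocial-minus-punishment composite of the residualized game
   variables. Reports exclude wall-clock information so a fixed seed gives
   an `identical()` report.

## The synthetic-study generator

`simulate_study()` is a first-class module, not a fixture: it generates
complete studies in which a standardized latent prosociality trait
$\theta$ drives all planted structure, with ground truth stored for
recovery testing.

* **Behavior**: each of the 108 default decision variables (every
  strategy-method grid cell is one variable — 16 ultimatum responder
  cells, 11 trustee return fractions, 11 second-party and 2 × 16
  third-party punishment cells, and so on) has a latent propensity
  $\beta_v \theta + \text{confounds} + \varepsilon$ with
  $|\beta_v| \sim U(0.5, 1) \cdot \mathrm{SNR}$, signed by the variable's
  direction tag (prosocial $+$, punishment/aggression $-$, untagged 0).
  Amounts are scaled to the legal range, rounded to the game's increment
  (JPY 100 or 10, or 10% return steps) and clipped; binary decisions
  threshold the propensity at zero. The payoff engine
  (`compute_payoff()`) implements every printed rule exactly and is what
  gives the variables their meaning, ranges and increments.
* **Structure**: per-region baselines at realistic magnitudes (thickness
  ≈ 2.2–3.2 mm, myelin ratio ≈ 1.3–1.8, plausible aseg volumes) plus
  $\gamma_r \theta$ effects whose signs mirror the planted directions —
  thickness $+$, myelin $-$, ventricles $-$, corpus callosum and limbic
  volumes $+$, NDI/ODI null — with per-region magnitudes drawn once and
  stored as the recoverable regional signature.
* **Connectivity**: matrices are generated directly (base skeleton +
  planted effects + noise) rather than through time series — the analysis
  consumes matrices, so a time-series path would only add unverifiable
  structure. The skeleton has mirrored modules, homotopic edges, stable
  long-range core bridges, and two count-matched marginal edge sets: long-
  range shortcuts whose weight rises log-linearly with $\theta$ and
  short-range (adjacent-module) filler that fades with $\theta$. All
  $\theta$ effects are multiplicative, so magnitude thresholding can
  never flip their sign, and edge noise is proportional to the edge
  baseline, leaving no reservoir of spurious strong long-range edges.
  This "rewiring axis" is what survives cost-efficiency thresholding:
  the optimizer picks a characteristic density and largely cancels any
  planting that merely rescales weights or dumps extra strong edges on
  top of the ranking (we verified both failure modes empirically while
  designing the generator), whereas swapping redundant short-range edges
  for long-range ones at matched rank genuinely shortens nodal path
  lengths for high-$\theta$ participants. Homotopic weights rising with
  $\theta$ plant the interhemispheric association. Structural matrices
  use the same skeleton as Poisson streamline counts with multiplicative
  rate effects, plus per-row waytotals for the normalization step.

What the generator does *not* emulate: fMRI temporal autocorrelation, raw
diffusion signal, spatial smoothness of cortical maps, repeated-game
learning, non-Gaussian covariate dependence, or missing data. Passing
recovery tests therefore show that the pipeline recovers the planted
multivariate structure under realistic dimensionality, discretization,
confounding and noise — not that it would behave identically on real
acquisitions.

A deliberate consequence of the design: under cost-efficiency thresholding
at desk-scale network sizes, clustering and integration trade off (the
budget spent on triangles is not available for shortcuts), so the
generator plants and the recovery suite claims signs only for the classes
the analysis is anchored on — interhemispheric connectivity ($+$), myelin
($-$), thickness ($+$), nodal path length ($-$), ventricles ($-$), plus
corpus callosum and limbic volumes ($+$). Segregation metrics are left
without a guaranteed planted sign.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n` | 217 | participants (the analyzed sample size) |
| `n_regions` | 360 | cortical parcels, L/R mirrored |
| `snr` | 1 | multiplier on every planted $\theta$ effect; 0 gives a null study |
| `noise` | 1 | multiplier on participant-level noise; 0 gives noiseless expectations |
| `penalty` | 0.5 | lasso bound as a fraction of $\sqrt{p_i}$, shared across sets (per-set penalties supported; the shared fraction is the default because nothing suggests per-set tuning) |
| `penalty_grid` | 10 values, 0.1–0.9 | selection grid (the original grid is unpublished) |
| `n_perm` | 1000 | permutations for selection and significance |
| `n_pcs_games`, `n_pcs_brain` | 30, 60 | retained components; robustness at 70/80 |
| `candidates`, `n_grid` | "unique", 50 | threshold sweep: all distinct magnitudes, or a quantile grid |

## Numerical choices and degenerate inputs

* Cost-efficiency ties resolve toward lower cost; an all-zero matrix is an
  error; a complete equal-weight graph has a single candidate and returns
  it.
* The L1-constrained update handles the unattainable-bound case (tied
  leading magnitudes, where the L1 norm of the normalized weight cannot
  drop below $\sqrt{\#\text{ties}}$) by returning the nearest-feasible
  weight and recording the slack.
* Constant columns: undefined loadings are flagged and excluded from
  summaries; constant features are dropped (with a record) before
  z-scoring and PCA — at small samples binary strategy-method cells can
  be degenerate.
* PCA of an input with *some* zero-variance columns is valid (a single
  informative column explains all variance); only an entirely constant
  matrix is an error.
* Seeds: a single master seed expands into per-stage streams via a stable
  string-keyed derivation, so the permutation stage can be re-run in
  isolation and a fixed seed reproduces the entire report bit for bit.

## Problem sizes used in the test and acceptance suites

Statistical checks run at the study's sample conditions with a reduced
parcellation, chosen once as the smallest network scale at which
thresholded-graph topology is informative (at 10–20 nodes every
cost-efficient graph is within two hops of everything and nodal path
length is pinned by density alone; 40 nodes is past that saturation):

* feature enumeration at the full 360 parcels;
* graph-metric certification on 200 random graphs with up to 12 nodes
  against exhaustive BFS enumeration;
* null calibration on 200 independent-set studies ($n = 100$, 199
  permutations each);
* recovery on 50 planted studies ($n = 217$, SNR 1, 40 parcels, 30 PCs
  per brain set) checking per-class loading signs and
  estimated-vs-planted signature correlations;
* robustness on 10 planted studies at 60/70/80 brain PCs.

## Known limitations

* The default 108-variable schema is a best-effort enumeration from the
  printed game descriptions; the exact deposited variable list may differ,
  so the schema is configurable and the count is not hard-coded anywhere
  in the analysis path.
* Parcel labels are synthetic indexed names with the standard L_/R_
  hemisphere convention, not the published multimodal-parcellation names;
  any label set with that convention can be supplied.
* Only the single leading canonical component is fitted by default; the
  deflation rule for further components is implemented but lightly
  exercised.
* Cross-loading confidence intervals use the normal approximation over
  regions; a bootstrap is not built in.
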