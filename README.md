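# prosocca

Brain markers of human prosocial behavior via sparse multi-set canonical
correlation analysis.

## What this package does

Incentivized economic games (dictator, trust, ultimatum, public goods,
prisoner's dilemma variants, second- and third-party punishment, chicken,
stag hunt, preemptive strike, faith game) measure individual differences in
prosociality, and multimodal MRI yields thousands of candidate brain
features per participant: cortical thickness, T1w/T2w myelin, neurite
density and orientation dispersion over 360 parcels, 41 subcortical and
ventricular volumes, and graph-theoretical summaries of functional and
tractography-based structural connectivity. `prosocca` implements a
data-driven pipeline linking the two, for researchers who want a
many-to-many association analysis instead of thousands of univariate
tests — together with a payoff-aware synthetic-study generator that plants
a known latent prosociality trait so the whole pipeline can be validated
by parameter recovery.

## The model

With participant-aligned, column-standardized variable sets
$X_1,\dots,X_K$ (games, structure, functional connectivity, structural
connectivity), the sparse multi-set CCA finds one sparse weight vector per
set maximizing the sum of pairwise between-set covariances

$$\max \sum_{i<j} w_i^\top X_i^\top X_j w_j
\quad\text{s.t.}\quad \|w_i\|_2 \le 1,\ \|w_i\|_1 \le c_i,$$

fitted by block-coordinate ascent with a closed-form L1-constrained
soft-thresholding update. Penalties are selected by a permutation gap
statistic, significance is assessed by permutation of the sum of canonical
correlations, and interpretation uses canonical cross-loadings: the
correlation of each original residualized variable with the *other* side's
canonical variate, summarized per metric class (mean, normal-approximation
95% CI, percent of regions per sign) with top-30% region maps.

Around the fit, the pipeline provides confound residualization (age and
sex for behavior; additionally handedness, intracranial volume and
transmit amplitude for brain variables; an extended mode adds education,
income, IQ and go/no-go false alarms), cost-efficiency thresholding of
connectivity matrices (maximize global efficiency minus edge density over
candidate thresholds), the five standard nodal graph measures, homotopic
interhemispheric connectivity, and PCA reduction (30 game components, 60
per brain set, robustness re-runs at 70/80).

## Worked example

```r
library(prosocca)

study  <- simulate_study(n = 217, n_regions = 40, seed = 42)  # planted SNR 1
cfg    <- pipeline_config(seed = 42, n_pcs_games = 20, n_pcs_brain = 30,
                          n_perm = 199, candidates = "grid", n_grid = 40)
report <- run_pipeline(study, cfg)
print(report)
```

```
Prosociality brain-marker analysis (n = 217, 641 brain features, config 00165236)
  PCs retained: games=20, structure=30, functional_connectivity=30, structural_connectivity=30; ...
  penalty fraction 0.50; canonical correlations with games: structure=0.97,
  functional_connectivity=0.98, structural_connectivity=0.98 (sum 5.841)
  permutation p = 0 (add-one 0.005, 199 permutations)
Canonical cross-loading report
  thickness              mean +0.453 (95% CI +0.417 to +0.489), 100% positive (m=40)
  myelin                 mean -0.452 (95% CI -0.486 to -0.418),   0% positive (m=40)
  ventricle              mean -0.462 (95% CI -0.520 to -0.403),   0% positive (m=7)
  corpus_callosum        mean +0.409 (95% CI +0.361 to +0.457), 100% positive (m=5)
  path_length_f          mean -0.099 (95% CI -0.177 to -0.021),  38% positive (m=40)
  interhemispheric_f     mean +0.667 (95% CI +0.629 to +0.705), 100% positive (m=20)
  interhemispheric_s     mean +0.744 (95% CI +0.702 to +0.785), 100% positive (m=20)
  ...
  recovery: all planted class signs recovered: TRUE; median signature r = 0.90
```

Reading this: the three canonical correlations say each brain set shares a
strong axis with game behavior; the permutation p-value says no
row-shuffled dataset matched it. The cross-loading summary shows which
feature classes carry the axis — here thicker cortex, lower myelin,
stronger homotopic interhemispheric connectivity, larger callosal volume,
smaller ventricles and shorter nodal path lengths go with prosocial play,
exactly the directions the generator planted, and the recovery line
confirms the planted regional signatures were recovered (median r = 0.90).

Individual stages are exported if you want them separately:
`compute_payoff()`, `default_variable_schema()`, `residualize()`,
`threshold_cost_efficiency()`, `nodal_metrics()`,
`interhemispheric_connectivity()`, `reduce_pca()`, `smcca()` (an S3 model
object with `print`/`summary`/`coef`/`predict`/`plot` methods),
`select_penalties()`, `permutation_test()`, `cross_loading_report()`,
`run_robustness()`, `write_study()` / `write_report()`.

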