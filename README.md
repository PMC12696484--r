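# nanoqstr

Quantitative structure–toxicity (QSTR) modelling of iron carbide
nanoparticle (ICNP) cytotoxicity, from crystal unit cells to validated,
domain-gated, explainable predictions.

ICNPs (Fe₂C, Fe₃C, Fe₅C₂) are candidate agents for MRI contrast and
magnetic hyperthermia; their safety screening produces dose–response
tables of cell viability after 24 h exposure. `nanoqstr` is for
nano-safety modellers who want to go beyond exposure variables: it
builds spherical particles from CIF unit cells, computes a 57-entry
atomistic descriptor vector per particle, fuses it with the experimental
table, and trains a regression model of viability

> viability ~ f(core diameter, coating group, shell material, shell
> thickness, concentration, D₁…D₅₇)

validated the way regulators expect OECD-compliant QSARs to be:

* **Model selection** — nested 5-fold CV with randomised search over six
  algorithms (RF, kNN, linear SGD, MLP, LightGBM, XGBoost), winner by
  cross-validated MAE.
* **External validation** — Golbraikh–Tropsha criteria
  (r² > 0.6, Q²loo > 0.5, through-origin slopes k, k′ ∈ (0.85, 1.15),
  (r² − r₀²)/r² < 0.1), leave-one-out Q², Y-scrambling, bootstrap
  out-of-bag confidence intervals.
* **Applicability domain** — nearest-neighbour threshold ⟨d⟩ + Zσ on the
  retained below-mean pairwise distances, with Euclidean and weighted
  Gower (mixed-type) metrics.
* **Explanation** — sampling permutation Shapley attributions (exactly
  additive), permutation importance, feature-addition curves, PDP/ICE,
  per-sample waterfall payloads.

A synthetic-data module (toy CIFs + a Hill dose–response simulator)
makes the whole workflow runnable and testable offline.

## Worked example

```r
library(nanoqstr)

# full atomistic workflow on the default 186-row synthetic scenario
res <- run_pipeline(run_config(seed = 7, bootstrap_B = 200))
res
#> <pipeline_result> atomistic approach; 186 rows; 13 features
#>   winner: xgboost (MAE_cv 0.0590)
#>   test R2 0.924, MAE 0.048 | train R2 0.921 | Q2_loo 0.830
#>   Golbraikh-Tropsha: PASS | scrambling: degraded
#>   APD thresholds: euclidean 3.6432, gower 0.3362
```

Reading the output: the 57 descriptors are filtered (zero-variance +
|r| > 0.99) and SHAP-ranked down to 8, united with the five experimental
features (13 total); XGBoost wins the CV; the test-set R² of 0.924 with
all Golbraikh–Tropsha flags green means the model predicts held-out
treatments quantitatively; "scrambling: degraded" means the true model
beat all five Y-scrambled refits, so it learned signal, not noise. Any
new treatment is then gated: a prediction is flagged unreliable when its
nearest training neighbour lies beyond the APD threshold.

Individual stages are ordinary functions:

```r
cells <- toy_unit_cells()
np <- partition_core_shell(carve_sphere(cells$Fe3C, diameter = 50), 4)
v <- compute_descriptor_vector(np, cells$Fe3C)
v[c("D5", "D7", "D15", "D21", "D32", "D33", "D46", "D48")]
#>         D5         D7        D15        D21        D32        D33        D46
#> -1.5199955 -0.3859536  0.0000000  9.1462185 -1.3696568 -0.1527093  0.5775633
#>        D48
#>  0.5823261
```

A thin CLI mirrors the stages (`inst/cli/nanoqstr`):
`simulate`, `descriptors`, `run`, `report`.

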