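---
title: "From crystal unit cells to validated cytotoxicity predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From crystal unit cells to validated cytotoxicity predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoqstr)
```

## The modelling problem

Iron carbide nanoparticles (ICNPs, phases Fe~2~C, Fe~3~C, Fe~5~C~2~) are
candidate agents for imaging and hyperthermia, and their cytotoxicity is
usually screened with colorimetric viability assays: cells are exposed for
24 h at a ladder of concentrations and the fraction of surviving cells
relative to an untreated control is recorded. `nanoqstr` implements a
quantitative structure–toxicity (QSTR) workflow for such data. Exposure
and formulation variables (core diameter, shell material and thickness,
surface coating, dose) are augmented with *atomistic* descriptors computed
from a geometric model of the particle itself, a regression model of
viability is trained and validated to OECD QSAR standards, and every
prediction is gated by an applicability domain and explained by additive
feature attributions.

A treatment is called cytotoxic when viability drops strictly below 70 %
of control, the usual ISO reading for in vitro assays; the modelled
endpoint stays continuous, and the binary label is used for stratification
and reporting only.

## Particles and descriptors

Particles are built from crystallographic unit cells (a constrained CIF
dialect is parsed: cell parameters, symmetry-operator loops, fractional
atom sites). The cell is replicated into a supercell, a sphere of the
requested diameter is carved (atoms within `d/2` of the center,
inclusive), and atoms within 4 Å of the nominal surface form the *shell*,
the rest the *core*. Both boundary rules are inclusive toward the named
region: an atom exactly at radius `R` belongs to the particle, an atom
exactly at `R - 4` Å to the shell. The carving center defaults to the
geometric center of the supercell; centering on the nearest atom, or on
explicit coordinates, is available because the choice is genuinely open —
the two conventions differ in whether the smallest particles contain a
central atom, and the default is the one that makes no assumption about
the motif.

```{r particle}
cells <- toy_unit_cells()
np <- partition_core_shell(carve_sphere(cells$Fe3C, diameter = 30), 4)
np
```

The descriptor vector has exactly 57 entries (D1–D57) spanning atom
counts, per-atom potential-energy statistics, coordination numbers at 3,
4 and 5 Å, bond-orientational order parameters, lattice energies and
sphere geometry, each over the whole particle, the core, the shell, or as
core–shell differences and ratios. Eight ids have externally fixed
meanings and the registry pins them: D5 (core potential energy), D7
(core–shell energy difference), D15 (3 Å coordination, core), D21 (4 Å
coordination, shell), D32 (particle lattice energy), D33 (bulk minus
particle lattice energy), D46 and D48 (second hexatic order, all/shell).
The remaining 49 positions are filled by systematic region families; the
registry ships as an ordinary data frame and is configuration, not
hard-code, because only those eight positions are anchored by external
convention.

Two interpretation choices deserve a note:

* **"Second hexatic order parameter"** is read as the `l = 6`
  bond-orientational invariant, with `l = 4` as the "first" companion.
  Both the 3-D Steinhardt form `q_l` (spherical harmonics averaged over
  neighbors within 4 Å) and the planar `psi_l` form are implemented; the
  Steinhardt form is the default for 3-D particles and the registry
  records which variant each id uses. Reference values anchor the
  implementation: a perfect hexagon gives `psi_6 = 1`, the ideal fcc
  12-neighbor shell gives `q_6 = 0.5745`.
* **Energy model.** Descriptors are generic over an energy-model contract
  (`per_atom_energy`, `bulk_energy_per_atom`), so external interatomic
  potential engines can be adapted. The built-in reference implementation
  is a cut-off pairwise Lennard-Jones/Morse potential with
  per-species-pair parameters and the half-assignment convention
  `E_i = 1/2 * sum phi(r_ij)`, which makes region sums well defined.
  Lattice energies are reported *per atom*, signs preserved, so the
  bulk-minus-particle difference is negative for small particles whose
  under-coordinated surface raises the per-atom energy. No relaxation is
  applied by default; a steepest-descent hook exists (200 steps,
  1e-3 eV/Å force tolerance) but is off in all tests.

A species-resolved coordination variant with cutoff
`1.2 x (sum of covalent radii)` also exists: with realistic radii this
cutoff can fall below the shortest bond lengths, yielding identically
zero descriptors — exactly the behaviour the zero-variance filter is
there to catch. Because practice varies between a fixed "3 Å" rule and the
covalent-radius rule for the smallest cutoff, both are implemented and
neither is asserted to be the canonical one.

## Dataset curation

Viability tables carry one row per treatment (experiment id, phase, core
diameter and size spread, shell, coating, dose, cell line, organism,
health status, viability). Viability is stored as a fraction; percent
input is detected (values above 2) and divided by 100. Zeta potential and
hydrodynamic size columns are accepted and dropped. Categoricals are
encoded ordinally or binarily, with coating free text mapped by a keyword
table onto {bare, polymer-based, protein-based, other} and shell material
ranked by descending training frequency; the dictionary is fitted on
training rows only and persists as JSON. Unseen categories at prediction
time map to the most frequent level, warn, and set a flag that the
applicability domain can inspect.

The 70:30 split is constrained: first one uniformly chosen row of every
multi-row experiment enters the test set (so every chemistry appears in
the hold-out), then the remaining quota is filled stratified on the
cytotoxicity label, and a repair pass swaps rows (never an experiment's
only representative) until the label proportions of both subsets are
within five points of the full table, up to one-row granularity.
Single-row experiments stay in training with a warning, since moving
them would empty their training representation. Z-scoring uses training
statistics only; the *population* standard deviation is the documented
convention (switchable), and constant columns pass through with a
warning rather than dividing by zero.

## Model development and validation

Six regression algorithms are compared under nested 5-fold
cross-validation with randomised hyperparameter search (25 draws per
algorithm by default, folds shared across algorithms, scaling refit
inside each fold for the scale-sensitive learners): random forest,
k-nearest neighbours, linear SGD, a one-hidden-layer MLP, LightGBM
(optional backend, skipped with a recorded warning when not installed)
and XGBoost. Each grid tunes the parameters that matter for its learner:
trees/depth/node-size for the forest, neighbours and weight function for
kNN, learning rate and iterations for SGD, activation (relu/tanh) and
initial learning rate for the MLP, trees and learning rate for LightGBM,
learning rate and depth for XGBoost. The MLP is deliberately *not*
scaled — a documented exception to the usual scale-the-MLP convention;
the adaptive optimiser keeps training stable and the comparison honest. The winner is the algorithm with the lowest
mean validation MAE.

The tuned model then faces the external-validation battery:

* test-set metrics (R², adjusted R², MAE, MSE, RMSE);
* leave-one-out `Q²` with refits at fixed hyperparameters (re-tuning per
  left-out point is not done — it answers a different question and is two
  orders of magnitude more expensive);
* Golbraikh–Tropsha criteria: `r² > 0.6`, `Q²_loo > 0.5`, through-origin
  slopes `k`, `k'` with at least one in (0.85, 1.15), and at least one of
  the two `(r² − r₀²)/r²` ratios below 0.1 — both regression directions
  are computed and reported because the standard reading requires only
  one to pass;
* Y-scrambling (5 rounds): the response is permuted within training, the
  model refit identically, and the verdict is "degraded" only when the
  true model beats every scrambled round on the untouched test set;
* bootstrap (percentile, not BCa — simpler, and adequate at these B) of
  out-of-bag MAE and R².

## Applicability domain

All pairwise training distances are computed, the subset strictly below
their mean is retained, and the threshold is `<d> + Z * sigma` over the
retained subset (sample standard deviation). A query is reliable when its
nearest training neighbour is at or below the threshold — "exceeds" reads
strictly, so the boundary itself is in-domain. `Z` defaults to 0.5, the
conventional multiplier for this retained-subset thresholding scheme, and
is configuration. Two metrics are fitted: Euclidean on the z-scaled
numeric block (categorical columns excluded), and weighted Gower for the
mixed-type feature set, with numeric ranges learned on training data,
query differences clipped at 1, and weights taken from the final model's
normalised mean |SHAP| scores so that the domain is tight where the model
actually looks. The worked example `{0, 1, 2, 10}` with `Z = 0.5`
(pairwise distances {1, 2, 10, 1, 9, 8}, retained {1, 2, 1}, threshold
1.6220) is frozen in the tests.

## Explanation

Attributions are *sampling permutation Shapley values*: feature
permutations are sampled in antithetic pairs and the explained row's
values replace background values one at a time, crediting each feature
with the change it causes, averaged over a background sample. By
telescoping, per-row attributions plus the base value equal the model
prediction exactly, for any model — this additivity is asserted in the
tests at 1e-6. The sign convention follows the endpoint: positive
attributions push predicted viability up. The same machinery drives
feature selection (a 40-tree, depth-10 random forest on the filtered
pool, features ranked by mean |SHAP| on training rows only, top 8
atomistic descriptors united with the five pre-chosen experimental
features for the final 13), global summaries, and per-sample waterfall
payloads. Permutation importance, feature-addition curves (refits on
top-k prefixes), and PDP/ICE curves (decile grids, centred option, 10x10
two-feature surfaces) complete the toolkit.

## The synthetic-data module

Everything above is exercised without downloads by a first-class
generator. Three minimal synthetic lattices (`*_synthetic.cif`: simple
cubic Fe, fcc Fe, orthorhombic Fe/C — stand-ins, *not* the real carbide
structures) give the three phase labels twelve (phase, diameter)
particles between 4.9 and 7 nm. The dose–response table follows a Hill
law,

    viability = 1 / (1 + (C / IC50_eff)^h) + eps,
    IC50_eff  = IC50_base * coating_multiplier * (d / 20 nm)^gamma,

with a log2 dose ladder of 3.125–200 µg/mL, Hill slope 1.3, base IC50
300 µg/mL, coating multipliers {bare 0.6, polymer 1.4, protein 1.7,
other 1.0}, a weak size exponent gamma = 0.3, and Gaussian noise
(sd 0.06) clipped at zero. A Hill response was chosen because observed
dose–viability curves are sigmoidal; the defaults were calibrated once so
the 186-row table carries a cytotoxic fraction near 18.3 % and then
frozen. The generator emulates the *statistical* structure the analysis
assumes — dose-dominant, coating-modulated, weak size effect, modest
noise — and none of the things real assay data add: inter-laboratory
heterogeneity, correlated replicates, reporting errors, or real crystal
chemistry. Passing tests therefore demonstrate that the machinery
recovers known structure under its own assumptions, not that any real
ICNP is safe.

```{r sim}
tab <- simulate_viability(sim_scenario(seed = 7))
nrow(tab)
mean(tab$viability < 0.70)
```

## Problem sizes and numerical choices

The shipped test and acceptance runs use the 186-row scenario, twelve
particles up to 7 nm (about 9,000 atoms at the largest), 25 random-search
draws per algorithm, 5 scrambling rounds and 200 bootstrap resamples —
sizes chosen so a full run completes in a couple of minutes on one core
while every statistical check retains its power; users can raise any of
them in `run_config()`. Neighbor searches use a linked-cell grid above
800 atoms and are bit-identical to the direct double loop. Degenerate
inputs are contracts, not accidents: empty regions flag descriptors as
missing rather than zero, constant responses flag R²/Q² as undefined,
all-equal distance sets make the domain threshold an error with guidance,
and mean-|SHAP| ties break in registry order so selections are
reproducible.

## Limitations

The reference energy model is a pair potential, not a many-body carbide
potential; descriptor *values* are therefore internally consistent rather
than materials-accurate, which suffices for the modelling machinery the
package is about. Real 20–44 nm particles (10^5–10^6 atoms) are outside
the intended problem size of the pure-R geometry kernels. The workflow
models a single 24-h endpoint; nothing here extrapolates to other
exposure times, shapes, or in vivo outcomes.
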