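---
title: "Compositional analysis of chemical element profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of chemical element profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codafood)
```

## The problem

Tables of chemical element concentrations (samples × elements, mg/kg) are
*compositional*: what characterises a honey, a saffron, or their
adulterated imitations is the ratio structure between elements, not the
absolute numbers. Absolute concentrations are contaminated by a per-sample
"size effect" — dilution, instrument scaling, total mineral content — that
multiplies a whole row by an arbitrary constant. Two measurements `x` and
`c·x` are the same composition.

Applying ordinary multivariate statistics to such data ignores this.
Worse, when rows are closed to a constant sum (proportions, percentages),
each part's covariances with the other parts must sum to minus its own
variance, so correlations are forced towards negative values even for
independent parts. Biplots of standardized closed data show all loading
arrows squeezed into a half-plane, and classifiers trained on raw
concentrations spend their capacity modelling the irrelevant totals.

The remedy is log-ratio analysis: map compositions into a Euclidean space
whose geometry (the Aitchison geometry) respects ratios, and do the
statistics there.

## Representations

For a composition `x = (x₁, …, x_D)` with all parts strictly positive:

* **Closure** `C_κ(x) = κ·x / Σxᵢ` rescales to a constant sum; it never
  changes ratios, so every log-ratio method is invariant to it.
* **clr** (centred log-ratio): `clr(x)ᵢ = log(xᵢ / g(x))` with `g(x)` the
  row geometric mean, evaluated in log space so extreme parts cannot
  overflow. clr rows sum to zero, so the D coefficients are
  rank-deficient by one — convenient for biplots (one arrow per element;
  the cosine between two arrows approximates the correlation of the
  corresponding clr coordinates), inconvenient for classifiers that
  invert a covariance.
* **Pivot coordinates (ilr)**: the orthonormal representation
  `z_j = sqrt((D-j)/(D-j+1)) · log(x_j / g(x_{j+1..D}))`, j = 1..D−1. It
  is an isometry: pairwise distances among pivot coordinates equal those
  among clr coefficients, for any pivot order, which is the package's
  central internal consistency oracle. The default order is the column
  order of the input.
* **ilr_var**: pivot coordinates after ordering parts by the strength of
  association between `log(part)` and the class label, strongest first,
  so the leading coordinates carry the discriminating contrasts. The
  label is categorical, so "correlation" is implemented as the
  correlation ratio η (square root of between-class over total sum of
  squares of the log-part; for two classes this is the absolute
  point-biserial correlation). Exact ties are broken by original column
  index so the ordering is deterministic.

The non-compositional regimes kept for comparison are `raw`, `scale`
(column z-scores, variance denominator n−1), `log`, `log_scale`, and
`closed_scale` (closure to 1, then z-scores).

## Non-detects

Concentrations below the instrument's detection limit (DL) arrive as
zeros or blanks. They are *rounded zeros*, not true zeros; a log-ratio
with a zero is undefined, so they must be replaced first. The package
deliberately keeps naive strategies alongside the principled one so their
downstream cost can be measured:

* `replace_const`: every masked cell ← 0.1 mg/kg (benchmark strawman).
* `replace_dl23`: masked cell in part j ← (2/3)·DL_j.
* `replace_unif`: uniform draw on `[0.1, 0.9] · min⁺_j` where `min⁺_j`
  is the smallest positive observed value of part j.
* `replace_bdls_pls`: iterative censored-PLS imputation. Starting from
  (2/3)·DL, each censored part is pivoted first so its leading pivot
  coordinate `z₁` is, given the rest of the row, a monotone function of
  that part alone; `z₁` is regressed on the remaining pivot coordinates
  by a PLS1 fit (component count chosen once per part by 5-fold
  cross-validation over 1..min(10, D−2)); a censored cell is replaced by
  the expected value of the fitted normal *conditional on lying below*
  the coordinate image of its DL (the tobit adjustment
  `m − s·φ(a)/Φ(a)`, `a = (c − m)/s`), mapped back to the
  concentration scale without touching any observed cell. Sweeps repeat
  until the maximum relative change of the imputed cells drops below
  `tol = 1e-4` (cap 50).

The conditional-expectation step matters: plain truncation of the fitted
value at the DL parks most imputations *at* the limit, which is both
biased upward and violates strict below-DL imputation. The conditional
expectation is strictly below the DL by construction and, on synthetic
censored data with known truth, restores the expected quality ordering
bdls_pls ≤ dl23 ≤ const in clr-space RMSE.

When no DLs are shipped with a dataset, the per-part minimum positive
observed value is used as a proxy (`detect_limits_proxy`), which is the
tightest upper bound on where left-censoring occurred. With only D = 2
parts the regression has no predictors and the method falls back to the
(2/3)·DL value.

## PCA and biplots

`pca_coordinates` eigendecomposes the covariance matrix of the chosen
representation. For the z-scored regimes this equals the correlation
matrix of the underlying variables; for clr/ilr the coordinates enter
unstandardized, because z-scoring log-ratio coordinates would destroy the
isometry. Estimators are classical (non-robust) throughout. Components
get a deterministic sign (largest-magnitude loading positive). The clr
spectrum has one structural zero eigenvalue; its non-zero part must equal
the ilr spectrum for any pivot order, and the test suite asserts this at
1e-8.

## The classification benchmark

`benchmark_grid` crosses replacement × representation × classifier under
stratified 10-fold cross-validation repeated 5 times, with the fold
assignment shared across cells so methods are compared on identical
splits. Everything data-dependent is learned on the training fold only
and applied frozen to the held-out fold: proxy DLs and per-part minima,
the censored-PLS fits, z-score centre and scale, the `ilr_var` ordering
(it uses the labels, so computing it on all rows would leak), the tuned
KNN neighbourhood size (inner 5-fold CV over k ∈ {1, 3, …, 15}), and the
network weights. An `audit = TRUE` switch records which rows each fitting
step saw, and the tests assert the intersection with the test fold is
empty.

Classifiers:

* **LDA** (`MASS::lda`). clr input is rank-deficient, so for LDA it is
  mapped internally to a pivot basis — an isometry, hence
  decision-equivalent, and free of pseudo-inverse arbitrariness.
* **KNN** (`class::knn`) with the inner-CV-tuned k.
* **ANN** (`mlp_classifier`): a dense feed-forward network written with
  plain matrix algebra — three ReLU hidden layers of 300/128/64 units,
  10% dropout after the first two, softmax output, mean squared error on
  one-hot targets as the loss with mean absolute error tracked as the
  metric, Adam, an 80/20 train/validation split and early stopping with
  best-weight restoration. MSE-on-one-hot is kept as the default loss on
  purpose (cross-entropy is available behind `loss = "cross_entropy"`).
  The default profile trains 100 epochs with patience 20, which reaches
  near-zero validation loss on the synthetic studies in a few seconds;
  `faithful = TRUE` switches to 500 epochs with patience 50. Inputs are
  taken exactly as the representation delivers them — no hidden
  standardization — because the sensitivity of a network to
  pre-processing is part of what the benchmark measures.

## The synthetic generator

Real deposited tables are not bundled, so the generator supplies study
conditions with the structure the analysis assumes:

* **Logistic-normal classes**: each class has a mean and covariance in
  pivot-coordinate space; draws are mapped to the simplex by the inverse
  pivot transform. This is the standard distributional model on the
  simplex and makes the latent truth available for scoring.
* **Size effect**: each row is multiplied by a lognormal total, so raw
  tables carry exactly the nuisance that log-ratio methods must ignore.
* **Adulteration** (`apply_adulteration`): selected samples are moved
  towards a contaminant profile by the Aitchison power perturbation
  `C(x^(1−α) ⊙ c^α)` with the row total preserved — a perturbation
  inside the simplex geometry with α as the tunable severity knob.
  Mass-balance mixing is available as an alternative mode.
* **Left-censoring** (`censor_below_dl`): per-part DLs are set at the
  empirical quantile matching a target overall non-detect rate; cells
  below their DL are masked and the truth retained.

Two fixed presets define the package's study conditions. The
*honey-like* conditions (`simulate_honey_like`) mirror the layout of a
mineral-element authentication study: 12 elements, six pure classes of
34/34/34/33/33/33 samples, one 45-sample syrup class, 183 adulterated
samples (α = 0.35 towards the syrup centre) and a 7.75% censoring rate;
class centres are drawn once from N(0, 0.8²) in pivot space, within-class
standard deviation 0.5, totals lognormal(log 1000, 0.5) — moderate
overlap, neither trivial nor hopeless. The *size-effect* conditions
(`size_effect_spec`) put three well-separated classes (n = 200 each,
D = 10) under heavy total noise (lognormal sd 1.5 on the log scale) so
that raw-space classifiers degrade while log-ratio classifiers do not.
The imputation-recovery studies use a correlated AR(1) covariance
(ρ = 0.7, sd 0.7) in pivot space, because element profiles in real food
tables are strongly inter-correlated and a diagonal covariance would
make any regression-based imputation pointless by construction.

What the generator does *not* emulate: instrument-specific error
structure, element-specific detection limits, outliers on the simplex
boundary, or true (structural) zeros. Passing tests therefore demonstrate
correctness of the machinery and the direction of the methodological
effects, not the exact magnitudes any particular real dataset would show.

## Numerical choices and degenerate inputs

* Geometric means and all log-ratio maps run in log space; `1e-300` and
  `1e+300` parts coexist without overflow.
* Log arguments are validated strictly positive — no silent clamping;
  masked cells must go through a replacement strategy, and the error
  message says so.
* Zero variance: constant columns fail `zscore_columns` by name;
  zero-total-variance input fails `pca_coordinates`.
* `make_folds` reduces k to the smallest class size (with a warning)
  when a class is too small, and errors on a single class.
* Fold assignment, uniform draws, network initialization and all
  generator draws run under explicit seeds through an internal
  RNG-state-preserving helper, so a fixed seed reproduces every number
  and caller RNG state is never disturbed.
* Tie-breaks: `ilr_var` ordering by original column index; KNN tuning
  prefers the smaller k; PCA signs by largest-magnitude loading.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full pipeline at
n = 400–600 samples, D = 8–12 parts, 10–20 replicate seeds for the
imputation studies and 2–5 repetitions of 10-fold cross-validation.
These sizes put every qualitative conclusion (spectrum equality,
imputation ordering, benchmark ordering, chance-level nulls) well inside
their noise margins while keeping a full run in the low minutes on one
core.

## Known limitations

* True zeros are out of scope; every masked cell is treated as
  left-censored at (a proxy of) the detection limit.
* No robust estimators: outlying samples influence PCA and LDA in the
  classical way.
* Balances beyond pivot coordinates, and all-pairwise log-ratio feature
  selection, are not implemented.
* The network is a small dense MLP; with dozens of samples per class it
  can overfit, which is visible in its benchmark cells and is a property
  of the method, not a defect of the harness.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_honey_like(seed = 1)
comp <- replace_dl23(sim$data)$data
tab <- explained_variance_table(comp, c("scale", "closed_scale", "clr", "ilr"))
subset(tab, k == 2)

spec <- size_effect_spec()
X <- generate_composition(spec, seed = 11)
benchmark_grid(X, replacements = "none",
               representations = c("raw", "clr"),
               classifiers = c("lda", "knn"), seed = 42)$summary
```
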