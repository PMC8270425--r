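---
title: "Methods: expression trends, cell-cycle scoring and labeling kinetics"
author: "stemcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression trends, cell-cycle scoring and labeling kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemcycle)
```

stemcycle implements three quantitative procedures used to study
proliferation of neural stem and progenitor cells (NSPCs), together with
seeded generators that produce synthetic inputs with the statistical
structure each procedure assumes. This vignette is the package's account of
the underlying models, the tunable parameters, the numerical choices, and
the limits of what the synthetic data can demonstrate.

## 1. Expression trends along a pseudotime trajectory

**Input.** A cells x genes CPM matrix with a per-cell pseudotime. The
pseudotime is an *input*: it comes from an upstream trajectory inference on
the same cells and stemcycle never re-estimates it.

**Relative expression.** For one gene, `log2(CPM + 1)` is divided by its
maximum over cells, giving a unitless profile in [0, 1]
(`relative_expression()`). Normalization happens *before* smoothing; a gene
with no expression anywhere maps to the all-zero profile by the 0/0
convention. This scale makes genes with very different absolute abundances
comparable on one axis, at the cost of making single-cell outliers define
the scale maximum.

**Trend smoothing.** `fit_trend()` smooths relative expression against
pseudotime with local polynomial regression — `stats::loess`, degree 2,
tricube weights, the standard local-regression family in R. The default
span of 0.75 is the conventional loess default; it is exposed because the
appropriate span depends on the cell density along the trajectory
(`span = 0.5` is often better below ~150 cells). The curve is evaluated on
an evenly spaced grid of `n_grid = 200` points spanning the observed
pseudotime range, and 95% pointwise bounds are formed as the fit plus or
minus 1.96 loess standard errors (a normal approximation; no simultaneous
coverage is claimed).

**Stage cutoff.** The trajectory is split into an early stage T1 and a late
stage T2 at the onset of increasing expression of a stage-marker gene
(classically *Tbr2*, marking the transition from stem-like to
intermediate-progenitor identity). `stage_cutoff()` computes the
central-finite-difference derivative of the fitted curve on the grid and
declares a grid point stationary where the derivative changes sign or its
magnitude is at most `derivative_tol`. The cutoff is the **rightmost
stationary point that is followed by a positive derivative** — the last
quiet point before the final rise. Two deliberate edge rules:

* if the curve ends flat (a rise-then-plateau or rise-then-peak shape), the
  last sign-change location is used instead, so a peaked trend returns its
  peak;
* a monotone curve raises an explicit no-cutoff error; returning a grid
  boundary silently would manufacture a stage split where none exists.

`derivative_tol` defaults to `1e-4 * range(fitted) / grid_step`. Scaling by
the curve's range and the grid step makes the tolerance invariant to the
units of both axes; the 1e-4 factor is small enough that genuinely sloped
regions (derivative of order `range/1` per unit pseudotime) are never
classified as flat. Cells with pseudotime exactly at the cutoff are
assigned T1 (a `<=` convention, recorded in the object).

**Stage association.** `count_positive_by_stage()` tabulates cells positive
for a gene (CPM strictly above a threshold, default 0) against stage, and
`fisher_exact()` tests the association. The default positivity threshold of
0 matches the usual "any detected expression" reading of single-cell data;
with synthetic data whose dropout is expression-independent (Section 4) a
small positive threshold such as 1 CPM is the appropriate analogue.

**Fisher's exact test.** The two-sided p-value uses the probability-mass
method: conditioning on the margins, the hypergeometric probabilities of
all tables whose point probability does not exceed the observed one (with a
1e-7 relative tie tolerance) are summed. This is the most common two-sided
convention and the one used by `stats::fisher.test`; the test suite checks
the implementation against an exhaustive `choose()`-based enumeration for
every table with row margins up to 30. The reported effect size is the
cross-product odds ratio `(a d)/(b c)` with the boundary conventions
`Inf` when only `b c = 0`, `0` when only `a d = 0`, and `1` when both
vanish — not the conditional maximum-likelihood estimate, which differs in
small tables.

## 2. Cell-cycle scoring and cycling/positivity association

`score_cell_cycle()` computes per-cell G1/S and G2/M scores as the **sum of
transformed expression over the phase's marker genes**, then divides each
score by its median across cells, so a typical cell scores 1 and scores are
comparable across datasets. The default transform is `log2(CPM + 1)`,
consistent with the trajectory module; raw CPM summation is selectable
(`transform = "cpm"`). Markers absent from the matrix are dropped with a
warning. If a raw-score median is 0 (very sparse data) the score is instead
normalized by the mean of the strictly positive raw scores, and left
unnormalized with a warning if there are none — this keeps the statistic
defined without inventing signal.

The bundled marker lists are the widely used G1/S (43 genes) and G2/M (54
genes) signatures of Tirosh and colleagues, converted to mouse symbol
casing by upper/lower-case conversion. They ship as editable plain-text
files under `extdata` with a provenance header; any custom `marker_set()`
can be substituted, and results should always be reported together with the
list used.

`classify_cycling()` calls a cell cycling when
`max(norm_g1s, norm_g2m) >= threshold`, default threshold 2 — twice the
typical cell's score. The decision rule is the package's own construction
(score scatterplots in the literature rarely state their boundary); the
threshold is stored on the result and must be treated as part of any
reported cycling percentage. `tabulate_by_positivity()`,
`percent_cycling()` (rounded half-away-from-zero to one decimal) and
`odds_ratio()` then quantify the association between cycling status and a
marker gene's positivity.

## 3. Cumulative-labeling cell-cycle kinetics

**Model.** In an asynchronously cycling population continuously exposed to
an S-phase label (EdU), the labeling index rises linearly and then
plateaus:

    LI(t) = GF * (Ts + t) / Tc   for t <= Tc - Ts,      LI(t) = GF after,

where GF is the growth fraction (percent of cells actively cycling), Tc the
cell-cycle length and Ts the S-phase length (hours). At `t = 0` the rise
line's intercept is the initial labeling index `Li0 = GF * Ts / Tc` (the
fraction of cycling cells in S phase at any instant), and the rise meets
the plateau at `t* = Tc - Ts`.

**Fitting.** `fit_two_segment()` fits the two lines *independently*, as the
classical cumulative-labeling analysis prescribes: candidate breakpoints
are the midpoints between consecutive distinct observation times; for each
candidate the rise is ordinary least squares on points at or before it and
the plateau is the mean (zero-slope least squares) of points after it; the
split minimizing pooled SSE wins, ties to the smallest breakpoint.
Continuity is not enforced — the reported changepoint is the analytic
intersection `t* = (GF - b)/m`, which need not coincide with the search
breakpoint, and both are reported. Replicates enter as individual points
(preserving degrees of freedom; `average_replicates = TRUE` fits per-time
means). `min_rise_points` defaults to 3 so the slope keeps a residual
degree of freedom; a nonpositive optimal slope is an explicit error, since
no kinetics are derivable from a non-increasing timecourse.

**Derivation.** `derive_kinetics()` inverts the model: `Tc = GF/m`,
`Ts = b/m`, `Li0 = b`. The identities `Li0 = GF*Ts/Tc` and `Tc - Ts = t*`
hold by construction and are asserted in the tests. An intercept above the
plateau (`b > GF`) is rejected as an inconsistent fit. Optional uncertainty
comes from a nonparametric bootstrap stratified by timepoint
(`bootstrap_kinetics()`, default 1000 resamples, seeded).

**Precision at realistic counting depth.** The rise-line slope is the
precision bottleneck: with duplicate samples of ~200 cells every 2 h up to
24 h (the bundled simulation design) the binomial counting noise is about
2.2 LI points per observation, giving a slope relative standard error near
30%. GF, a mean of many plateau points, recovers to a few percent, but Tc
= GF/m and especially Ts = b/m inherit the slope noise, with median
absolute relative errors of roughly 20-50% in the packaged simulations
(`scripts/acceptance.R` recomputes these). Cumulative-labeling kinetics at
this depth are therefore order-of-magnitude estimates unless cell counts
per sample reach the thousands; the simulation spec's `cells_per_sample`
lets users evaluate their own design before running it.

## 4. What the synthetic generators do and do not emulate

`simulate_trajectory()` draws genes as smooth mean curves in pseudotime —
logistic sigmoids for monotone trends (the field's archetypes: an *H2-K1*-
like decline, *Ki67*/*Tbr2*-like rises), constants, and a Gaussian bump for
transient programs — with multiplicative log-normal noise (mean-preserving,
`exp(N(-d^2/2, d))`) and Bernoulli dropout. Pseudotime is evenly spaced on
[0, 1]. Defaults of ~100-120 cells match the scale of published adult
hippocampal NSPC trajectories. Two modeling choices matter for
interpretation:

* **Dropout is expression-independent.** Real single-cell dropout is
  strongly anticorrelated with expression level; here it is a constant
  per-gene probability. Consequently "positive at CPM > 0" carries no
  trend information in synthetic data, and trend-linked positivity must be
  created through the mean curve falling below a positive threshold. The
  packaged end-to-end demonstration therefore places the declining gene's
  logistic midpoint (0.35) before the stage marker's rise onset (0.65) —
  biologically, the decline precedes the progenitor transition — and
  counts positivity at 1 CPM.
* No library-size or read-level noise is simulated: inputs are already
  CPM, and realism is validated only by downstream parameter recovery, not
  by resemblance to any particular dataset.

`simulate_labeling()` draws labeled counts `Binomial(cells, LI(t)/100)` per
replicate from the theoretical curve; `cells_per_sample = Inf` is a
noiseless sentinel returning the expectation exactly, used by the
round-trip identity tests. `simulate_cycling_population()` builds two
positivity groups with known cycling probabilities (defaults: 18 positive
cells with cycling probability 1/18, 82 negative with 20/82, matching the
observed study condition), assigns each cycling cell one active phase, and
elevates that phase's markers; with a 4x or larger separation between
cycling and noncycling marker means, default-threshold classification is
essentially perfect, which is what the accuracy tests demonstrate — they
say nothing about threshold choice on real, continuous score
distributions.

## 5. Stereological scaling and the pipeline

`estimate_total_count()` converts per-section immunopositive counts to a
whole-structure estimate by summing sections and multiplying by the
sampling multiplier (default 12, the reciprocal sampling fraction of a
series of 40-um sections spaced 240 um apart counted in one hemisphere).
Summation is the default because the multiplier is defined against the
summed sampled volume; per-section averaging is available
(`method = "mean"`) for designs quantified as cells per section.

`run_pipeline()` executes trajectory, cell-cycle, kinetics and
quantification stages from one JSON/YAML or in-memory configuration. All
randomness flows through the single configured seed, the report records the
seed and a hash of the configuration (excluding the output location), and
identical configurations produce byte-identical reports. File formats are
deliberately strict: duplicate ids, unmatched pseudotime cells, negative
CPM and non-numeric fields are rejected with located errors rather than
coerced.

## 6. Problem sizes and determinism in the packaged checks

The test suite and `scripts/acceptance.R` run entirely from generated
data: trajectories of 100-150 cells, labeling designs of 12 timepoints in
duplicate, 50 noiseless round-trip draws, 200 stochastic recovery
simulations, and an exhaustive Fisher comparison over all 2x2 tables with
row margins up to 30. These sizes make every check reproducible on a
laptop in well under a minute apiece while keeping the stochastic checks'
Monte Carlo error far below their decision margins. All simulations are
seeded; reruns are bit-identical.

## Known limitations

* The stage cutoff is defined on a smoothed curve; with noisy data the
  detected onset-of-rise can move substantially between seeds or spans.
  Report the span and grid used alongside any T1/T2 split.
* The cycling threshold (2 on median-normalized scores) is a convention,
  not an estimate; percentages of cycling cells are only comparable under
  the same threshold, transform and marker list.
* Kinetics assume a single homogeneous cycling population with
  time-invariant parameters; quiescence exit, subpopulation mixtures and
  label dilution are out of scope.
* The generators' noise model (log-normal plus uniform dropout) is a desk-
  scale idealization; passing tests demonstrate correctness of the
  estimators under the model, not robustness to real single-cell noise.
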