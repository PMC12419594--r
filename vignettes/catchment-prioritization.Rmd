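---
title: "Presence-only distribution models and catchment prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only distribution models and catchment prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`musselscape` models the distribution of freshwater mussel species across a
region of nested catchments from presence-only survey records, stacks the
per-species models into richness surfaces, and scores every catchment for
three conservation actions: species surveys, population restoration, and
land protection.  This vignette is the package's account of its methods:
the model, its assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where published practice leaves the design open.

## The data model

The analysis unit is the *catchment*: the land area draining directly to a
single stream segment.  Catchments nest inside hydrologic units (HUC12
inside HUC10 inside HUC8; larger code, smaller unit).  Four tables drive
the pipeline:

* `catchments.csv` — one row per catchment: HUC codes, state label,
  centroid coordinates, survey count;
* `covariates.csv` — per-catchment environmental values, each column
  tagged continuous or binary with a declared spatial scale;
* `occurrences.csv` — species occurrence records `(species, catchment,
  year, habitat)`;
* `surveys.csv` — survey events `(catchment, year)`;

plus `aux_covariates.csv` with the prioritization inputs (percent
protected land, percent forest, percent wetland, projected land-use
change, climate resilience).  Records are filtered to `year >= 1952` for
modelling — mussels are long-lived, so decades-old records can still
represent living animals — and to `year >= 1992` for the binary
"recently surveyed" indicator used by survey prioritization.  Both cutoffs
are configuration values, not constants, because the balance between
record relevance and sample size is a judgement call that should be
visible and changeable.

Covariates are screened before modelling: pairs with Spearman
`|rho| > 0.70` (strictly; an exact 0.70 is tolerated) lose their
lower-priority member, where the priority ordering `keep_priority` is an
explicit, reproducible stand-in for the expert judgement that usually
resolves which of two correlated variables is more ecologically relevant.
The procedure is a greedy pass in priority order and therefore
deterministic and row-order invariant.  Retained continuous covariates
must have variance inflation factors below 5 (`VIF_j = 1/(1 - R2_j)`);
exact collinearity is reported as an `Inf` sentinel.  One covariate is
deliberately exempt from screening: the species-specific HUC8-occurrence
layer, a binary column marking every catchment whose HUC8 contains a
record of the focal species.  It encodes historical range and dispersal
limitation and necessarily differs between species.

## Background selection under uneven survey effort

Maximum-entropy models assume every location had an equal chance of being
sampled.  Real mussel surveys are strongly clustered, so the background
("available environment") sample is corrected in three steps:

1. each catchment is represented once, by its centroid — all points in a
   catchment share one environment;
2. catchments inside HUC10s with *no* survey records (for any species) are
   excluded: the model should not learn the difference between surveyed
   and unsurveyed regions;
3. catchments with a known occurrence of the focal species are excluded.

From the survivors, up to `n_background` (default 10,000) catchments are
drawn by weighted sampling without replacement, the weight reflecting each
catchment's probability of having been surveyed.  Two published readings
of that weight are implemented: `catchment_share` (default; the share of
all survey events that occurred in the catchment) and `huc10_share` (the
encompassing HUC10's share, divided evenly among its candidate
catchments).  Under `catchment_share`, a never-surveyed but eligible
catchment would get exactly zero weight; a floor of `0.1/n_candidates`
(configurable, zero allowed) keeps the support positive while preserving
the bias correction.  Sampling is without replacement because a catchment
is one centroid — duplicates carry no information at this resolution.  If
the exclusions leave no more candidates than the cap, every candidate is
used, which is exactly how the widest-ranging species are handled in
practice.

## The maximum-entropy model

For species with presence catchments \(P\) and background catchments
\(B\), the model is the Gibbs distribution over the background,

\[ q_\lambda(i) = \frac{\exp(\lambda \cdot f_i)}{\sum_{j \in B}
   \exp(\lambda \cdot f_j)}, \]

with \(f_i\) the feature vector of catchment \(i\).  Fitting maximizes the
penalized presence log-likelihood

\[ \frac{1}{|P|}\sum_{i \in P} \lambda\cdot f_i - \log Z(\lambda)
   - \sum_j \beta_j |\lambda_j|,
   \qquad \beta_j = \beta \cdot \frac{s_j}{\sqrt{|P|}}, \]

where \(s_j\) is the feature's background standard deviation and
\(\beta\) is the regularization multiplier.  The per-feature scale
\(s_j/\sqrt{|P|}\) is a deliberate simplification of the class-specific
default-penalty tables used by the packaged MaxEnt implementations; the
multiplier grid absorbs the scale difference.  At the optimum the
Karush-Kuhn-Tucker condition pins every feature's presence expectation to
within its penalty of its model expectation:
\(|E_P[f_j] - E_q[f_j]| \le \beta_j\), with equality where
\(\lambda_j \ne 0\).  Every fit carries this certificate
(`model$kkt`), and the test suite re-derives it from the raw matrices.

**Features.**  Continuous covariates are rescaled to \([0,1]\) by their
background minimum and maximum, then expanded into the classical classes:
linear, quadratic, pairwise products, forward and reverse hinges, and step
thresholds, with knots at 10 evenly spaced background quantiles per
covariate (packaged implementations use denser data-driven knots; 10 keeps
desk-scale fits fast and is configurable).  Binary covariates get one
indicator per level and nothing else.  At prediction time the rescaled
values are clamped to \([0,1]\), so the model never extrapolates beyond
the background envelope.  A covariate constant over the background
contributes no features and is logged, not an error.

**Optimization.**  The objective is convex; the solver is accelerated
proximal gradient (FISTA) with backtracking and function-value restart,
stopped when the KKT slack falls below `1e-6` or the objective change
below `1e-9`, followed by an active-set Newton polish that drives the
stationarity residual to near machine precision.  One degeneracy needs
guarding: when a feature direction separates presences from background
faster than its penalty accumulates, the penalized optimum does not exist
(packaged implementations dodge this by adding presence samples to the
background, which this model deliberately does not).  Coefficients are
therefore box-bounded at \(\pm 50\) — enormous on the unit feature scale
— and a fit that stalls at the bound is returned flagged
(`certified = FALSE`, `at_bound = TRUE`) and noted in the run manifest
rather than erroring; this arises on tiny landscapes, not at the
reference scale.  On micro-instances the
result is checked against an independent dense optimizer (L-BFGS-B on the
split \(\lambda = \lambda^+ - \lambda^-\) formulation) to `1e-5` in
objective value.

**Output transforms.**  The raw values \(r_i = \exp(\lambda\cdot f_i -
\log Z)\) sum to one over the background.  The default display transform
is the logistic, \(e^H r_i / (1 + e^H r_i)\), with \(H\) the entropy of
the raw background distribution (the historical packaged default; the
empty model then scores 0.5 everywhere).  The complementary log-log
transform is available by flag.  The publication this design follows does
not state which transform it used; the choice only reorders nothing —
both are monotone in \(r\) — so thresholds and richness are computed
consistently on whichever transform is configured.

**Tuning.**  The multiplier is tuned over an integer grid (default 1..15)
by training AUC of presences against background, mirroring a
single-dataset selection procedure; ties go to the smaller (less
regularized) value, and cross-validation is reserved for the prediction
variability maps: presences are split into `k = 10` folds and the
per-catchment standard deviation of the refitted logistic predictions is
reported.  Whether published AUCs of this kind are training or
cross-validated values is usually unstated; the package reports training
AUC and labels it as such.

## Evaluation, thresholding, stacking

* **AUC** is the Mann-Whitney pair statistic (ties count one half),
  computed via ranks and exactly equal to brute-force pair counting; 0.7
  is the conventional acceptability bar.
* **Continuous Boyce Index**: 101 overlapping windows, each one tenth of
  the score range wide, slide across the evaluation scores; the index is
  the Spearman correlation between the predicted-to-expected ratio
  \(P/E\) and the window midpoint.  Both window parameters are
  configurable because only the index itself, not its discretization, is
  standardized.  Exact invariance under monotone transforms is *not*
  claimed: re-binning changes window geometry.
* **Threshold**: the score maximizing sensitivity plus specificity
  against background-as-pseudoabsence, scanning the pooled unique scores;
  a presence exactly at the threshold counts as predicted present, and
  ties resolve to the smallest threshold — both choices implement a
  greater-inclusion-than-exclusion stance, and are stated because
  packaged implementations differ.
* **Bookkeeping**: false negatives (recorded but predicted absent) and
  possible new catchments (predicted present, never recorded) are counted
  over the full landscape, not just the background.

Thresholded maps stack into overall richness and the richness of species
of conservation concern (RSGCN ranks very high, high, moderate).

## Priority scores

All criteria are min-max scaled to \([0,1]\) before combination, and each
composite is rescaled after summation, so every surface spans \([0,1]\)
whenever its inputs are non-constant.  A constant input scales to all
zeros — a convention, documented here, that a criterion with no contrast
contributes nothing; it cannot occur at regional scale.

* **Surveys** (everywhere): `scale(scale(richness) - surveyed_since_1992)`.
* **Restoration** (species of high or very high concern only): one shared
  habitat-quality surface, `scale(scale(protected) + scale(forest) -
  scale(landuse_change))`, with species-specific eligibility: catchments
  whose HUC8 holds no record of the species get *no score* (`NA`), not a
  zero — restoration happens inside the recorded range.
* **Protection** (everywhere): `scale(scale(richness) + scale(forest) +
  scale(wetland) + scale(resilience))`.

Ranked outputs break ties by catchment id so runs are reproducible
byte-for-byte.  Two ambiguities in the source material are resolved
explicitly rather than silently: the forest-cover scale (catchment-scale
column accepted, its declared scale label recorded) and the
protection-correlation sentence, which names percent protected land
twice; the implemented correlation is protection *priority* against
current percent protected land, the pairing the surrounding results
discuss.

## The synthetic landscape

Real inputs are multi-agency survey compilations and regional GIS layers
that cannot ship with a package.  The generator replaces them with a
world whose truth is known, so that every downstream stage is testable:

* a nested HUC8/HUC10/HUC12/catchment hierarchy laid out on a planar
  grid, catchments contiguous within their units, each HUC8 assigned a
  state label;
* spatially autocorrelated covariates: Gaussian-kernel-smoothed white
  noise over centroids with unit marginal variance (a range of zero gives
  independent noise; a range beyond the extent gives a spatially constant
  field).  A kernel smoother rather than a full Gaussian process: only
  the rank structure matters downstream.  One binary covariate (a
  tidal-influence analogue) is made by thresholding a smoothed field at
  its 80th percentile, so it forms spatial clusters;
* species with known logistic truth: suitability is the inverse-logit of
  a sparse linear predictor, the intercept root-found so mean suitability
  equals a prevalence target to within `1e-6`.  The published method has
  no explicit truth model; a logistic link makes parameter recovery
  well-defined;
* uneven survey effort: HUC10 weights from a symmetric Dirichlet (one
  concentration knob spans the unsurveyed-HUC10 regime through
  near-uniform effort), catchment uniform within HUC10, years uniform
  over 1948-2022;
* imperfect detection: latent occupancy is a Bernoulli draw from the
  truth; each survey of an occupied catchment yields a record with
  probability `detection_prob`.  Output is presence-only.

**Default scale and calibration.**  The reference configuration is 12
species over ~5,000 catchments (6 HUC8 x 4 HUC10 x 5 HUC12 x 42), about
1/13 of the real region, with 4,000 survey events at Dirichlet
concentration 0.5 and detection probability 0.8.  Species prevalences
spread from 5% to 35%, matching the span of published
percent-of-catchments occupancy, and the RSGCN composition is two very
high, three high, two moderate, five unlisted.  Effect sizes are drawn
with magnitudes 2-3.5 over three or four covariates: this makes the
*truth model's own* discrimination of occupied from unoccupied catchments
(AUC ceiling ~0.93-0.99) comparable to the published fits (0.94-0.99).
That calibration matters: with weak effects even an oracle that knows the
truth cannot reach the recovery levels the generator exists to verify, so
the check would be vacuous rather than stringent.

**Scaled background cap.**  `demo_pipeline_config()` caps background at
2,000 rather than 10,000.  At 1/13 scale the candidate pool is ~4,200, so
the full-scale cap would silently return every candidate and the
survey-probability weighting — the centerpiece of the bias correction —
would never run.  The original cap was ~18% of its candidate pool; 2,000
keeps the weighted sampling engaged.  `pipeline_config()` itself keeps
the full-scale default of 10,000.

**What the generator does not emulate** — and hence what a green test
does not establish: real hydrography (flow direction, upstream
accumulation, network connectivity), reach-scale habitat, spatial error
in record georeferencing, temporal nonstationarity of habitat, and
covariate measurement error.  Recovery results on the synthetic landscape
show the estimator works when its assumptions hold; they are not evidence
about any particular real region.

## Numerical conventions

* Solver: objective tolerance `1e-9`, KKT tolerance `1e-6`, Newton polish
  to ~`1e-10`; features with zero background variance are excluded from
  fitting (coefficient fixed at zero).
* Determinism: every stochastic step takes a seed derived from the master
  seed; reruns are byte-identical, and the run manifest (config, seed,
  chosen multipliers, warnings) suffices to reproduce a run.
* Degenerate inputs fail loudly: empty background candidate sets, constant
  covariate columns, constant prediction vectors for the Boyce index, and
  fewer presences than folds are errors with named causes; a constant
  HUC8 layer or a failed grid value during tuning is skipped with a note
  in the manifest.

## Interface note

The package is operated from R: `run_pipeline()` is the one-command
orchestrator (with `demo_pipeline_config()` for the reference synthetic
run), and each stage — generation, screening, background selection,
fitting, tuning, evaluation, richness, prioritization — is an exported
function usable in isolation.  `scripts/acceptance.R` wraps the reference
run for shell use; no separate command-line binary is shipped, since the
intended users work in R.

## Known limitations

* Training AUC for multiplier selection favours weak regularization on
  separable data; the grid's upper range matters only when presences are
  few.
* The per-feature penalty scale is simpler than packaged MaxEnt's
  class-specific schedule, so chosen multipliers are not numerically
  comparable to published ones (the grid absorbs the difference).
* Possible-new-catchment counts depend on the threshold's
  inclusive-tie convention; with heavily tied score distributions other
  conventions give different counts.
* The catchment-share weighting approximates the probability a catchment
  was *surveyed* by its share of survey *events*; where repeat visits are
  common the two diverge, and detection near one makes the event-share
  weight an overcorrection.
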