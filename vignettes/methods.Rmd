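---
title: "Induced risk stratification: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Induced risk stratification: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskstrat)
```

## The modelling setting

`riskstrat` studies an *induced* classification task. A continuous risk
index is constructed from harmonized signals, discretized into ordinal
classes at its empirical quantiles, and models are then trained to
recover those classes from the same signal space. Performance metrics in
this setting measure how faithfully a model family reproduces the
structural organization of the induced risk space — not predictive power
for any external clinical outcome. Two consequences shape everything
else in the package:

* a trivial baseline that routes the index through the fitted quantile
  edges reconstructs the classes exactly on its fitting partition
  (accuracy 1.000 whenever the index is tie-free), upper-bounding every
  learned model; and
* high headline metrics for learned models must be read as internal
  coherence, never as generalization to real outcomes.

An optional, fully independent outcome path (`threshold_outcome()`)
thresholds a *raw* clinical column, untouched by any transform, for
analyses that need a label not derived from the representation. It is
disabled by default because the induced classes drive every standard
report.

## Harmonization

Each raw variable is declared in a manifest with a semantic kind, a risk
direction (+1/−1/0), plausibility bounds or a code map, and optional
sentinel codes treated as missing. The pipeline:

1. recodes sentinels to missing, removes exact duplicate rows (string
   normalization, no fuzzy matching), and blanks continuous cells
   outside their plausibility range;
2. drops any variable whose missing fraction *strictly* exceeds
   τ~m~ (default 0.3) — the boundary value itself is retained;
3. imputes (median for continuous, mode for categorical — mode ties go
   to the smallest encoded value so no seed is involved) and then
   standardizes continuous variables with the *population* standard
   deviation. Imputing first guarantees a complete matrix feeds the
   moment estimates and keeps one code path; the convention is recorded
   in `transform_params`. A zero-variance column becomes the constant 0
   with a flag rather than an error;
4. stores every statistic (μ, σ, median, mode, code map, reference
   value) so `apply_transform()` can map new records — including the
   held-out partition — without re-estimating anything. Unknown
   categorical codes at apply time are treated as missing and imputed
   with the fit-time mode.

## Risk index and quantile classes

The package's default index is the simplest construction consistent
with a direction-annotated signal space: an equal-weight, direction-
signed linear combination over the signals with nonzero direction,
`score = Σ w_j d_j s_j`, with the weights exposed in configuration so
alternative indices are pluggable. Interior class edges are the k/K
empirical quantiles (order-statistic interpolation, R type 7); a score
equal to an edge falls in the lower class, which makes labelling
deterministic under ties. With tie-free scores class sizes differ by at
most one, and any strictly increasing transformation of the index leaves
the labels unchanged.

## Hybrid model and the weight search

The two base learners have complementary inductive biases: a multinomial
logistic regression (global linear boundaries, stable under
distributional shifts) and a probability random forest (local,
interaction-capable). Fixed settings, all surfaced in
`default_hyperparams()`:

| parameter | default | note |
|---|---|---|
| logistic penalty grid C | 0.01, 0.1, 1, 10 | chosen by 5-fold CV macro-F1; penalty weight is 1/C |
| logistic iteration cap | 3000 | warns (not fails) on non-convergence |
| forest size | 500 trees | probability forest, one thread for determinism |
| minimum leaf size | 3 | capacity control |
| weight grid | 0.0–1.0 step 0.1 | convex combination weight on the linear model |
| split / folds | 70/30, 5 folds | stratified by induced class |

The aggregate is `R(x) = w f_lin(x) + (1 − w) f_rf(x)` on class
*probability vectors* (so combined rows remain distributions), with the
continuous representation defined as the expected ordinal class
`Σ_c c · P(class = c | x)`. The probability-vector reading is the one
that supports both ROC analysis and a continuous `R(x)` for correlation
and attribution.

Two losses appear in training because they do different jobs: macro-F1
selects the logistic penalty (it is the criterion that exposes
class-balance failures), while mean multiclass cross-entropy selects the
combination weight — the weight search is a loss minimization over the
combined probabilities and cross-entropy is its natural instantiation.
Both are recorded per candidate. The search loop fits the base models
once per fold and scores every candidate weight on the cached validation
probabilities; this is algebraically identical to refitting per
candidate, eleven times cheaper, and makes ties exact. Weight ties go to
the larger nonlinear share; argmax ties in prediction go to the lower
class. All randomness (split, folds, forest) fans out from one integer
seed recorded in the training metadata.

The held-out partition is never visible to harmonization statistics,
penalty selection, or the weight search: the pipeline fits its
transforms and quantile edges on the training rows alone and maps the
test rows through `apply_transform()` and the stored edges.

## Attribution and perturbation

The attribution of signal *j* for record *x* is
`Φ_j = R(x) − R(x^(j))`, where `x^(j)` replaces the j-th signal with its
training-set reference (median of the transformed continuous signal,
mode of the encoded categorical signal). This one-at-a-time,
fixed-reference scheme is deterministic and requires no sampling over
feature coalitions. It is *not* an exact additive decomposition for the
hybrid model: `Σ_j Φ_j` equals `R(x) − R0` only in the linear limit, and
the package intentionally asserts additivity only there. Dataset-level
summaries normalize mean absolute contributions to sum to one;
rescaling `R` leaves the normalized shares unchanged.

Perturbation sensitivity applies a kind-specific shift — +1 SD on the
transformed scale for continuous signals, +1 level capped at the top for
ordinal, set-to-risk-present for binary — and reports the mean absolute
change in `R` with the fractions of positive, negative, and exactly-zero
changes (zeros are tracked separately rather than folded into either
sign; ordinal records already at the top level are the typical source).
The magnitudes are configuration, not science: sign patterns on real
data are data-dependent geometry.

## Evaluation conventions

Macro averages weight classes equally; classes absent from the truth are
excluded with a warning, and a class never predicted contributes
precision 0 (this is exactly the regime where a linear model collapses
minority induced classes, and silently dropping it would hide the
failure). ROC-AUC is one-vs-rest on class probabilities, macro-averaged,
with ties counted half (the implementation delegates to trapezoidal AUC;
the test suite checks it against a brute-force all-pairs concordance
oracle). Fold stability reports mean, *sample* standard deviation
(ddof = 1), and `log10(1 − m)` per fold, with metrics within 10⁻⁶ of 1
capped at distance −6 and flagged. Fold metrics come from each fold's
validation part within the training partition — never from the test
partition.

## The synthetic generator

`generate_cohort()` emulates the *structure* the framework assumes, not
the marginals of any real survey. One standard-normal latent factor `u`
drives every signal through `loading · u + noise`; continuous signals
are affinely rescaled to clinical-looking ranges (arbitrary presentation
constants), ordinal signals are cut into five ordered levels, binary
signals threshold at zero with survey-style 1/2 codes. Missingness is
planted completely at random — the framework treats missingness only by
threshold-exclusion plus imputation, so richer mechanisms would exercise
nothing. Defaults (loadings 0.8, noise SD 0.5, 5% missingness; clinical
archetype 6 continuous + 5 binary, behavioral/integrated 2 continuous +
3 ordinal + 4 binary) are the package's canonical study conditions for
its recovery checks.

The `nonlinearity` option exists to make the linear/nonlinear model gap
reproducible in kind. Its design needs care: tertiles of any *linear*
index of the signals are representable by a linear decision surface, and
a *monotone one-sided* threshold sum of a single-factor structure is
itself well approximated by a plane — neither can separate the model
families even in principle. The planted nonlinear score is therefore an
exact function of the *observed* signal space with a non-monotone
component: in `"threshold"` mode each continuous signal contributes a
two-sided diagnostic-cutoff indicator (deviation beyond 0.8 SD in either
direction — the J-shaped risk profile familiar from BMI, blood pressure,
and glycemia), in `"interaction"` mode pairwise products of continuous
signals; non-continuous signals contribute their observed encodings.
Model-gap analyses label records by quantile-discretizing this planted
score with the package's own discretizer. A flexible learner can
reconstruct those classes; a linear surface cannot, which reproduces the
direction (not the magnitudes) of the gap seen on clinical-heavy data.

What passing tests on these cohorts show — and do not show: they verify
the mechanics (fit/apply separation, quantile construction, convexity,
attribution algebra) and directional phenomena (baseline ceiling, model
gap under planted nonlinearity, fold-dispersion shrinking with n). They
say nothing about real surveys' non-random missingness, coding drift
across cycles, survey weights (deliberately unhandled), or multi-factor
risk structure (a single latent factor is the default; the generator is
not a realism claim).

## Problem sizes and numerical choices in the shipped checks

The package's own test suite runs its statistical checks at n = 2000–
5000 with 20-seed majorities for directional claims — large enough that
the directions are stable, small enough to keep a full run in the
minutes range. Degenerate inputs are contracts, not crashes: constant
risk index errors with a pointer to the index weights; a singleton
weight grid skips the search; folds that lose a class are skipped with a
warning, and only if all folds are lost does the search error.

## Known limitations

* The risk index is an induced construct; nothing here validates it
  clinically, and attribution rankings describe the fitted geometry,
  not causal importance.
* Median/mode imputation is the only supported mechanism, by design.
* The logistic/forest pair is fixed; `combine_probabilities()` is
  written for any number of probability matrices, but the training
  loop deliberately instantiates exactly two base models.
* Probabilities are not calibrated; the cross-entropy weight search
  partially rewards calibration, which is why a memorizing forest can
  dominate on tasks whose labels are deterministic in the signals.
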