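---
title: "Assessing vocal individuality and its sampling biases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing vocal individuality and its sampling biases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalid)
library(dplyr)
```

`vocalid` implements a complete pipeline for asking two questions about a
set of animal calls: *how much individual identity do these calls carry?*
and *how badly do study-design choices — number of individuals, number of
calls per individual, choice of features — bias the answer?* This vignette
explains the models behind each stage, the tunable parameters and why their
defaults are what they are, and what the synthetic data generator can and
cannot stand in for.

## The classification model

Calls arrive as a table: one row per call, an `individual` label, and
numeric features — typically fundamental-frequency (F0) measurements at
evenly spaced points along the call (`F1..F20`, in Hz), a `duration` (s),
or whole-call spectral summaries (`minF`, `q25`, `dF`, `q50`, `q75`,
`maxF`, in Hz).

`classify_loo_lda()` assigns each call by linear discriminant analysis
under leave-one-out cross-validation: the model is refitted on all other
calls and the held-out call goes to the individual with the highest
posterior. Two modelling commitments matter:

- **Equal priors**, `1/n` per individual. Monitoring asks "which of these
  n individuals called?", not "which individual calls most often?", so
  class frequencies in the training sample are deliberately ignored.
  Class-frequency priors are not offered.
- **Pooled within-individual covariance** (the LDA assumption). The fit is
  delegated to `MASS::lda(CV = TRUE)`. When a training fold is singular
  (more features than calls, or collinear features) `MASS::lda` either
  errors or returns `NA` posteriors; the package then refits with a
  ridge-regularized pooled covariance (diagonal inflation
  `1e-8 * trace/dim`) and warns. On well-conditioned data the ridge never
  activates, so exactness — including invariance to affine rescaling of
  single features — is preserved.

`classify_similarity()` implements the decision rule used with spectrogram
cross-correlation: average the query call's similarity scores to each
individual's calls and take the argmax. The query's self-score (always the
diagonal maximum) is excluded from its own individual's average by default;
including it would leak a perfect match and make the rule incomparable with
the cross-validated LDA. Exclusion requires at least two calls per
individual. `exclude_self = FALSE` is available for sensitivity analysis.

Both classifiers break score ties toward the lexicographically smallest
individual label and flag the tie per call, so downstream metrics are
deterministic and auditable.

## Two levels of accuracy and the plurality rule

Call-level accuracy is the proportion of single calls assigned correctly —
the trace of the confusion matrix over its total. Individual-level accuracy
applies the plurality ("majority") criterion: a whole call set (a calling
bout recorded from one bird) is attributed to the individual that received
the most of its calls. The criterion is a strict mode, *not* a >50% rule: a
row whose own column holds 8 of 20 calls (40%) while every competitor holds
fewer is scored correct. Tied modes are conservatively scored incorrect and
surfaced in the `ties` column of `discrimination_summary()`, rather than
resolved at random, so repeated runs agree.

```{r fig2}
asg <- data.frame(
  individual = rep(c("A", "B", "C"), each = 20),
  predicted = c(
    rep(c("A", "B", "C"), c(15, 3, 2)),
    rep(c("A", "B", "C"), c(2, 15, 3)),
    rep(c("A", "B", "C"), c(7, 5, 8))
  )
)
discrimination_summary(asg)
```

63% of calls correct, 100% of individuals correct: optimizing a method on
call-level numbers alone can pick the wrong method for monitoring.

## Beecher's information statistic

`compute_hs()` quantifies identity information in bits. Features are
standardized to zero mean and unit variance, rotated by PCA (so the
correlation structure, not the raw scales, defines the axes), and each
component contributes

$$H_i = \log_2 \frac{F + n - 1}{n},$$

where $F$ is the one-way ANOVA F-statistic of the component scores with
individual as the factor and $n$ the number of individuals; the total is
$H_S = \sum_i H_i$. Implementation choices:

- **All components are retained** — no variance cutoff, and components with
  non-significant F still enter. $F = 1$ (no between-individual signal)
  contributes exactly 0 bits; $F < 1$ contributes negative bits, which is
  retained.
- Component signs are arbitrary (F is sign-invariant), and numerically
  zero-variance components from rank-deficient inputs are dropped since a
  constant carries no information.
- Unbalanced designs (unequal calls per individual) use the ordinary
  one-way F. The per-component F values are assembled from a single
  multivariate `lm` fit; the unit tests cross-check them against
  `anova(lm(...))` and a hand-written mean-squares oracle.

`estimate_discriminable_n()` converts bits to a head count,
$N = P \cdot 2^{H_S}$, where $P$ is the probability that a target
individual's signature is not duplicated in the group. The default
$P = 0.9$ matches the practical reliability of colour-ring resighting;
$N$ is reported both raw and rounded to the nearest integer.

A caution the package makes easy to see with `hs_population_curve()`:
$H_S$ is not independent of how many individuals were sampled. On both
field and synthetic data it typically peaks after a handful of individuals
and declines as more are added, so $H_S$ values from studies with
different sample sizes are not directly comparable, and a feature set
should be ranked by $H_S$ only against alternatives measured on the same
sample.

## The resampling experiments

All simulations share one design: randomness enters only through an integer
`seed`, and within each repetition the individual subsets are *nested* —
individuals are added one at a time along a random ordering — rather than
drawn independently at each size. Nesting mirrors how a monitoring
population actually grows, and makes the per-repetition curves smooth.

- `sweep_population_size()` evaluates the classifier at growing population
  sizes; accuracy declines toward the full-set value as more individuals
  compete.
- `sweep_calls_per_individual()` subsamples `k` calls per individual
  without replacement at each step (`k >= 2`; leave-one-out is undefined at
  one call). Individuals with fewer than `max(calls)` calls are excluded
  with a warning so every step compares the same individuals.
- `monitorable_population()` combines both: at a fixed number of calls per
  individual it scans population sizes and returns the largest size whose
  *mean accuracy over repetitions* still meets the criterion — at least 90%
  of individuals correct (the colour-ring standard) or at least 65% of
  calls correct. The mean-then-threshold reading (rather than thresholding
  each repetition and averaging) is the interpretation adopted here.
  When the criterion holds at every scanned size the result is flagged
  `open_ended`: the dataset, not the method, set the limit.
- `prescreen_models()` emulates a pilot study: mean H_S on random
  `subset_size`-individual pilots (the same pilots for every candidate
  feature set, so models are compared fairly), full-set H_S and LDA
  performance, and the pilot-predicted head count versus the realized one,
  `n_realized = round(individual_accuracy * n)`.
  `correlate_prescreen()` summarises the association with Spearman rank
  correlations and an OLS regression with intercept (slope, F, adjusted
  R², p) — the linear form is the natural null because a perfect pilot
  would put every model on the `y = x` line.

The candidate family `measuring_point_specs()` covers prefix sets `F1..Fk`
and alternating-point subsets (every 2nd/3rd/4th point) — 23 models at 20
measuring points. It is a configurable default, not a canonical list; any
list of feature specs can be screened.

## What the synthetic generator does and does not emulate

`generate_population()` draws, per individual, a stable mean F0 contour
(base contour plus Gaussian offsets with SD `between_sd` per feature), then
adds independent Gaussian noise with SD `within_sd` to every call, and
clips all features to `feature_bounds`. Defaults are matched to a published
54-male little owl study and are treated as fixed study conditions, not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 54 | the study population |
| `calls_per_individual` | `(26.9, 6.0, 20, 41)` | observed mean ± SD and range of calls per male; drawn by rounding a truncated Gaussian via its inverse CDF (one uniform per individual, so the RNG stream is draw-count stable) |
| `n_features` | 10 | F0 measured at 10 points, the study's working description |
| `between_sd`, `within_sd` | 70, 70 Hz | total per-feature SD `sqrt(70² + 70²) ≈ 99` Hz matches the observed ~98 Hz SD of minimum call frequency; the 1:1 split gives realistic, imperfect discrimination |
| `feature_bounds` | 500–2000 Hz | the study's band-pass; clipping (not resampling) keeps generation deterministic |
| base contour | linear 776 → 1668 Hz | the observed mean minimum and maximum call frequencies |

Gaussian between- and within-individual variation is the minimal model
consistent with LDA's own assumptions, which is exactly what makes
classifier behaviour analyzable (chance level, saturation, monotonicity in
`between_sd/within_sd` are all predictable). The generator does **not**
emulate: correlation between adjacent measuring points beyond what the
shared contour induces, bout-level variance components (calls from
different bouts are more variable than within a bout, so real-data accuracy
will tend to be lower than same-bout accuracy), amplitude features, or
recording noise. Passing tests on synthetic data therefore demonstrate the
*statistical machinery* is correct, not that any particular species is
discriminable.

`derive_similarity_matrix()` maps a feature table to a synthetic
cross-correlation analogue, `exp(-d²/(2·ls²))` on standardized Euclidean
distance. The default `length_scale = sqrt(n_features)` keeps the
same-versus-different-individual score contrast stable as features are
added, because expected squared distance grows linearly with dimension.
Real cross-correlation matrices are ingested with
`read_similarity_matrix()`; asymmetric (template-direction) input is
symmetrized by averaging with its transpose, an idempotent and recorded
operation.

## Numerical and degenerate-input policy

- Score ties: lexicographically smallest label, flagged per call; plurality
  ties: incorrect, counted.
- Singular LDA folds: ridge `1e-8 * trace/dim`, with a warning; never
  applied to well-conditioned data.
- Constant feature columns: dropped with a warning (classification and
  H_S); an all-constant feature set is an error.
- Individuals with one call: tolerated at ingestion with a warning, fatal
  for any leave-one-out or self-excluded computation.
- `N` from `estimate_discriminable_n()`: rounded to the nearest integer
  (0.9 · 2^6.94 ≈ 110.6 → 111).
- Percentages are reported at full precision; round only for display.

## Problem sizes used by the test suite

The shipped tests run entirely on generated data at deliberate scales:
Monte-Carlo checks of chance level and of the H_S null use 50 replicate
datasets of 10 individuals × 10 calls; the signal-ratio grid uses 20
replicates at each of five `between_sd/within_sd` ratios with 20
individuals × 10 calls; the chance-tracking population sweep uses twelve
54-male noise datasets. These sizes put Monte-Carlo standard errors well
below the effect sizes being asserted while keeping the whole suite in the
order of seconds.

## Known limitations

- The LDA and similarity rules are the two classifiers evaluated here;
  random forests or neural alternatives are out of scope.
- H_S inherits the one-way ANOVA framework: temporal non-independence of
  calls within a bout inflates F and hence H_S; treat absolute bit values
  with care and prefer within-study comparisons.
- The pre-screening regression assumes the pilot subsets are exchangeable
  with the full population; spatially or socially structured populations
  violate this.
- Audio ingestion, spectrogram computation, and cross-correlation scoring
  itself are out of scope: the package consumes feature tables and score
  matrices.
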