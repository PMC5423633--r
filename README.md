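# vocalid

Quantitative assessment of vocal individuality and of the biases that
afflict it.

Many vertebrates have individually distinctive calls, which makes acoustic
monitoring of known individuals an attractive, non-invasive alternative to
trapping and marking. But the discrimination performance a study reports is
not a property of the species alone: it depends on how calls are described,
how many individuals are in the comparison, and how many calls per
individual were recorded. `vocalid` packages the full assessment pipeline
for tabular call-feature data (e.g. fundamental-frequency contours of owl
territorial calls) so those biases can be measured instead of guessed:

- **Call classification.** Leave-one-out linear discriminant analysis with
  equal priors (`classify_loo_lda()`), and the average cross-correlation
  score rule for pairwise spectrogram similarity matrices
  (`classify_similarity()`).
- **Two levels of accuracy.** Per-call accuracy and per-individual accuracy
  under the plurality ("majority") criterion, where a whole calling bout is
  attributed to the individual receiving the most of its calls
  (`discrimination_summary()`). A 40% plurality can identify an individual
  perfectly, so the two levels can tell very different stories.
- **Beecher's information statistic.** `compute_hs()` rotates standardized
  features by PCA and sums per-component identity information
  `H_i = log2((F + n - 1) / n)` (one-way ANOVA F, `n` individuals) into
  `H_S`; `estimate_discriminable_n()` converts it to a population size via
  `N = P * 2^H_S`, with `P = 0.9` mirroring colour-ring reliability.
- **Bias simulations.** Resampling sweeps over population size
  (`sweep_population_size()`), calls per individual
  (`sweep_calls_per_individual()`), the largest reliably monitorable
  population (`monitorable_population()`), the H_S-vs-sample-size curve
  (`hs_population_curve()`), and pilot-study pre-screening of candidate
  feature sets (`prescreen_models()`, `correlate_prescreen()`).
- **Synthetic data.** `generate_population()` draws call-feature datasets
  with controlled between- and within-individual variation (defaults emulate
  a 54-male little owl study: 20–41 calls each, F0 in 500–2000 Hz), and
  `derive_similarity_matrix()` turns any feature table into a synthetic
  similarity matrix, so every stage is testable without recordings.

Everything is tibble-first: results are tidy tables (or carry `tidy()` /
`glance()` methods) and plot via `autoplot()`.

## Worked example

```r
library(vocalid)

calls <- generate_population(seed = 1)   # 54 males, 20-41 calls each, F1..F10
res <- classify_loo_lda(calls)
glance(res)
#> # A tibble: 1 × 5
#>   call_accuracy individual_accuracy n_individuals n_calls  ties
#>           <dbl>               <dbl>         <int>   <int> <int>
#> 1         0.613                   1            54    1541     0
```

At the call level only 61% of 1541 calls are assigned correctly, yet every
one of the 54 males is identified once his whole call set is attributed by
plurality — the gap between the two levels is the point.

```r
hs <- compute_hs(calls)
hs
#> Beecher's information statistic
#>   H_S = 5.959 bits over 10 components (54 individuals, 1541 calls)
estimate_discriminable_n(hs)
#> # A tibble: 1 × 4
#>      hs     P n_raw     n
#>   <dbl> <dbl> <dbl> <int>
#> 1  5.96   0.9  56.0    56
```

About 6 bits of identity information, enough for roughly 56 individuals at
90% signature uniqueness. How does recording effort change the picture?

```r
sw <- sweep_calls_per_individual(calls, calls = c(2, 5, 9, 14, 20),
                                 n_reps = 5, seed = 1)
tidy(sw)
#> # A tibble: 5 × 7
#>   axis     step mean_call_accuracy se_call_accuracy mean_individual_accuracy
#>   <chr>   <int>              <dbl>            <dbl>                    <dbl>
#> 1 n_calls     2              0.202          0.0199                     0.130
#> 2 n_calls     5              0.458          0.0148                     0.6
#> 3 n_calls     9              0.570          0.0103                     0.907
#> 4 n_calls    14              0.583          0.00549                    0.967
#> 5 n_calls    20              0.599          0.00243                    0.993
autoplot(sw)
```

Call-level accuracy saturates early (57% by 9 calls), but individual-level
accuracy keeps climbing to 99% at 20 calls per male: extra recording effort
pays off at the level that matters for monitoring.

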