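# gbmsize

Tools for studying the prognostic effect of tumour size on overall
survival (OS) in glioblastoma (GBM), and for understanding why similarly
sized cohort studies disagree about it.

Published GBM prognostic models are inconsistent on whether pre-operative
tumour size — maximum core diameter (cm), core volume (CV, cm³) or whole
volume (WV = core + peritumoural oedema, cm³) — predicts survival. Two
methodological suspects are the sample size at which models are built and
the handling of skewed volume distributions (linear vs log-transformed
covariates). `gbmsize` implements the full study design needed to probe
both, for biostatisticians and imaging researchers who want to reproduce,
extend or stress-test this kind of analysis:

* **A synthetic cohort generator** (`cohort_config()`, `generate_cohort()`)
  calibrated to a published single-centre cohort of 279 IDH-wildtype
  unifocal GBM patients: quartile-matched marginals (lognormal volumes,
  truncated-normal diameter and age), a Gaussian copula joining the three
  size measures, a proportional-odds surgery–size association, a Weibull
  proportional-hazards outcome and uniform potential censoring. Real
  patient data are confidential; the generator is the reproducible stand-in
  population.
* **Cox modelling** (`fit_cox()`, `build_model_suite()`,
  `fit_penalized_spline()`): the hazard for patient *i* is
  `h_i(t) = h0(t) · exp(β·size_i + γ'z_i)` with `size` entered raw or as
  `log(size)` and `z` any subset of {age, sex, surgery, oncology, MGMT};
  inference on the size effect uses the Wald test `β̂/se(β̂)` and Harrell's
  concordance, with penalised splines (AIC-chosen smoothness) as the
  non-linearity check. 42 models make up the full suite.
* **The bootstrap resampling experiment** (`run_resampling()`): for sample
  sizes `n ∈ {50, 100, 150, 200, 250, 258, 279}` draw resamples with
  replacement, refit, and record the percentage of resamples in which the
  size coefficient's Wald p falls below 0.05/0.01/0.001 — the probability
  of "finding" the prognostic effect at each cohort size — plus
  Kolmogorov–Smirnov comparisons of the p-value distributions
  (`ks_compare()`, `compare_extremes()`).

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
`autoplot()` figures; a command-line interface (`exec/gbmsize`, wrapping
`cli_simulate()`, `cli_fit()`, `cli_resample()`) drives the same pipeline
from a shell.

## Worked example

```r
library(gbmsize)

cohort <- generate_cohort(cohort_config(seed = 1))
summarize_cohort(cohort)
#> Cohort of 279 patients, 236 deaths
#>   KM median OS 10.8 months (95% CI 8.6-13.1); median follow-up 42.9 (max 64.3)
#> # A tibble: 4 × 5
#>   variable    median    q1     q3   mean
#>   <chr>        <dbl> <dbl>  <dbl>  <dbl>
#> 1 age          62.2  56.3   68.9   62.4
#> 2 diameter_cm   4.19  3.21   5.32   4.20
#> 3 cv_cm3       24.9  13.2   52.2   40.3
#> 4 wv_cm3       83.2  48.4  177.   137.
```

One synthetic cohort behaves like the real one: 236 deaths among 279
patients, a Kaplan–Meier median OS near 12 months (10.8 in this draw —
single-cohort medians scatter by a month or two; the replicate average is
12.0), and size summaries near the published `4.4 / 28.1 / 103.3`
medians. Fitting the operation-adjusted log(WV) model:

```r
fit <- fit_cox(cohort, model_spec("wv", "log", adjustment = "surgery"))
glance(fit)[, c("hr", "conf_low", "conf_high", "p_value", "concordance", "n_used")]
#> # A tibble: 1 × 6
#>      hr conf_low conf_high p_value concordance n_used
#>   <dbl>    <dbl>     <dbl>   <dbl>       <dbl>  <int>
#> 1  1.29     1.11      1.50 0.00112       0.575    279
```

The hazard ratio 1.29 per log-unit of WV (95% CI 1.11–1.50, p = 0.001)
recovers the generator's true effect (HR e^0.22 ≈ 1.25), and the
penalised-spline check confirms the log-linear shape
(`fit_penalized_spline(cohort, "wv", transform = "log")` reports
`edf = 1.00`, i.e. no detectable non-linearity). The resampling
experiment then asks: *at what cohort size would this effect actually be
detected?*

```r
res <- run_resampling(cohort, resampling_config(
  repetitions = 5000, thresholds = 0.05, master_seed = 1,
  model_specs = list(model_spec("wv", "identity", "surgery"),
                     model_spec("wv", "log", "surgery"))
))
resampling_table(res, 0.05)
#> # A tibble: 7 × 3
#>       n `wv + surgery` `log(wv) + surgery`
#>   <int>          <dbl>               <dbl>
#> 1    50           19.0                27.9
#> 2   100           33.0                47.5
#> 3   150           48.1                65.7
#> 4   200           61.4                78.0
#> 5   250           74.3                87.5
#> 6   258           76.1                88.9
#> 7   279           80.4                90.4
```

Read: a 50-patient study of this population would report a significant
WV effect only ~19% of the time (28% with log transformation), rising to
80%/90% at the full 279 — sample size and the log transform jointly decide
whether "WV is prognostic" appears in print. `autoplot(res)` draws the
power curves; `autoplot(res, type = "pvalues")` the p-value boxplots;
`compare_extremes(res, "log(wv) + surgery")` formalises the n = 50 vs
n = 279 distribution shift.

The same pipeline runs from the shell:

```sh
gbmsize simulate --config inst/extdata/paper_like.yaml --seed 1 --out out/
gbmsize fit      --cohort out/cohort.csv --out out/
gbmsize resample --cohort out/cohort.csv --repetitions 10000 --out out/
```

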