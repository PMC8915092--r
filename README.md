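# wristhrv

Time-domain heart-rate-variability (HRV) analysis from the gappy
instantaneous heart-rate series exported by wrist-worn PPG devices, with a
validation pipeline against a chest-strap-grade reference.

Wrist wearables estimate heart rate optically and their exported series
are biased, noisy, interrupted by dropouts and occasionally corrupted by
ectopic-beat-like events. This package is for researchers and engineers
who want to derive the standard time-domain HRV indices — SDNN, RMSSD,
pNN50, SDNN index, SDANN — from such data and quantify how trustworthy the
result is. It implements the whole correction chain:

1. **Imputation** — eleven classical gap-filling methods (mean, ffill,
   bfill, linear, quadratic/cubic spline, PCHIP, Akima, EWMA, nearest,
   k-nearest-slot mean) benchmarked by RMSE on artificially masked slots,
   plus an Augmented Dickey–Fuller stationarity diagnostic.
2. **Wrist→reference mapping** — eight model families (multinomial
   logistic, kNN, decision tree, random forest, AdaBoost.R2, linear
   regression, RNN, LSTM) tuned by exhaustive grid search under 5-fold
   cross-validation on negated MSE, with a subject-stratified 75/25
   chronological split and a final test-RMSE ranking in bpm.
3. **Pseudo-IBI reconstruction** — IBI[ms] = 60000 / HR[bpm], one
   interval per sample.
4. **Artifact correction** — the Malik (20%), Karlsson (20%), Kamath
   (+32.5% / −24.5%) and Acar (20% of the last-9 mean) rejection rules
   with cubic-spline replacement, and R²-based rule selection against a
   reference.
5. **HRV indices and validation** — per-subject summaries and paired
   Student t-tests (two-tailed p, one-tailed critical values, df = n − 1)
   comparing the pipeline against the reference.

A seeded synthetic paired-device cohort generator (respiratory-sinus
oscillation + AR(1) noise + drift; configurable bias, noise, dropouts and
ectopics) provides known ground truth so every stage is testable without
proprietary device data. See `vignette source in vignettes/hrv-validation.Rmd`
for the methods account.

## Worked example

```r
library(wristhrv)

# a 10-subject cohort of paired 15-minute recordings with mild wrist
# degradation (1 bpm noise, 10% clustered dropouts, 2% ectopic rate)
cohort <- make_cohort(n_subjects = 10, degradation = "mild", master_seed = 42)

# which gap-filling method is most accurate on a reference-grade series?
bench <- benchmark_imputation(cohort$reference$S01, fraction = 0.1, seed = 7)
glance(bench)
#> # A tibble: 1 × 6
#>   best_method best_rmse n_methods n_failed missing_fraction  seed
#>   <chr>           <dbl>     <int>    <int>            <dbl> <dbl>
#> 1 spline3          1.69        11        0              0.1     7

# full pipeline: impute (PCHIP), map wrist -> reference, reconstruct IBI,
# Kamath-correct, summarise, validate
res <- run_pipeline(pipeline_config(degradation = "mild",
                                    mapping_model = "linear_regression",
                                    seed = 42))
tidy(res$comparison)
#> # A tibble: 3 × 8
#>   metric     n    df t_value p_value critical_t_95 critical_t_99 decision
#>   <chr>  <int> <int>   <dbl>   <dbl>         <dbl>         <dbl> <chr>
#> 1 sdnn      10     9   1.86  0.0951           1.83          2.82 no_difference
#> 2 rmssd     10     9   4.22  0.00223          1.83          2.82 difference
#> 3 pnn50     10     9   0.175 0.865            1.83          2.82 no_difference
```

Reading the table: for each index the per-subject pipeline values are
paired with the ground-truth reference values; `t_value`/`p_value` are the
paired Student t-test (two-tailed), and `decision` is taken at α = 0.05.
Here SDNN and pNN50 show no detectable systematic difference after the
correction chain, while RMSSD — the index most sensitive to
sample-to-sample jitter — is still inflated by the residual measurement
noise, and the test says so. With `degradation = "none"` the pipeline
reproduces the ground truth exactly and all three decisions are
`no_difference`.

Each fitted object has `tidy()` / `glance()` methods and an `autoplot()`
(imputation ranking, model ranking, paired boxplots). A thin command-line
front end over the same functions is installed at
`inst/cli/hrvtool.R` with subcommands `simulate`, `impute-bench`,
`train-map`, `hrv`, `validate` and `run`.

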