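# scanopt

**Choosing and validating scan-sampling intervals for group behavioral
observation.**

Ethologists watching a pen of animals rarely record behavior continuously;
they *scan sample*: every Δ seconds they count, per behavior, how many
visible animals are engaged in it.  The occurrence of a behavior is the
mean over scans of the percentage of visible animals performing it.  The
choice of Δ trades observer effort against fidelity — long intervals are
cheap but systematically distort rare behaviors (aggression, escape,
allo-grooming) whose bouts last seconds.

scanopt implements a multistep methodology for making that trade-off
explicit, together with a renewal-process flock simulator that supplies
ground-truth continuous timelines so every stage can be tested:

1. **Reference selection** — candidate intervals vs continuous recording on
   matched (session, behavior) occurrence pairs: R² of the regression of
   continuous on candidate values, MAE and RMSE; the majority winner of the
   three criteria becomes the reference interval.
2. **Reliability** — two-way intraclass correlation coefficients
   (Shrout–Fleiss, consistency or absolute agreement, single or average
   measure) with exact F-based 95% CIs; ICC(C,1) = (MS_R − MS_E)/(MS_R +
   (k−1)MS_E), labelled poor/fair/good/excellent at 0.40/0.60/0.75.
3. **Accuracy** — behaviors binned by occurrence (low ≤ 0.49%, medium
   ≤ 3.50%, high > 3.50% of visible animals per scan); signed error scores
   (test − reference) with t-based category CIs; Bland–Altman bias and
   limits of agreement (bias ± 1.96 SD of the differences) in raw
   percentage points and in percent of the reference value.
4. **Validity** — per sampling method, a Tweedie GLM (variance V(μ)=μ^p,
   1<p<2, log link) estimates a group effect on each behavior; the
   log-scale estimates of two methods are compared with
   z = (β̂_a − β̂_b)/√(SE_a² + SE_b²).

The simulator draws, per animal, i.i.d. behavior segments with probability
w_b ∝ π_b/m_b and exponential durations of mean m_b, so the long-run time
budget equals the target occupancy π_b exactly in expectation
(renewal–reward); visibility is an independent on/off renewal process.
Multi-group studies apply multiplicative occupancy effects, renormalized —
the same mean-ratio scale the log-link models estimate.

## Worked example

Simulate a two-genotype study (5 × 2-h sessions per group, 50-animal pens)
in which group B shows twice as much "Attacking", then run the whole
workflow:

```r
library(scanopt)

base   <- broiler_preset(n_animals = 50)        # pasture-broiler ethogram
design <- sim_study_design(base,
                           effects = list(A = c(), B = c(Attacking = 2)),
                           sessions_per_group = 5, seed = 20)
timelines <- simulate_study(design)

cfg    <- study_config(validity_behaviors = c("Walking", "Dust bathing",
                                              "Attacking"), seed = 20)
report <- run_pipeline(timelines, cfg, broiler_ethogram())
report$reference_selection$metrics
#> # A tibble: 3 × 6
#>   method interval_s    r2   mae  rmse     n
#>   <chr>       <dbl> <dbl> <dbl> <dbl> <int>
#> 1 10min         600 0.992 0.465 0.727   200
#> 2 15min         900 0.986 0.565 0.923   200
#> 3 30min        1800 0.970 0.879 1.37    200
```

The 10-min interval tracks the continuous record best on all three
criteria (higher R², lower MAE/RMSE) and is chosen as the reference.
Relative (percent-mode) Bland–Altman differences against the 30-min
interval show the practical cost of sparse scanning:

```r
report$accuracy$bland_altman[["10min_30min_percent"]]
#> <bland_altman> 10min vs 30min (percent): bias -1.45, SD 66.06,
#>   LoA [-130.9, 128], n=164 (36 zero-reference pairs dropped)
```

Relative errors of ±130% mean a rare behavior's occurrence can easily be
halved or doubled by 30-min scanning, while raw-mode limits stay within a
few percentage points (the funnel: relative error shrinks as occurrence
grows).  The validity stage shows what that does to conclusions — the
doubled Attacking effect is significant under 10-min scanning:

```r
report$validity$fits[["Attacking|10min"]]
#> <tweedie_glm> power=1.50 dispersion=0.187 n=10
#>          term estimate    se    or ci_low ci_high      z p_value
#> 1 (Intercept)  -1.0876 0.410 0.337  0.151   0.753 -2.653 0.00798
#> 2      groupB   0.7069 0.310 2.028  1.104   3.725  2.278 0.02275
#> 3         day   0.0869 0.108 1.091  0.882   1.348  0.804 0.42165
```

Here `or` (the conventional label; formally a ratio of expected
occurrences) recovers the simulated factor of 2 with CI 1.10–3.73.  Across
many replicate studies the 10-min interval detects this rare-behavior
effect far more often than the 30-min interval, while both agree on
high-occurrence behaviors — the quantitative version of "long intervals
are fine for broad characterization, rare behaviors need short intervals".

`export_report(report, "report/")` writes the JSON summary plus CSV tables
(reference selection, per-behavior ICCs, method comparison with compact
letters, error summaries, Bland–Altman point clouds, GLM tables, effect
comparisons).  A thin command-line front end is installed at
`inst/cli/scanopt.R` (subcommands `simulate`, `sample`, `run`).

## Package layout

| Area | Functions |
|---|---|
| Ethogram & I/O | `ethogram()`, `load_ethogram()`, `broiler_ethogram()`, `read_timeline()`, `write_timeline()`, `read_scan_table()`, `write_scan_table()` |
| Simulation | `sim_config()`, `broiler_preset()`, `simulate_flock()`, `sim_study_design()`, `simulate_study()` |
| Sampling | `sampling_scheme()`, `scan_times()`, `scan_sample()`, `occurrence_from_scans()`, `occurrence_continuous()` |
| Reliability | `two_way_anova()`, `icc()`, `interpret_icc()` |
| Accuracy | `reference_metrics()`, `select_reference()`, `bin_behaviors()`, `error_scores()`, `summarize_errors()`, `compare_error_distributions()`, `bland_altman()`, `loa_limits()` |
| Validity | `friedman_test()`, `pairwise_posthoc()`, `fit_tweedie_glm()`, `compare_effect_sizes()`, `compare_glm_terms()` |
| Pipeline | `study_config()`, `run_pipeline()`, `export_report()` |

See `vignettes/scan-sampling-methodology.Rmd` for the model details,
assumptions, numerical choices and limitations.
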