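# rarfosr

Analysis of 24-hour rest/activity rhythms (RARs) from wrist actigraphy in
two-group cohort studies, centred on **function-on-scalar regression
(FOSR)** — the analysis used to ask whether two groups of subjects (for
example amyloid-positive vs amyloid-negative older adults) differ in *when*
during the day their activity differs, rather than only in scalar rhythm
summaries.

## What it does

Starting from epoch-level activity counts (30-second epochs, several days
per subject), the package:

1. **Preprocesses** counts to `log(AC + 1)`, bins them into 48 half-hour
   (or 24 hourly) clock-time intervals per day, applies a valid-day rule
   (a subject needs ≥ 3 valid days), and collapses days into each
   subject's *mean* 24-hour profile and *across-day SD* profile.
2. Computes **standard rhythm metrics** per subject:
   - cosinor: MESOR, amplitude, acrophase, from OLS on
     `{1, cos(2πt/24), sin(2πt/24)}`;
   - nonparametric: interdaily stability (IS), intradaily variability
     (IV), relative amplitude (RA) with M10/L5 windows;
   - sleep parameters (TST, WASO, SE, SOL, average wake bout) from a
     weighted-moving-window sleep/wake scorer and scored rest intervals.
3. Fits the **FOSR model**

   `RARᵢ(t) = β₀(t) + ageᵢ·β₁(t) + sexᵢ·β₂(t) + educationᵢ·β₃(t) + groupᵢ·β₄(t)`

   with each coefficient function expanded in 8 spline basis functions and
   estimated by penalized generalized least squares (GCV-chosen smoothing,
   inverse-variance bin weights, cluster-robust covariance). Inference on
   `β₄(t)` comes three ways: pointwise confidence bands, simultaneous
   (max-statistic) bands with joint coverage over the day, and a global
   permutation F-test. Maximal runs of bins whose band excludes zero are
   reported as clock-time windows (wrapping midnight).
4. Provides a **synthetic cohort generator** with closed-form ground truth
   (two groups, circadian mean structure on the log scale, time-localized
   group effects on mean and on across-day variability), so every stage
   can be validated against known truth.

## Worked example

```r
library(rarfosr)

cfg <- sim_config(rng_seed = 7)        # 26 pos vs 33 neg, up to 6 days
cohort <- generate_cohort(cfg)
res <- run_pipeline(cohort = cohort, out_dir = "run1",
                    n_sim = 5000, n_perm = 499, seed = 7)

print(subset(res$comparisons, outcome %in% c("amplitude", "mesor", "IS")),
      digits = 3)
#>     outcome mean_pos  sd_pos mean_neg  sd_neg        p B_adjusted SE_adjusted
#> 6     mesor    3.317 0.16003    3.134 0.16863 8.46e-05   0.171593    0.044420
#> 7 amplitude    2.395 0.02330    2.259 0.01696 2.47e-33   0.134823    0.005355
#> 9        IS    0.991 0.00226    0.991 0.00215 2.46e-01   0.000918    0.000586
#>   p_adjusted
#> 6   3.02e-04
#> 7   1.63e-31
#> 9   1.23e-01

res$fosr$mean_30min$windows_simultaneous
#>   start_hours end_hours sign       label
#> 1         0.5       3.0   -1 00:30-03:00
#> 2         3.5       9.0    1 03:30-09:00
#> 3        11.0      18.5    1 11:00-18:30

res$fosr$mean_30min$f_test[c("F", "p")]
#> $F
#> [1] 185.0398
#>
#> $p
#> [1] 0.002
```

The three windows are where the simultaneous band for the group
coefficient function `β₄(t)` excludes zero: the positive group is *less*
active in the small hours (00:30–03:00) and *more* active in the morning
and afternoon — recovering the three effect bumps this cohort was
simulated with (centres 01:15, 06:30, 15:00, heights 0.5 log units; the
windows are wider than the bumps because neighbouring bins borrow
strength). The scalar table shows the corresponding group comparison of
cosinor and nonparametric metrics with the covariate-adjusted group
coefficient `B` (SE) and p-value; note IS barely moves even though the
time-localized differences are large — exactly the contrast between
scalar summaries and functional analysis the package exists to study.

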