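---
title: "Rest/activity rhythm analysis with function-on-scalar regression"
author: "rarfosr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest/activity rhythm analysis with function-on-scalar regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarfosr)
```

# The scientific problem

Wrist actigraphy records movement ("activity counts", AC) in short epochs
over several days, giving an objective picture of a person's 24-hour
rest/activity rhythm (RAR). Scalar rhythm summaries — cosinor MESOR,
amplitude and acrophase; nonparametric IS, IV and RA — compress the whole
day into single numbers, and two groups of subjects can have identical
scalar summaries while differing sharply in *particular clock-time
windows* (more restless at 3 am, more active mid-afternoon). This package
implements the full analysis chain for that question in two-group cohort
designs: preprocessing to functional daily profiles, the standard scalar
metrics, and a function-on-scalar regression (FOSR) that estimates a
*coefficient function* for group status over the 24-hour day, with
pointwise bands, simultaneous bands, and a global permutation F-test.

# Preprocessing model

Counts are transformed as `log(AC + 1)` — the **natural** logarithm
throughout — to symmetrize their heavily right-skewed distribution. Days
are anchored midnight-to-midnight in local clock time and cut into
`1440 / bin_minutes` half-open bins `[start, end)`; the default 30-minute
resolution gives 48 bins. Each cell of the resulting days × bins matrix is
the mean log count of the wearable (non-off-wrist) epochs in that bin;
cells with no wearable epochs are missing, and missing cells are
*excluded* from downstream means and SDs rather than zero-filled, since
zero-filling would bias log activity downward.

A day is *valid* when at most `max_missing_fraction` (default 0.5) of its
bins are missing — a documented stand-in, since validity rules beyond
"at least three valid days per subject" are not standardized. Subjects
with fewer than `min_valid_days = 3` valid days are flagged excluded from
rhythm analyses (never dropped silently; exclusion is a flag). The
subject's functional outcomes are then the per-bin **mean** over valid
days and the per-bin **sample SD** (denominator n − 1) over valid days:
the mean profile describes the typical day, the SD profile the day-to-day
instability of behaviour at each clock time. A 60-minute rebinning of the
same epochs feeds the sensitivity analysis through identical code paths.

# Scalar metrics

**Cosinor.** OLS of the pooled valid-day bin values on
`{1, cos(2πt/24), sin(2πt/24)}` with `t` the bin-midpoint clock hour.
MESOR is the intercept; *amplitude is the cosine coefficient* — half the
peak-to-trough excursion — which is the standard convention; because part
of the literature glosses "amplitude" as the full peak-to-trough
difference, the fit also reports `peak_to_trough = 2 × amplitude` so
either convention can be read off. The acrophase is
`(24/2π)·atan2(β_sin, β_cos) mod 24`, the clock time at which the fitted
cosine peaks; when the amplitude is numerically zero the acrophase is
reported as missing, never as an arbitrary angle.

**Nonparametric.** IS, IV and RA are computed on the same log-binned data
as the rest of the pipeline (a raw-count mode would be inconsistent with
the preprocessing; the log scale is the package default and the tested
configuration). IS is the ratio of variance explained by the mean daily
pattern to total variance, 1 for a perfectly repeated day. IV is the
normalized mean squared successive difference; successive differences are
taken **within days** by default (no artificial midnight jump; a
concatenated variant is available), and never across missing cells. Its
range is worth remembering: ≈ 2 for white noise, exactly 4 for a strictly
alternating sequence, and ~0.02 for a half-hour-sampled pure 24-hour
cosine. RA = (M10 − L5)/(M10 + L5) with M10 and L5 the best 10-hour and
worst 5-hour **circularly wrapped** window means (L5 typically straddles
midnight); ties break to the earliest onset. IS and IV are invariant to
adding a constant; RA is not — a consequence of its ratio form users
should keep in mind when comparing across transforms.

**Sleep.** The proprietary scorers shipped with actigraphy software are
not public; the package implements a configurable weighted-moving-window
threshold scorer as a documented stand-in (no equivalence claim): an
epoch is wake when the weighted activity sum over ±2 minutes (central
weight largest) exceeds a threshold, default 40. Sleep onset is the first
run of ≥ 10 consecutive sleep minutes after lights-out (the onset run
length is not standardized either; it is configurable). From scored
epochs and an in-bed interval the five standard parameters follow: SOL,
TST, WASO, SE, and mean wake-bout length, with the accounting identity
TST + WASO = interval − SOL. Nights are averaged within subject before
any group comparison.

# The FOSR model

For subject $i$ with profile $Y_i(t)$ on the bin grid,

$$Y_i(t) = \beta_0(t) + \mathrm{age}_i\,\beta_1(t) + \mathrm{sex}_i\,\beta_2(t)
  + \mathrm{education}_i\,\beta_3(t) + \mathrm{group}_i\,\beta_4(t) + e_i(t).$$

Age and education are mean-centred (so $\beta_0$ is the reference-group
mean curve); sex is coded 1 = female, group 1 = positive. Each
$\beta_j(t) = \sum_k \theta_k(t) a_{jk}$ is expanded in a common basis of
**8 cubic B-splines** on [0, 24] with a second-order difference penalty on
the coefficients (linear functions unpenalized). The default basis is
non-periodic, mirroring the common practice of ignoring the circularity
of the day; a periodic (midnight-wrapped) basis and penalty are available
for analyses that want $\beta_j(0) = \beta_j(24)$. The default design
deliberately keeps the number of bins (48) below the number of subjects
(59 in the motivating design) for numerical stability; `fosr_rar()` warns
when that is violated.

## Estimation

Step 1 fits penalized OLS; the normal equations have Kronecker structure
$(X'X \otimes \Theta'W\Theta + \Lambda \otimes P)\,\alpha = \mathrm{vec}(\Theta'W Y'X)$,
a 40 × 40 solve, so hundreds of fits (GCV grids, permutations,
simulations) cost little. A single smoothing parameter shared across
coefficient functions is chosen by GCV over a 33-point log-spaced grid.
Step 2 estimates the residual covariance over the grid from the Step-1
residual functions and shrinks it toward its diagonal by `cov_shrink`.
Step 3 re-estimates by penalized GLS with the inverse shrunk covariance
as working weight, re-running GCV in the weighted metric.

## Why the default weight is diagonal, and why the covariance is a sandwich

With 48 bins and ~54 residual degrees of freedom, the empirical 48 × 48
residual covariance is at the edge of estimability: its small eigenvalues
are severely underestimated, so its inverse overweights noise directions.
In null simulations at exactly these dimensions, weighting by the
inverse of a lightly shrunk covariance (shrinkage 0.1) produced pointwise
bands whose non-coverage was 0.17–0.22 at nominal 0.05 — the fit chases
the noisy weight and every plug-in variance formula inherits the
distortion. The package therefore defaults to `cov_shrink = 1`:
inverse-variance weights per bin with working independence across bins,
the GEE-style compromise that keeps the heteroscedasticity gain and none
of the inverse-covariance pathology. Standard errors never trust the
working weight at all: the covariance of the basis coefficients is a
by-subject cluster-robust sandwich over residual functions (with an
n/(n − q) factor), valid under any working weight. Under the same null
simulations this combination gives pointwise non-coverage ≈ 0.06–0.07 and
familywise error ≈ 0.07–0.08 at α = 0.05. Full covariance weighting
remains available (`cov_shrink < 1`) for designs where subjects far
outnumber bins.

## Inference

*Pointwise band:* $\hat\beta_j(t) \pm z_{1-\alpha/2}\,SE_j(t)$.
*Simultaneous band:* the parametric max-statistic construction — draw
Gaussian vectors from the estimated covariance of $\hat\beta_j(\cdot)$ on
the grid, take the $1-\alpha$ quantile $q^\*$ of
$\max_t |Z(t)|/SE(t)$, and report $\hat\beta_j(t) \pm q^\* SE_j(t)$;
$q^\* \ge z_{1-\alpha/2}$ always, so the simultaneous band contains the
pointwise band and is the conservative choice for claiming windows. Both
are deterministic given a seed. *Global F-test:* full-vs-reduced residual
sums of squares integrated over the grid, with effective degrees of
freedom from the penalized fits; because asymptotic reference
distributions for functional F-tests are not well settled at small n, the
p-value comes from permuting the tested covariate's column across
subjects (smoothing parameters and the working weight held at their
observed values for exchangeability and speed). Windows are maximal runs
of bins whose band excludes zero, merged across the midnight wrap and
reported with their effect sign as clock-time intervals covering full bin
extents.

# The synthetic cohort generator

There is no public epoch-level dataset for this design, so the generator
*is* the study-conditions definition, not a convenience: 26 vs 33
subjects, 30-second epochs, up to six midnight-aligned days (a range
setting draws 2–6 days with weights giving mean ≈ 5.7, SD ≈ 0.8 days),
and a latent Gaussian log-activity process

$$x = \mu(t - J_{id}) + b_i + \delta(t)\,\mathbf 1[\mathrm{pos}] + \varepsilon,
\qquad \mathrm{count} = \max(0, \mathrm{round}(e^{x} - 1)),$$

with $\mu(t)$ a cosinor (MESOR 3.16, amplitude 2.30 log counts, acrophase
14.72 h — typical older-adult values) plus a second harmonic; subject
intercepts $b_i$ (SD 0.2); day-level phase jitter $J_{id}$ (SD 0.25 h)
that shifts the curve, not the timestamps; and epoch noise (SD 1.0 log
counts). Group effects are three Gaussian bumps in $\delta(t)$ — negative
at 01:15, positive at 06:30 and 15:00, each 0.5 log units, matching the
magnitude and placement of reported overnight/morning/afternoon group
differences — and three SD windows multiplying the positive group's epoch
noise (×1.5 in 21:30–01:00 and 04:30–08:30, ×0.6 in 02:30–03:30) so the
SD-profile analysis also has ground truth. Covariates mimic the
motivating cohort (age ≈ 71 ± 4.6, 59% female, education ≈ 16.6 ± 2.4
years). Nightly rest intervals (~23:00–07:00 ± 30 min) are emitted so the
sleep module runs end-to-end.

Two deliberate modelling notes. First, the latent-Gaussian count model is
a stand-in for the unknown device noise process: it matches the analysis
scale (log counts) and keeps ground truth closed-form, but it does not
claim to reproduce raw accelerometer count distributions, zero-inflation
from motionless wear, or off-wrist artefacts — so passing tests validate
the *pipeline*, not device physics. Second, integer rounding of emitted
counts biases observed mean log counts upward by up to ~0.3 log units at
low-activity (night) bins. `cohort_truth(observed = TRUE)` therefore
supplies the exact observed-scale expectation
$E[\log(\mathrm{count}+1)]$ (a truncated Gaussian–discretization sum,
marginal over subject intercept and noise); observed-scale profile checks
must use these columns, while the latent curves remain the right oracle
for effect *shape* (the observed-scale extrema of the group contrast fall
within one bin of the latent bump centres). Phase jitter attenuates
realized amplitudes by a factor $e^{-\sigma_J^2\omega^2/2} \approx 0.998$
— negligible at the default jitter and ignored in the truth curves.

# Numerical choices and degenerate inputs

- Acrophase and all window onsets are circular quantities; distances and
  window membership use clock arithmetic mod 24 with half-open intervals.
- Zero-variance inputs make IS and IV undefined (missing with a warning),
  never infinite; RA with M10 = L5 = 0 is undefined.
- The sample SD needs two contributing days per bin; short bins give a
  missing SD with a warning.
- Collinear designs are rejected with an explicit error (rank check)
  rather than silently dropped; the permutation F-test refuses a
  duplicated covariate for the same reason.
- GCV ties resolve to the smallest grid value reached first; a zero
  smoothing parameter is allowed and used by the bin-wise OLS oracle
  identity (saturated basis + zero penalty + unit weight ≡ per-bin OLS,
  verified to 1e−8).
- All Monte-Carlo machinery (simultaneous bands, permutation tests, the
  generator) is seeded explicitly; reruns with the same config and seed
  are byte-identical, which the test suite asserts end-to-end.

# Problem sizes used in validation

The shipped validation uses sizes chosen to exercise the study's own
dimensions while keeping the suite quick: null-band calibration uses 500
replicates of 59 subjects × 48 bins with 1000 draws per simultaneous
band; effect recovery uses 100 regenerated default cohorts (26 vs 33
subjects × 6 days × 2880 epochs/day); the acceptance script reduces these
to 300 and 30 replicates and runs five permutation F-tests at 199
permutations. Localization is scored per bump: within ±3 hours of each
injected centre (the three neighbourhoods are disjoint), the maximizer of
the sign-aligned group coefficient must fall within 1 hour of the centre;
SD-window recovery requires the window-mean of the SD-profile group
coefficient to carry the injected sign. Larger runs only tighten the
Monte-Carlo error.

# Known limitations

- The non-periodic default basis loses power near midnight by
  construction; the periodic mode is the remedy when circularity matters.
- The global F-test aggregates over the whole day and can miss effects
  confined to a few hours — the very situation the bands are for; treat a
  non-significant F alongside significant simultaneous windows as the
  expected behaviour of a conservative whole-day test, not a
  contradiction.
- Scalar group comparisons are reported without multiplicity adjustment
  across outcomes, matching common cohort-table practice; interpret
  accordingly.
- The sleep scorer is a stand-in; absolute sleep-parameter values are not
  comparable to proprietary-software output, though within-study group
  contrasts are.
- Simulated profiles are smoother than real actigraphy (IS ≈ 0.99 on
  defaults vs ≈ 0.75 in real cohorts), because the generator's
  day-to-day variation is limited to intercept, phase jitter and epoch
  noise. Recovery rates measured on it are therefore optimistic relative
  to field data.
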