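---
title: "Models and methods behind psymon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psymon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psymon)
```

`psymon` analyses longitudinal cohorts in which patients with
schizophrenia wear activity/sleep sensors, answer short smartphone symptom
surveys, and attend periodic clinical assessments. This vignette documents
the statistical models, the synthetic-data generator that stands in for
undeposited patient data, the tunable parameters, and the numerical and
design choices a maintainer should know about.

## The generative model of the synthetic cohort

Every generated channel (each device metric per period, each survey item,
each clinical scale) is driven by a latent Gaussian decomposition

$$u_{ict} = \frac{b_{ic} + e_{ict}}{\sqrt{\sigma_b^2 + \sigma_e^2}},
\qquad b_{i\cdot} \sim N(0, \sigma_b^2 R),
\qquad e_{i\cdot t} \sim N(0, \sigma_e^2 R),$$

where $i$ indexes patients, $c$ channels and $t$ days. Two properties
follow by construction and are what the downstream analyses estimate:

* every channel has intraclass correlation
  $\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$ — the share of
  variance due to stable between-patient differences; and
* the correlation between any two channels is the corresponding entry of
  the target matrix $R$ (`cross_corr`).

A deliberate design choice: $R$ is imposed on **both** the trait vector
$b_i$ and the day-level noise $e_{it}$ (via an eigen square-root factor,
so positive-semidefinite targets are accepted). Applying it to the noise
alone would leave channels with a zero entry still correlated through the
shared patient trait, which would break the null calibration of the
association test and make `cross_corr` hard to interpret. With the
both-components construction, the within-patient and between-patient
regression slopes both equal the planted correlation, so the mixed-model
estimand is exactly the `cross_corr` entry, and zero means independent.

Latent values map to natural scales per channel type:

* **linear** channels are affine transforms `mu + disp * u` with the
  per-metric location/dispersion of `metric_registry()` (e.g. nightly
  sleep duration 480 ± 45 min, sleep efficiency 85 ± 5%). Values chosen
  to be plausible for a stable outpatient cohort; they are stand-ins, the
  source studies do not publish device-metric distributions.
* **clock times** (sleep/rest start) are generated on the 1440-minute
  circle, rounded to whole minutes (device resolution), serialized as
  `"HH:MM"`. Default sleep start 23:00 ± 45 min.
* **counts** (steps, activity counts) are `round(mu * exp(disp * u))`,
  floored at zero — positivity and right skew without a second
  distributional family.
* **ordinal survey items** bin the latent value at fixed cut points
  (0.25, 0.9, 1.5, 2.05 on the standard-normal scale), giving mostly-low
  0–4 scores; summary scores are item sums.
* **clinical scales**: PANSS items are 1–7 ordinals driven by the scale
  latent with loading 0.7 plus item noise, binned so the stable-cohort
  total averages ≈ 36 (items mostly 1–2); the PANSS total is always the
  item sum, as is the PSQI global over its 0–3 components. BPRS/CDS/YMRS
  are rounded affine transforms; CGI-S is a clipped 1–7 rounding.

Visits follow the study cadences (PANSS/BPRS every 14 days, the others
every 28), i.e. 8 and 4 visits over the default 120-day observation
period. Device non-wear drops whole device-days with probability
`1 - wear_prob` (default 0.94) and survey slots with
`1 - survey_response_prob` (default 0.85); both were chosen to land in the
high-80s/low-90s coverage range typical of engaged cohorts. The default
ICC of 0.6 reflects the good-to-excellent within-patient stability such
stable cohorts show. The truth record carries the generative ICC, the
correlation target and the relapse metadata, and labels all distributional
choices as synthetic stand-ins.

**What the generator does not emulate**: physiological waveforms or
epoch-level (30-s/15-min) data — metrics are simulated directly at the
daily/nightly summary level; medication-adherence dynamics; seasonal or
weekday structure; heavy-tailed or device-error artifacts. Passing tests
therefore demonstrate statistical correctness of the pipeline under its
own assumptions, not robustness to every artifact of real actigraphy.

### The injected pre-relapse signature

`inject_relapse()` modifies only data at or after `onset_day`: the sleep
start time drifts linearly on the circle by a configured minutes/week
(the canonical scenario: −15 min/week, i.e. a 20:00 baseline trending to
an ~18:30 two-week average after six weeks); daily steps are spread about
the patient's pre-onset mean so their variance is multiplied by a factor;
named survey items are spiked (+2, capped at 4) with summaries recomputed;
and at the first post-onset PANSS visit, item P1 is raised to the
configured target (≥ 5) with the total recomputed, so the relapse rule
fires. Pre-onset samples are bit-identical with and without the injection,
which the tests assert.

## Ingestion, compliance, relapse rule

Metrics travel as long CSV (`patient_id, metric, period, date, value`)
validated against the registry vocabulary; clock times are parsed from
`"HH:MM"` and values written back at full double precision, so the
round trip is lossless. Dates are calendar days with no time-zone notion;
all windows are half-open `(start, end]`. Nightly metrics are dated by the
morning their sleep period ends, aligning each night with the assessment
window it informs.

The relapse flag is exactly the study rule: any positive item ≥ 5, or at
least two negative items ≥ 5, or `total_increased & med_change`. The
"increased total" is a caller-supplied boolean because no universal
increase threshold exists; missing items are an error rather than
imputed. The compliance definition ("all devices ≥ 50% of 24 h, or 2 of
4 streams") is ambiguous about whether the 2-of-4 clause is daily or
whole-period; `compute_compliance()` applies both clauses per patient-day
and aggregates over the requested window, isolating that reading in one
function.

## Window features

For each visit, each metric is summarised over `(d − 14, d]` — the two
weeks immediately preceding the assessment; at exactly biweekly spacing
consecutive windows partition the calendar. Linear metrics use the
arithmetic mean and `n − 1` SD; clock metrics use the circular mean and
circular SD $\sqrt{-2\ln \bar R}$ (in minutes, via the mean resultant
length $\bar R$). A feature is emitted only when at least half the
scheduled days in the window have data (`min_coverage = 0.5`); remaining
missing entries are imputed with *training-fold* means inside
cross-validation, never globally, to avoid leakage. Windows are anchored
to visit dates (not calendar fortnights), since assessments are what the
features must explain.

## Mixed-effect associations and ICC

Each pairwise association fits `y ~ x + (1 | patient)` by REML after
scaling both variables to unit pooled variance, so the fixed slope is a
standardized, correlation-like quantity; the Wald z test of that slope is
the association test. Estimation choices the sources leave open and the
package fixes: REML with a Wald normal reference; pooled (grand) variance
scaling; negative variance components truncated at zero before the ICC
ratio; any optimizer failure (or unscalable constant input) mapped to a
non-converged `"nc"` row instead of an exception, mirroring how such
tables are reported. With one observation per patient the GLS covariance
is proportional to the identity, so the slope collapses to the OLS
(≈ Pearson) value — a tested limit. The ICC is the variance-ratio
(consistency, single-measure) form from the random-intercept model;
a scale constant within every patient returns exactly 1 without invoking
the optimizer. Significance is two-sided at 5% with no multiplicity
adjustment — the analysis is exploratory by design.

## Elastic-net prediction

Clinical scales are predicted from windowed feature sets under repeated
cross-validation **at the patient level**: folds partition patients (10
folds, 30 repeats by default), so all visits of a held-out patient are
unseen during training. Within each training split, the mixing parameter
(grid 0.1–1.0 by 0.1) and penalty strength (50 log-spaced values per
mixing value) are chosen by an inner patient-level CV minimising pooled
RMSE; imputation and standardization are fit on training data only and
reused at test time (the test suite audits this by corrupting test folds
and asserting unchanged preprocessing). Per repeat, held-out predictions
are pooled into one RMSE and one out-of-sample
$R^2 = (SST - SSE)/SST$ (about the held-out mean; negative when
predictions are worse than that mean); the reported SDs are across
repeats, which the output metadata states explicitly.

## The streaming monitor

Each patient-metric stream is monitored like a process-control chart:

* **Baseline norm**: mean and variance over the first `baseline_days`
  (default 30 — the first month), requiring `min_baseline_days = 21` days
  with data; frozen once fitted. Clock metrics take the circular mean,
  with values unwrapped into ±720 minutes around it so the t/F/slope
  machinery is valid locally; a drift crossing midnight is detected
  identically to one at midday (tested shift invariance).
* **Point outliers**: two-sided alerts beyond `outlier_k = 2.5` baseline
  SDs. Against a norm at the population values the alert rate is exactly
  $2(1-\Phi(k))$; with a norm *estimated* from $n$ baseline days the
  realized rate is inflated to roughly
  $2(1 - F_{t,n-1}(k/\sqrt{1+1/n}))$ (≈ 0.020 instead of 0.0124 at
  $k = 2.5$, $n = 30$), which the tests document.
* **Mean shift**: per windowed day, a Welch two-sample t between the
  trailing 14-day window and the baseline sample (summary-statistic
  form, Welch–Satterthwaite df). **Variance shift**: the window/baseline
  variance ratio on $F(n_w - 1, n_b - 1)$, two-sided; a zero-variance
  window yields ratio 0 and is flagged as a degenerate downward shift.
  **Slope**: the trailing 14-day least-squares slope's t statistic.
  All three tests treat samples as independent; under day-to-day
  autocorrelation the flag rates are anti-conservative, which is
  accepted for an alerting stream (no multiplicity correction across
  days or metrics — alert density, not inference, is the calibrated
  quantity). A ×4 variance inflation is detected with ≥ 95% probability
  once the moving window has filled with post-change data (within about
  two window lengths of the change).
* Rolling statistics are computed with cumulative sums on a daily grid
  after centering (cancellation residue below `1e-10 * (1 + mean^2)` is
  snapped to an exact zero so constant windows report variance 0); the
  tests assert equality with naive recomputation. No statistic for day
  $d$ uses any sample after $d$.

## Numerical and engineering choices

* All randomness flows through explicit seeds; per-stage seeds are
  derived from the master seed and the stage name, so toggling one
  pipeline stage never changes another's draws. Identical config + seed
  reproduces cohorts and results bit-for-bit.
* Circular means snap values within 1e-9 minutes of the 1440 wrap point
  to 0; `glmnet` is padded with an inert zero column for single-feature
  fits; exact linear dependence between paired variables (a variable
  against itself) bypasses the degenerate mixed fit and returns the
  definitional ±1.
* Test problem sizes were chosen to make Monte-Carlo checks sharp but
  quick: ICC recovery uses 200 replicates of 40 patients × 8 visits per
  generative value (recovering truth within 0.05); association
  calibration uses 200 replicates; shift-detection power 500 replicates;
  outlier calibration 100,000 monitored days; the full suite runs in a
  few minutes on one core.

## Known limitations

The generator's Gaussian latent structure cannot express, e.g.,
zero-inflated non-wear bursts, weekday effects, or survey response styles;
ICC estimates on ordinal instruments (PANSS total, PSQI) are mildly
attenuated relative to the latent generative value by binning and
truncation. The monitor's tests assume day-level independence, and the
association analysis fits random intercepts only (no random slopes or
covariate adjustment). The elastic-net stage reports predictive skill
only; it makes no inferential claims about feature importance.
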