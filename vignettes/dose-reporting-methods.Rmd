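---
title: "Methods: norepinephrine dose reporting and mortality prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: norepinephrine dose reporting and mortality prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedose)
```

## The problem

Norepinephrine doses are communicated either as the active base molecule or
as a salt (hydrochloride, bitartrate, tartrate) containing less base per
milligram. A salt-reported dose is the base dose multiplied by a conversion
factor $c_f$: 1.22 (hydrochloride), 1.89 (bitartrate), 2 (tartrate). When
the NE dose is also used as a mortality predictor, the convention silently
rescales the predictor axis, which distorts both the per-unit odds ratio
and the risk read off at familiar cut-offs. This package implements the
full chain needed to quantify that distortion on an ICU cohort and to
verify the analytic identities it rests on.

## The dose–response model

28-day mortality is modelled by univariate logistic regression,

$$\mathrm{logit}\, p_i = \alpha_f + \beta_f\, d_{f,i},$$

where $d_{f,i} = c_f \, d_{\mathrm{base},i}$ is patient $i$'s dose on
reporting scale $f$. Because the stacked per-formulation rows are
deterministic rescalings of one observation per patient, the model is
exactly reparameterization-equivalent across conventions:

- **slope identity:** $\beta_f = \beta_{\mathrm{base}} / c_f$, so the
  per-unit odds ratio is $\mathrm{OR}^{1/c_f}$ and the percent reduction is
  $100(1 - \mathrm{OR}^{1/c_f - 1})$;
- **prediction equivariance:** $\hat p_f(d) = \hat p_{\mathrm{base}}(d / c_f)$.

`fit_dose_response()` offers three parameterizations — independent fits per
formulation (default), a single fixed-effects model with
formulation-by-dose interaction, and the interaction model with a
patient-level random intercept. The first two have identical likelihoods
and must agree to optimizer tolerance; the test suite enforces agreement to
1e-6 and the slope identity to 1e-8 (IRLS is run with `epsilon = 1e-12` so
numerical convergence error stays far below those bounds). The
random-intercept variant is provided for fidelity to mixed-model practice,
but with four deterministic copies of each outcome the variance component
is weakly identified; it is reported in the fit metadata and deliberately
not interpreted. Dose enters linearly on the logit scale only — the
sigmoid shape of the risk curve is the model, no splines — because the
divergence-with-dose phenomenon under study is a property of that sigmoid.

Confidence intervals for predicted mortality use the delta method on the
logit scale: the linear predictor's variance comes from the coefficient
covariance, the interval is formed there and then transformed through the
inverse logit, so it is always inside $[0,1]$ and always contains the point
estimate. A patient-level bootstrap was considered and rejected as the
default: the delta method is standard, deterministic and adequate at the
cohort sizes involved.

`calibrate_logistic_from_anchors()` solves $(\alpha, \beta)$ exactly
through two (dose, mortality) anchor points on the logit scale, or by least
squares for more. It serves two roles: reconstructing a published cut-off
table analytically from its base-molecule column, and calibrating the
synthetic generator's mortality model to published anchor proportions.

## Dose variables from infusion streams

The infusion record is treated as a right-open step function: a rate holds
on $[\mathrm{start}, \mathrm{end})$, and gaps between segments mean the
pump is off (rate 0), which breaks stability intervals.

**Peak dose (24 h).** To keep registry errors and transient pump
manipulations out of the peak, a candidate rate $r$ only counts as the peak
if the rate function stays within $[0.9r, 1.1r]$ over a contiguous interval
of at least 5 minutes containing at least one record at exactly $r$.
Candidates are the distinct observed rates in descending order; the first
that qualifies is the peak, and if none does the patient has no valid peak
and falls under the dose-availability exclusion. Two readings of "within a
10% range" are possible; the band is centred multiplicatively on the
candidate because that reading is symmetric and scale-free. The
implementation is a linear scan over merged in-band runs; the test suite
checks it against an independent brute-force scanner that enumerates every
candidate interval of the step function on randomized streams of up to 10
segments.

**Diagnosis dose.** The rate of the event whose start time is nearest the
shock-diagnosis time, before or after, with ties broken toward the earlier
event.

**Outliers.** Records above a plausibility ceiling (default 5 µg/kg/min
base, configurable in `screen_criteria()`) are removed before any dose
extraction and counted per patient. No published ceiling exists for this
filter, so it is an exposed parameter rather than a constant baked into
code.

**NE equivalents.** Multi-vasopressor regimens are collapsed to a single
NE-equivalent rate by a weighted sum over concurrent step functions, using
the updated equivalence weights of Kotani et al. (2023): epinephrine 1,
phenylephrine 0.1, dopamine 0.01, metaraminol 0.125, vasopressin 2.5 per
U/min, angiotensin II 10. The weights ship as a plain-text config with a
provenance column and are overridable; unit mismatches (e.g. vasopressin
declared in µg/kg/min) are rejected rather than converted.

## Sepsis-3 screening

Septic shock requires suspected infection (a culture/antibiotic pair:
antibiotics within 72 h after a culture, or a culture within 24 h after
antibiotics — the widely used pairing convention, exposed as
configuration), SOFA ≥ 2 at or after the suspicion time, NE use, and a
lactate ≥ 2 mmol/L nearest NE initiation within ±6 h. Exclusions: NE
started more than 12 h before or 72 h after sepsis diagnosis, missing age
or weight, and no NE dose values after outlier removal (which includes
streams whose every rate fails the stability filter).

The criteria are applied in a fixed, documented order — age, infection,
SOFA, NE use, lactate, window, demographics, dose availability — and each
excluded patient is attributed to the first criterion failed, so the
ledger is reproducible and conserves counts exactly:
input $n$ = retained + $\sum$ exclusions. Screening is idempotent:
re-screening the retained patients' tables excludes nobody.

## What the synthetic generator emulates

`generate_cohort()` produces the five input tables with the statistical
structure the analysis assumes:

- **Base peak doses** are log-normal, parameterized by median and quartiles
  via `lognormal_from_quartiles()` (σ = ln(q₃/q₁)/(2·z₀.₇₅)); defaults give
  median 0.24 and quartiles ≈ 0.13/0.44 µg/kg/min. Latent peaks are
  truncated at 4.9 µg/kg/min — doses beyond the registry-error ceiling are
  not clinically plausible true peaks, and the generator injects registry
  errors separately.
- **Diagnosis doses** are the peak times a Beta(2, 2.28) fraction; the
  second shape parameter was calibrated once by simulation so the
  diagnosis-dose median sits at 0.1 µg/kg/min.
- **Mortality** is a Bernoulli draw on
  $\mathrm{logit}^{-1}(\alpha + \beta\, d_{\mathrm{peak}})$; the default
  $(\alpha, \beta) = (-1.281, 2.867)$ solves the logistic through mortality
  anchors of 27% at 0.1 and 83% at 1.0 µg/kg/min. A binary 28-day outcome
  is simulated directly; there is no censoring or time-to-event structure.
- **Infusion streams** start at the diagnosis dose, titrate up to a
  sustained plateau (20–120 min) at exactly the latent peak, and taper.
  Transient spikes (< 5 min, 1.3–1.8× the peak) and outlier records
  (6–12 µg/kg/min, 1 min) are appended after pump-off gaps so they can
  never merge with a stable interval. The generator and the peak extractor
  are therefore mutually consistent by construction, and a test asserts
  exact recovery of the latent peak on spike-free output.
- **Secondary vasopressors** (vasopressin, phenylephrine, epinephrine)
  appear in 57% of patients.
- **Screen failures**: a configurable fraction of patients is constructed
  to violate one randomly chosen criterion each (underage, no culture,
  SOFA 1, no NE, lactate < 2, NE start 13–24 h before diagnosis, missing
  weight, all rates above the outlier ceiling), which lets tests assert
  exact ledger attribution.

All randomness flows from a single master seed; each table is drawn from an
independently derived substream, so adding a table never perturbs the
others and generation is byte-reproducible.

What the generator does **not** emulate: covariates (age, weight, lactate,
SOFA) are drawn independently of dose and of each other, because no joint
distribution is published — they are loosely matched to cohort medians and
marked non-calibrated. There are no multi-stay patients, no overlapping
concurrent NE pumps (the validator rejects overlaps), and no secular
trends. Passing tests therefore demonstrate correctness of the pipeline's
logic and calibration of its marginals, not realism of joint EHR structure.

## Numerical choices

- Conversion factors are stored at printed precision (2, 1.89, 1.22), not
  re-derived from molar masses.
- Stability comparisons use absolute tolerances of 1e-12 on rates and 1e-6
  minutes on segment contiguity; "at exactly $r$" means bitwise within
  1e-12, which is exact for rates originating from the same records.
- Table percentages round half-up (`round_half_up()`), matching clinical
  table typesetting; R's banker's rounding would turn 57.5 into 58 or 56
  depending on parity.
- Degenerate fits (single outcome class, non-convergence, quasi-separation
  flagged by |coef| > 25) raise explicit errors rather than returning
  unstable estimates.

## Problem sizes

The test suite runs the full generator at up to 50 000 patients (latent
structure only takes ~3 s; screening is exercised at 100–1000 patients),
parameter recovery over 200 replicates of 4086 patients, and brute-force
peak-scanner equivalence over 100 randomized streams; the whole suite
completes in about a minute. These sizes were chosen so Monte-Carlo error
is well below the tolerances asserted (e.g. ~1900 patients fall in the
latent-dose window used for the generative-logistic check, giving a
standard error of ~0.011 against a ±0.02 band).

## Known limitations

- The analysis is deliberately univariate: no covariate adjustment,
  severity scores or survival modelling — the object of study is the
  reporting-convention distortion, which covariates would not change.
- The random-intercept variant exists for completeness but adds no
  information on stacked deterministic rows.
- The infection-pairing windows, lactate lookback and outlier ceiling are
  conventions exposed as configuration; different choices change cohort
  membership at the margins.
- Real infusion data contain pathologies the generator does not model
  (documentation backfills, unit-entry errors other than magnitude
  outliers, overlapping pump records); the validator surfaces rather than
  repairs them.
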