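---
title: "Methods: matched open-cohort ITS evaluation of a patient portal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched open-cohort ITS evaluation of a patient portal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalits)
```

## The design

`portalits` implements a quasi-experimental evaluation of a primary-care
patient portal: did registration change how often patients used the
traditional, synchronous services — in-person physician (MD) visits,
nurse practitioner / physician assistant (NP/PA) visits, and calls to the
practice triage nurses (TC)?

Because registration is voluntary, registrants differ from
non-registrants. The design answers with two layers of control:

1. **Propensity-score matching** makes the comparison arm resemble the
   portal arm on observed baseline covariates at the index date.
2. **Interrupted time series (ITS)** contrasts each arm's *own* pre-index
   trend with its post-index level and slope, so a secular drift common
   to both arms cancels out of the portal-minus-control contrasts.

Controls have no registration date, so the design is an *open cohort*:
every never-registered patient enters the matching pool once per calendar
year 2010–2018 for which July 1 of that year has a full year of observed
data on each side, carrying that year's covariate profile. A matched
control therefore contributes one specific person-year, and its July-1
index date must lie within 366 days of the portal patient's registration
date — this anchors both members of a pair to the same calendar
neighbourhood and absorbs period effects.

## The outcome model

For relative year `t` (year 0 = the 12 months up to and including the
index date), arm `A` (1 = portal) and post-period `P = 1{t >= 2}`:

```
E[count | t, A] = b0 + b1 t + b2 P + b3 (t-2) P
                  + A (b4 + b5 t + b6 P + b7 (t-2) P)
```

* `b0, b1`: control intercept and pre-index slope.
* `b2`: control level change *in year 2* relative to the pre-index trend.
* `b3`: control post-index slope change; the `(t-2)` anchoring makes `b2`
  a pure year-2 level contrast rather than an extrapolated `t = 0`
  intercept shift.
* `b4..b7`: the portal-minus-control differences of the same quantities;
  `b6` (portal x period) and `b7` (the three-way interaction) carry the
  headline effects.

Years 0 and 1 are excluded from the fit in both arms: year 0 shows an
attribution spike (care-seeking around the moment the index date is
assigned) and year 1 a transient adoption effect. Excluding them trades
away some real early use for a stabler long-run estimate; the exclusion
set is a configurable argument (`exclude_years`).

**Unit of analysis.** The regression runs on patient person-years, not on
arm-level annual means. For a balanced panel the OLS point estimates are
identical either way; person-years keep the estimates well defined when
patients contribute different numbers of years, and give a natural
clustering unit. Each person-year has weight 1.

**Standard errors.** Patients contribute up to 16 repeated measurements,
so the primary SEs are cluster-robust by patient (CR1 sandwich with the
Stata-style small-sample factor `G/(G-1) * (n-1)/(n-k)`); conventional
OLS SEs are also emitted. The `sandwich` estimator is implemented
in-package (~15 lines) and verified against a longhand per-cluster oracle
in the test suite. Autocorrelation-corrected variants (Prais–Winsten,
ARIMA) and count-model links are out of scope; the mean structure is
linear by design and the Poisson generator keeps OLS unbiased for it.

## Matching

* **Propensity model**: maximum-likelihood logistic regression of
  registration on sex, age at index, rostering status, five
  chronic-condition flags (CAD, CHF, COPD, diabetes, hypertension) at the
  index date, and the 12-month lookback counts (MD, NP/PA, TC, distinct
  medications). Counts enter as raw continuous values by default — the
  baseline table reports them banded, but banding discards information
  the score can use; a banded model can be requested via
  `ps_covariates`. Income and education are never used (recorded for only
  about a third of patients). Control person-years enter as separate
  records. Perfect separation is detected before fitting and reported
  with the offending covariate's name.
* **Caliper**: 0.2 — interpreted, as is standard when a matching paper
  gives a bare caliper multiplier, as 0.2 SDs of the *logit* of the
  pooled propensity scores. A raw-scale caliper is available
  (`caliper_scale = "raw"`). Within a portal patient's caliper-and-gap
  window, each distinct control patient contributes only its
  closest-scoring person-year.
* **Allocation**: iterative unique-first greedy matching without
  replacement. Repeat until stable: (1) match every portal patient with
  exactly one remaining candidate; (2) match every control that is a
  candidate of exactly one portal patient; re-check after every match.
  When neither rule fires, match the globally closest remaining pair.
  Ties break by smaller score distance, then smaller index-date gap, then
  lexicographic patient id, which makes the allocation deterministic and
  invariant to input row order (a property the suite checks by
  permutation). Unmatched portal patients are reported, not errors, and
  excluded downstream.
* **Diagnostics**: standardized differences pre and post matching
  (pooled-variance formulae; defined as 0 when both spreads are zero and
  locations agree), plus pooled propensity-score quintile groups
  (labelled 0–4).

## The synthetic EMR generator

The generator states one world and keeps it fixed:

* Calendar period 2002-01-01 – 2019-12-31; portal launch 2010-01-01.
* ~15,000-patient scale practice (tests use smaller populations where the
  property under test permits); age at launch ~ N(45, 17) truncated to
  5–90 so under-18 trimming is exercised; 54.3% female, 96.6% rostered,
  chronic-condition prevalences 3.4/1.3/2.4/6.2/17.0% (CAD/CHF/COPD/
  DM/HTN) — all taken from the published practice profile.
* 70% of patients span the full period; 30% enter late and/or 15% leave
  early, giving realistic staggered windows.
* Registration follows a logistic model on the same covariates the
  propensity stage uses (intercept −1.75; female +0.44 and rostered +1.50
  — the log odds ratios implied by the published baseline proportions —
  plus small age and diagnosis effects). This yields ≈48% registration
  among eligible adults, matching the published 48.7%, and guarantees the
  matched design is attainable because nothing unobserved drives
  registration by default.
* Encounter counts per person-year are Poisson around the segmented mean
  of the chosen preset (`paper-MD`, `paper-NPPA`, `paper-TC` — the
  published Table-2-style estimates — or `null`). The linear mean can go
  negative far from the index (the TC preset crosses zero before year
  −6), so it is clamped at `mean_floor` (default 0.01); when more than 5%
  of person-year cells are clamped the generator warns, because clamping
  biases recovery tests. Recovery protocols therefore restrict TC runs to
  pre-years −4..−1. The count distribution is this artifact's choice —
  the source design reports only a linear mean structure; Poisson keeps
  counts integer-valued while leaving OLS unbiased for the mean.
* Messages to portal patients arrive at 1.49/patient/year with
  Gamma(shape 2) handling times averaging 3.83 minutes; prescriptions
  carry ATC codes directly with ~12.5% in excluded schedule classes
  (`OTC`, `ethical`, `other`, literal `"NA"`), standing in for the
  drug-database exclusions applied upstream in the original extraction.
* An optional patient-level Gaussian random intercept (default SD 0) is
  available for robustness studies.
* Identical config (including the mandatory seed) gives byte-identical
  bundles; generation never perturbs the caller's RNG state.

### What a green test does and does not establish

The generator reproduces the *statistical shape* the design assumes:
index-anchored segmented count trends, covariate-driven selection,
staggered observation. It does not emulate coding realism (ICD/ATC
vocabularies), seasonality, within-year clustering of visits, calendar
shocks, or unmeasured confounding. Green recovery tests therefore
establish that the estimator is consistent *when the design's assumptions
hold*, not that the published estimates are robust to their violation.

One structural honesty note: the generator anchors each control's
trajectory at a single latent index (July 1 of the median eligible year),
but open-cohort matching may select a *different* eligible year for that
control. The matched panel then sees control trajectories shifted by the
offset between latent and matched year, which smears the (small)
control-side level/slope changes across relative years — so end-to-end
pipeline runs recover the portal-minus-control contrasts only
approximately. Coefficient-recovery acceptance checks therefore simulate
matched panels directly (`simulate_panel()`), where truth alignment is
exact by construction; the full pipeline is validated for determinism,
bookkeeping conservation, constraint satisfaction and balance instead.

## Numerical and convention choices

* **"One year of data"** is calendar-exact and leap-safe: the full
  365/366-day interval must lie inside the observation window
  (`lubridate::add_with_rollback`; Feb 29 anniversaries roll back to Feb
  28). A person-year span is half-open, `(index + (t-1)y, index + t*y]`,
  so an encounter dated exactly on the index date belongs to year 0 and
  spans tile time without overlap.
* **Lookback window** is `(index - 1y, index]`: "the 12 months prior"
  with the index day included on the closed end. One convention, fixed
  and tested.
* **"Two consecutive years of data between 2009 and 2019"** (control
  eligibility) is read as continuous registration coverage of ≥ 2 years
  intersected with 2009–2019; an alternative reading (two calendar years
  each containing activity) would admit patients with long gaps and is
  not implemented.
* **Control index years** are restricted to 2010–2018 so every control
  index is within a year of a possible portal index.
* **Age rule**: person-time before the 18th birthday is deleted *before*
  any window is evaluated; a patient can lose eligibility entirely this
  way.
* **Top utilisation band** is read as "11 or more" (the printed bands
  must partition the nonnegative integers after "6-10").
* **Quintile cut points** at pooled quantiles; duplicate cut points (mass
  ties) collapse groups rather than erroring.
* **Degenerate inputs**: missing sex and undated records are hard errors;
  missing income/education stay empty; empty candidate sets and empty
  registration cohorts are reported, not errors; a constant registration
  label or a separating covariate aborts the propensity fit with a
  diagnostic.
* **Pipeline seeds**: one master seed fans out to deterministic per-stage
  child seeds (kept below 2^31), so stages can be rerun in isolation.

## Known limitations

* Greedy (not optimal) matching; no replacement; no IPTW.
* Linear-mean OLS only; the segmented Poisson/negative-binomial variants
  are deliberately out of scope.
* The workload estimate divides provider-sent messages in a calendar year
  by patients registered by the end of that year; an "active patients"
  denominator is available as an option, since the right denominator is
  genuinely ambiguous.
* The published figure captions contain an internal tension (a post-index
  portal slope described as negative while the printed coefficient sums
  to slightly positive); no package output or test is built on either
  claim.
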