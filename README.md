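# portalits

Propensity-score–matched, open-cohort, interrupted time-series (ITS)
evaluation of the effect of patient-portal registration on the use of
traditional primary-care services — physician (MD) visits, nurse
practitioner / physician assistant (NP/PA) visits, and triage calls (TC) —
packaged as a tested, reusable pipeline with a synthetic EMR generator so
every stage can be exercised and validated without any real patient data.

It is written for epidemiologists and health-services researchers who want
to run (or interrogate) this study design end to end: cohort eligibility
with open-cohort index-date assignment for controls, index-date covariate
construction with 12-month lookbacks, logistic-regression propensity
scores with caliper-constrained greedy unique-first 1:1 matching, balance
diagnostics by standardized differences, segmented person-year ITS
regression with cluster-robust standard errors, and the descriptive
outputs (baseline table, ITS overlays, registration-cohort curves, and a
clinician messaging-workload estimate).

## The model

Each matched patient contributes annual encounter counts at relative years
`t` from their index date (portal registration date for the portal arm;
July 1 of the matched calendar year for controls; year 0 is the 12 months
up to and including the index date). With arm indicator `A` (1 = portal)
and post-period indicator `P = 1{t >= 2}`, the segmented regression is

```
E[count] = b0 + b1*t + b2*P + b3*(t-2)*P
           + A*(b4 + b5*t + b6*P + b7*(t-2)*P)
```

so `b6` is the portal-versus-control jump in visits at year 2 relative to
the pre-index trend, and `b7` is the difference in post-index slope
change. Years 0 and 1 are excluded from the fit (index-year attribution
spike; transient adoption year). The post-period slope term is anchored at
`t = 2`. Standard errors are reported both conventionally and
cluster-robust by patient (CR1); cluster-robust is the default because
patients contribute repeated annual measurements.

Balance is assessed with standardized differences
(`|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2))/2)` for proportions), with values
below 0.1 read as negligible. The caliper is 0.2 pooled SDs of the logit
propensity score, and a control person-year is only eligible for a portal
patient when the two index dates are within 366 days.

## Worked example

Recover the published MD-channel coefficients from a simulated matched
panel (3696 patients per arm, Poisson counts around the segmented mean):

```r
library(portalits)
pan <- simulate_panel(preset_coefficients("paper-MD"), 3696,
                      c(-8:-1, 2:8), seed = 1)
fit_its(pan)
#> Segmented ITS fit: channel MD, 110880 person-years, 7392 patients
#>   SEs: cluster (years 0, 1 excluded)
#>   b0     1.592 (SE 0.016, p <0.001)  intercept (control)
#>   b1     0.012 (SE 0.003, p <0.001)  annual visits (pre-index slope, control)
#>   b2    -0.048 (SE 0.026, p 0.066)  period (level change at year 2, control)
#>   b3     0.039 (SE 0.005, p <0.001)  annual visits x period (slope change, control)
#>   b4     0.002 (SE 0.022, p 0.92)  portal (intercept difference)
#>   b5     0.014 (SE 0.004, p 0.0015)  portal x annual visits (pre-slope difference)
#>   b6     0.435 (SE 0.037, p <0.001)  portal x period (level-change difference)
#>   b7    -0.061 (SE 0.008, p <0.001)  portal x annual visits x period (slope-change difference)
```

The single-replicate estimates sit within sampling error of the generative
truth (`b6 = 0.417`, `b7 = -0.054`): portal registration is followed by a
jump of ~0.42 extra MD visits per year at year 2, eroding by ~0.05 visits
per year thereafter.

Messaging workload reproduces the published arithmetic exactly:

```r
workload_estimate(3.83, 1.49)
#> Messaging workload: 3.83 min/message x 1.49 messages/patient/year = 5.7 min/patient/year
standardized_difference(0.598, 0.490, kind = "binary")  # sex, pre-matching
#> 0.2181  (rounds to 0.22)
```

A full synthetic run — generate a practice, build the cohort, match, fit
all three channels, and render every output file:

```r
rep <- run_pipeline(run_config(seed = 20260911, n_patients = 2000,
                               out_dir = "out"))
rep
#> portalits pipeline run
#>   data       rows 2000     2.21s
#>   cohort     rows 9132     0.15s
#>   covariates rows 9132     0.26s
#>   match      rows 837      0.48s
#>   its        rows 20945    3.79s
#>   report     rows 11       0.18s
#> Messaging workload: 3.85 min/message x 1.46 messages/patient/year = 5.6 min/patient/year
```

`out/` then holds `balance.csv`, `matches.csv`, `panel.csv`,
`its_fit_{MD,NPPA,TC}.json`, overlay plots, `cohort_curves.csv`,
`workload.json` and `manifest.json`. Note that end-to-end coefficient
estimates are *not* expected to equal the generative presets: matched
controls enter at an open-cohort index year that can differ from the
latent year their trajectory was generated around (see the methods
vignette, `vignettes/portalits-methods.Rmd`).

A command-line front end is installed at `inst/cli/portal-its`
(`portal-its run --config cfg.dcf`, plus `simulate`, `match`, `fit`,
`report` subcommands).

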