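---
title: "Methods: a salt-policy microsimulation for CVD and gastric cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a salt-policy microsimulation for CVD and gastric cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`saltsim` is a discrete-time, dynamic, stochastic microsimulation of an
English-like adult population under counterfactual dietary-salt policy
scenarios. Its purpose is to estimate cases and deaths prevented or
postponed (CPP/DPP) for cardiovascular disease (CVD = first coronary heart
disease or stroke) and gastric cancer (GCa), stratified by deprivation
quintile (QIMD, 1 = least deprived), together with regression-based equity
slope indices and second-order Monte Carlo uncertainty.

The causal chain is:

1. **Exposure.** Daily salt intake (treated as identical to 24-hour urinary
   sodium expressed as g/day of salt: all salt consumed is excreted) is
   assigned per individual-year. Cross-sectional survey waves are generated,
   a declining trend is fitted by quantile regression on `log(year - 2000)`,
   and each individual follows their persistent quantile (rank) of the fitted
   stratum distribution over time.
2. **Mediation and lags.** A salt change moves systolic blood pressure (SBP)
   linearly (configurable meta-regression coefficients, ~0.64 mmHg per
   g/day plus age and hypertension modifiers) and reaches CVD incidence with
   a 5-year mean lag; salt acts on GCa directly with an 8-year mean lag.
3. **Risk.** Relative risks are log-linear above ideal exposure levels
   (`RR = rr^max(0, x - ideal)`), multiplicative across risk factors, and
   fully reversible (the RR depends only on the current lagged exposure).
   The ideal salt level is uncertain: PERT(1.5, 3.8, 6.0) g/day.
4. **Events.** Baseline hazards are calibrated per (age group, sex, QIMD)
   stratum so that `mean(h0 * RR)` reproduces the baseline incidence table
   in the first simulated year; annual event probabilities are
   `1 - exp(-h0 * RR)`. Individuals develop first CHD, stroke and GCa
   independently and die of these or other causes in a competing-risk step;
   only first events count, and GCa survival of 10 years equals remission.

# Scenarios

* **no intervention** — salt frozen at its 2003 level.
* **current policy** — the logarithmic decline fitted on the 2001-2011
  waves, continued to 2030.
* **feasible** — from 2016, structural policies drive the mean intake of
  ages 19-64 linearly to a PERT(5.8, 6.0, 7.0) g/day target by 2020.
* **ideal** — the mean reaches a PERT(1.5, 3.8, 6.0) g/day level by 2025.

Target-rule reductions are proportional to each individual's excess over
the drawn target — structural policies (reformulation, taxation) bite
hardest for the highest consumers — and nobody is pushed below the target
by the intervention itself.

**Aging out of the intervention window.** The 19-64 window defines the
population whose mean is driven to the target, mirroring how national
intake targets are defined. People who age past 64 after 2016 stay on the
intervention at its current intensity: mandatory reformulation changes the
food supply, so an achieved dietary change persists and deepens rather
than reverting on a birthday. (A variant that freezes each person's last
in-window reduction fraction was considered and rejected: it strands early
aging-out cohorts on the barely-phased-in 2016-2018 intensities forever,
which has no behavioural interpretation.) Only cohorts already over 64 at
policy start are never treated.

# Key parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| salt anchors | 9.5 (2001), 8.1 (2011) | g/day population means; the printed survey calibration |
| salt distribution | lognormal, CV 0.40 | single-collection 24-h urine surveys show SD ~3-4 g/day on means of 8-9.5 (day-to-day variation inflates the cross-sectional spread) |
| QIMD salt gradient | 0.8 | g/day, most minus least deprived, additive, centred on quintile 3 |
| SBP per g/day salt | 0.64 (+0.11/decade >50, +0.42 if SBP>=140) | mmHg; externally sourced meta-regression defaults (`inst/extdata/sbp_meta_regression.csv`) |
| RR per mmHg SBP | 1.030 (CHD), 1.040 (stroke) | above ideal SBP 115 mmHg; externally sourced defaults with CI columns used for Monte Carlo draws |
| RR per g/day salt (GCa) | 1.080 | above the drawn ideal salt level |
| mean lags | 5 y (CVD), 8 y (GCa) | smoking-on-GCa follows the CVD lag |
| case-fatality improvement | 5%/y (CVD), 2%/y (GCa) | improvement decays 1% (relative) per year |
| QIMD fatality gradient | 5% per quintile | halved above age 70, centred on quintile 3 |
| GCa remission | 10 y after onset | remitted cases stop drawing GCa fatality |

Effect sizes for co-risk-factors (BMI, cholesterol, diabetes, smoking,
environmental tobacco smoke, fruit & vegetable deficit, inactivity) ship in
`inst/extdata/effect_sizes.csv` with source notes; all are externally
sourced defaults, not estimates of this package.

# The synthetic world, and what a green test establishes

No real survey, registry or mortality data ship with the package. The
generator emulates the *statistical structure* of the inputs: lognormal
salt with the printed mean anchors, a deprivation gradient, rank-persistent
trajectories, SBP positively dependent on salt, age and BMI, plausible
Gompertz-like incidence/fatality/mortality tables with configurable sex and
deprivation gradients, and a closed population (no migration, fixed QIMD)
replenished by cohorts entering at the minimum age. It does **not**
reproduce true English joint distributions, real secular trends in
co-risk-factors (flat by default), spot-urine calibration equations, or
ONS mortality levels. A green test therefore establishes that the
*machinery* — trend fitting, scenario transforms, lagged risk, calibration,
competing risks, equity summaries — behaves as specified on a world with
known truth; it does not re-establish the published burden estimates,
which depend on the real inputs.

# Numerical choices

* **Quantile regression.** Two parameters per stratum and quantile
  (intercept, slope on `log(year - 2000)`), fitted by Nelder-Mead descent
  of the pinball loss from an OLS start (no LP solver dependency); the
  test suite verifies the tau = 0.5 fit against a brute-force
  least-absolute-deviation oracle. Crossing quantile curves are remedied by
  rearrangement (sorting at each evaluation point); individual ranks are
  interpolated linearly between adjacent curves, with linear tail extension
  and a 0.05 g/day floor.
* **Lag kernels.** `lag_kernel()` implements a discretised normal over
  non-negative offsets whose location is solved so the discrete mean equals
  the stated mean lag exactly. The *default* in `risk_params()` is a point
  mass at the mean (`lag_sd = 0`): the published lag-window arithmetic
  (2003-2015 salt changes affect CVD incidence only in 2008-2020 and GCa
  only in 2011-2023) is exact only under a pure shift, and the test suite
  asserts that containment on the incidence-probability matrices.
  Containment is a statement about incidence; disease mortality trails
  incidence through prevalence.
* **Hazard vs probability.** Annual probabilities use the exponential
  transform `1 - exp(-hazard)` within each step, keeping them in `[0, 1]`
  for any hazard.
* **Cause of death.** When several causes fire in one year, a single cause
  is recorded with probability proportional to the competing hazards.
* **Common random numbers.** All Bernoulli draws use the `u < p`
  convention with uniforms drawn for every individual in a fixed order
  regardless of vital status, so paired scenario runs sharing a seed are
  positively coupled; with mortality disabled, the lower-salt run's
  incident event set is provably a subset of the higher-salt run's. CRN
  changes no expectation, only the variance of paired differences.
* **Equity slope indices.** The slope-index-of-inequality convention:
  quintile values are regressed (weighted least squares, weights =
  quintile populations) on the midpoint of each quintile's cumulative
  population share ranked least to most deprived, and the slope is the
  fitted rank-1 minus rank-0 difference. Reported slopes are therefore on
  the cumulative-population-fraction scale, not per quintile step. The
  relative index divides CPP by the counterfactual stratum burden.
  Standardised variants reweight age-sex-specific rates to the common
  population structure; person-year denominators use the population
  structure at the period midpoint ignoring deaths (an approximation
  documented here and used only for weights/denominators).
* **IQRs and Ps.** Quartiles use type-7 interpolation; `Ps` is the
  percentage of Monte Carlo iterations with a strictly positive value
  ("at least one case prevented or postponed").
* **Monte Carlo structure.** Each iteration regenerates waves and
  population (first-order uncertainty), refits the trend, draws relative
  risks from lognormals matching their CI columns and the ideal-salt /
  policy-target PERTs (second-order uncertainty), then runs all scenarios
  with one shared seed. Iterations never fail silently.

# Design decisions taken where the design was open

* Quantile regression is fitted *within* (sex, QIMD) strata rather than
  adjusting for QIMD as a covariate, because the deprivation gradient in
  both level and trend is the quantity of interest.
* The 2016-2030 current-policy projection reuses the trend fitted on the
  2001-2011 waves (not refitted on modelled 2012-2015 years): the modelled
  interim years contain no new information.
* The feasible scenario's PERT mode is set to 6.0 g/day, the national
  target bracketed by the stated 5.8-7.0 range.
* The QIMD fatality gradient is multiplicative per quintile step and
  centred on the middle quintile, so quintile 3 carries the table rate.
* SBP is age-flat within the simulation (age effects on absolute risk live
  in the age-stratified baseline hazards; individual SBP moves only with
  lagged salt). This avoids double-counting age both in the rate tables
  and in the RR term.
* Whether two diseases can start in the same year is unspecified; the
  competing-risk framework here allows it (independent incidence draws).

# Known limitations

* The synthetic rate tables are plausible stand-ins, not calibrated English
  rates; absolute CPP/DPP magnitudes are not comparable to published
  figures, only directions and mechanics are.
* Under the stated calibration (constant-CV lognormal anchored at printed
  2001/2011 means with a logarithmic decline), the projected *median* path
  reaches about 7.0 g/day by 2030 — the published median (6.2) falls faster
  than the published mean anchors allow for any constant-shape
  distribution, an inconsistency that cannot be resolved from the printed
  numbers alone (the original used a supplementary spot-urine synthesis).
  The acceptance suite reports this target honestly rather than retuning
  the generator toward it.
* Proportional-to-excess interventions drive the in-window *mean* to the
  target while leaving the below-target tail untouched, so the
  within-population median lands slightly above the target mean; published
  medians under the structural scenarios are correspondingly lower than
  this package produces.
* Other-cause mortality has no secular improvement; co-risk-factor trends
  are flat by default.
* No migration, social mobility, recurrent events, severity states, costs,
  kidney disease, or Responsibility-Deal modelling.
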