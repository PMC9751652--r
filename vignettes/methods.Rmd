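---
title: "Poisson hazard models, gradients of risk, and the synthetic cohort design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson hazard models, gradients of risk, and the synthetic cohort design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model implemented in `fracgr`, the
numerical choices behind the fitter, the design of the synthetic cohort
generator, and what validation on synthetic cohorts does and does not
establish about real data.

## The survival model

`fracgr` implements the "extension of Poisson regression" commonly used in
fracture epidemiology as an alternative to Cox regression. Follow-up for
each participant is split into at-risk intervals of exactly 1/12 year
(`split_followup()`); no calendar anchoring is used because follow-up is
measured in years from baseline. On an interval starting at time $t$ the
hazard per person-year is

$$\lambda(t) = \exp\{\beta_0 + \beta_1 t + \beta_2\,\mathrm{age}(t) +
\beta_3 x + \cdots\},$$

with $t$ the current time from baseline and $\mathrm{age}(t)$ the current
age, both entering linearly (the model this package targets specifies
linear terms; no splines are offered). Every analysis adjusts for age and
time since baseline through $\beta_1,\beta_2$; additional covariates are
the adjusters of `model_spec()`. With event indicator $y$ and interval
exposure $\Delta t \le 1/12$ the interval log-likelihood contribution is
$y\eta - e^{\eta}\Delta t$, i.e. a Poisson likelihood with offset
$\log\Delta t$. This makes the partial final interval exact: the last
month carries its true remaining exposure rather than being rounded, so
summed $\Delta t$ reproduces each subject's time at risk to machine
precision (asserted in the test suite).

Time at risk for an outcome is censored at the first qualifying fracture,
loss to follow-up, death, or end of follow-up, whichever comes first; one
fracture per person is counted. An event falling exactly on an interval
boundary belongs to the earlier interval — intervals are half-open
$(\mathrm{start}, \mathrm{end}]$ — which also resolves the tie when a
fracture coincides with death or administrative censoring: the fracture
counts. Loss to follow-up absent from the input is treated as never
occurring.

### Outcome sets

Fracture sites are classified by `classify_fracture()` into four nested
sets: any; osteoporotic (Kanis list: clinical vertebral, ribs, pelvis,
humerus, clavicle, scapula, sternum, hip, other femoral, tibia, fibula,
distal forearm/wrist); major osteoporotic (hip, clinical vertebral,
proximal humerus, distal forearm/wrist); hip. Cohort recording conventions
are mapped to the closest category (`wrist` → distal forearm/wrist,
`vertebra` → clinical vertebral, `shoulder` → proximal humerus). The codes
`arm` and `humerus` cannot be localized to the proximal humerus, so they
count as osteoporotic but not major osteoporotic; the mapping lives in a
plain-text table (`inst/extdata/fracture_sites.tsv`) and is overridable
per cohort via the `site_map` argument, which is the single point of truth
for such decisions. Pathological fractures are expected to be excluded
upstream, before events enter the person-level table.

### Competing mortality

The headline gradient of risk is a cause-specific hazard ratio: death
censors the fracture process. The duplicated-record construction for joint
cause-specific modelling is available as a sensitivity analysis:
`duplicate_for_competing()` stacks a fracture stratum and a death stratum
(time at risk to min(death, loss, follow-up), event = observed death).
With fully stratum-specific coefficients the joint Poisson likelihood over
the stacked records factorizes, so `fit_cause_specific()` fits each
stratum and together these constitute the joint fit. We do not claim this
reproduces any particular published duplication algorithm whose
construction is not described in the methodological literature we follow;
it is the standard stacked cause-specific formulation.

## Numerical choices in the fitter

`fit_poisson_hazard()` maximizes the log-likelihood by Newton–Raphson with
step-halving. Design choices:

* **Initialization**: $\beta_0 = \log(\text{events}/\text{person-years})$,
  all other coefficients 0. For the intercept-only model this is already
  the closed-form MLE, and the fitter reproduces it to $10^{-8}$.
* **Convergence**: relative log-likelihood change below $10^{-10}$, at
  most 100 iterations. Non-convergence is flagged (`converged = FALSE`),
  never silent; `gradient_of_risk()` refuses non-converged fits, and
  `run_analysis()` skips flagged cohorts from pooling with a warning.
* **Step-halving** (up to 30 halvings) keeps the ascent monotone far from
  the optimum and guards against overflow of $e^{\eta}$.
* **Covariance**: inverse observed information at the optimum. The
  log-likelihood is concave in $\beta$, so the information is positive
  semi-definite everywhere and the optimum, when it exists, is global —
  both asserted in tests, along with agreement with `glm(poisson)`/IRLS
  and with a restarted Nelder–Mead brute-force search on small instances.
* **Degenerate inputs**: no events, rank-deficient designs, missing
  covariate values (complete-case filtering is required *before*
  splitting) and singular information (separation) raise errors.
* **Wald inference**: $\exp(\hat\beta_3 \pm z_{0.975}\,\mathrm{se})$ with
  $z_{0.975} = $ `qnorm(0.975)`; p-values are two-sided normal.

Exposures are standardized within cohort by `standardize_exposure()`
(sample SD, denominator $n-1$), so $e^{\beta_3}$ is the hazard ratio per
within-cohort SD and is invariant to the raw measurement units. Whether the
original analyses standardized within cohort or on the pooled sample is
not documented; cohort-specific SDs are the implemented default because
the estimation is per-cohort with pooling afterwards (pooled
standardization can be had by passing a constant group label). FRAX
probabilities enter untransformed on the percent scale — a flagged
assumption; a log transform is a plausible alternative and can be applied
to the column before fitting. When the other pQCT measure is an adjuster
it is standardized identically to the exposure. Complete-case restriction
(dropping subjects missing any required covariate before splitting) mirrors
the FRAX-subset analyses of the motivating study design.

No aggregation of identical person-months is performed: with continuous
standardized exposures the rows are almost surely unique, and the
unaggregated fits are fast enough (about a second per cohort of 5,000
subjects).

## Meta-analysis

`pool_fixed_effects()` pools per-cohort log hazard ratios with weights
$w_i = 1/\mathrm{se}_i^2$, pooled SE $(\sum w_i)^{-1/2}$, Cochran
$Q = \sum w_i(\beta_i - \bar\beta)^2$ and
$I^2 = \max\{0, (Q-(k-1))/Q\}\times 100$ (defined as 0 when $Q = 0$).
Fixed effects are the headline method, consistent with the low-to-moderate
heterogeneity regime this design targets; $I^2$ is reported with every
pooled result so that the assumption is checkable on each run, and a
DerSimonian–Laird random-effects pooling (`pool_random_effects()`) is
provided as a labeled sensitivity output. Both agree with `metafor` in the
cross-check tests.

## The synthetic cohort generator

Real cohort data of this kind are access-controlled, so
`generate_cohort()` emulates them. `mros_cohort_configs()` encodes three
cohorts of older men ("hk", n = 1662; "sweden", n = 1521; "us", n = 991)
with published-table calibration: covariate means and SDs (e.g. muscle
density 77.0 ± 3.6 mg/cm³ and age 73.9 ± 4.9 in the Hong Kong cohort),
follow-up distributions (8.1 ± 2.3, 5.3 ± 2.0, 7.8 ± 2.2 years),
FRAX-complete fractions (1382/1662, 976/1521, 478/991), prior-fall
prevalences, per-cohort fracture-site frequencies chosen to reproduce the
relative sizes of the four outcome counts, and overall fracture rates
derived from events/person-years. Mortality intercepts are set to
plausible rates for men of these ages (3–5%/year at the cohort mean age,
log-hazard slope 0.09 per year of age), as the source tables do not report
mortality.

Design decisions, each exposed in `cohort_config()`:

* **Shared probability space.** Events are simulated in discrete time on
  the same monthly grid the estimator uses: in each month an event occurs
  with probability $1-\exp(-\lambda\Delta t)$ with $\lambda$ evaluated at
  the interval start. Parameter recovery is therefore exact in
  expectation up to the Bernoulli-vs-Poisson increment difference, whose
  relative bias is about $\lambda\Delta t/2$ — under 0.2% at
  fracture-like rates ($\lambda \approx 0.01$–$0.05$/year, $\Delta t =
  1/12$). The generator should not be used with hazards approaching
  1/month, where this bias becomes material.
* **One fracture process, thinned by site.** A single "any-fracture"
  hazard is simulated (recurrently — all fractures are recorded, not just
  the first) and each fracture receives a site code drawn from a
  configurable categorical distribution. The nested outcome processes are
  thinnings of one process, which makes the nesting invariants hold by
  construction and preserves per-SD log hazard ratios for every outcome
  because the site assignment is covariate-independent.
* **Fracture before death.** Within a month the fracture draw precedes
  the death draw, so a subject fracturing and dying in the same month
  contributes the fracture — the conservative reading of time-to-first-
  fracture counting.
* **Per-SD effects.** True exposure effects are specified per configured
  SD (`true_log_hr`), matching the estimand.
* **Covariate structure.** Continuous covariates are multivariate normal;
  FRAX probabilities are log-normal (moment-matched) clipped to (0, 100],
  with injectable joint missingness emulating the FRAX-complete subset.
  The source tables report no correlations, so `default_covariate_corr()`
  is an explicit assumption set: muscle CSA tracks body size
  (r = 0.45 with BMI) and bone density (r = 0.45 with T-score); FRAX
  rises with age and, for the with-BMD variant, falls steeply with
  T-score (r = −0.55). The default effect structure gives muscle density
  a direct protective effect and muscle CSA none: CSA's marginal
  association arises purely through its T-score correlation, so it
  attenuates to the null on T-score adjustment, while a small *negative*
  density–T-score correlation (−0.10) makes the density association
  strengthen slightly under the same adjustment — the qualitative
  suppression pattern this analysis design is built to detect.
* **Follow-up.** `fu_mean`/`fu_sd` parameterize *potential*
  (administrative) follow-up, truncated to [1/12, `max_followup`];
  simulated death then shortens observed person-years by roughly 10–15%
  under the default mortality. The descriptive `table_one()` reports
  observed person-years (time to end of observation, which runs past a
  fracture but not past death).
* **Seeds.** One master seed; cohort $i$ uses seed$+i-1$. Generation is
  byte-reproducible and restores the caller's RNG stream.

What the generator does **not** emulate: real fracture-site epidemiology
beyond category frequencies (site assignment is independent of age and
covariates), secular or seasonal trends, measurement error in exposures,
informative loss to follow-up, non-proportional hazards, and any
dependence of death on the exposures. Passing tests therefore establish
the *estimator's* correctness under the model's assumptions — recovery of
known per-SD hazard ratios, interval calibration, exact person-time
accounting — not that the model is correctly specified for any particular
real cohort.

## Validation problem sizes

The test suite validates the full path at sizes chosen to make Monte Carlo
noise small relative to the tolerances asserted: closed-form and IRLS
agreement on single cohorts of 500–1,700 subjects; brute-force oracle
agreement on 20 instances of at most 200 person-months; parameter recovery
at a known per-SD hazard ratio over 50 replicates of three cohorts of
5,000 subjects (pooled GR averaged across replicates recovers the truth to
within ±0.03); Wald coverage over 200 single-cohort simulations of 2,000
subjects; and the attenuation-on-adjustment pattern at three cohorts of
5,000. The whole suite runs in a couple of minutes on one CPU.

## Known limitations

* Left truncation, recurrent-event analysis and calendar-time effects are
  out of scope; time and age enter linearly only.
* Absolute 10-year fracture probabilities (integrating fracture and death
  hazards, FRAX-style) are not computed; FRAX output is consumed as a
  covariate only.
* The per-cohort coefficients of the motivating published analysis are
  unpublished, so pooled numbers from synthetic cohorts can mirror the
  published pattern but cannot be reconciled arithmetically with any
  single published table.
* Fixed-effects pooling assumes a common true effect; check the reported
  $I^2$ and prefer the DerSimonian–Laird output when heterogeneity is
  material.
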