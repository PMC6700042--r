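---
title: "Profiling hospital survival outcomes with hierarchical survival models and funnel plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling hospital survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oefunnel)
```

## The analysis in one paragraph

oefunnel compares survival outcomes after glioblastoma surgery across the
hospitals of a national registry. Two indicator outcomes are used: death
within 30 days of surgery (early mortality) and being alive at 730 days
(late survival). Because hospitals treat different patient populations, a
hierarchical proportional-hazards model first learns how age, performance
status and treatment year drive the hazard; each patient's expected outcome
probability is then computed *as if treated at an average hospital* (random
effect zero), summed per hospital into expected event counts, and the
observed-to-expected (O/E) ratio is judged against Poisson funnel control
limits. Hospital-level characteristics (case volume, academic setting,
biopsy percentage) are explored separately by univariate logistic regression
and fixed-effects hazard ratios.

## Model and assumptions

The death counting process is piecewise-exponential: time since surgery is
cut at `{0, 30, 90, 180, 270, 365, 545, 730, 1095, 1460, Inf}` days and the
baseline hazard is constant within each interval. Expanding each patient
into one row per interval at risk turns the likelihood into a Poisson GLM
(`build_counting_process()`), the standard log-Poisson realization of a Cox
model with a step baseline. The breaks always include 30 and 730 so the two
outcome horizons coincide with hazard steps and standardized probabilities
need no interpolation.

Covariates enter as `(age - 61.4)/10`, `(KPS - 80)/10` and treatment-year
indicators against the first year. The decade / 10-point scaling is a
modelling choice: it puts the hazard ratios on the scale on which published
glioblastoma prognostic effects (age HR about 1.5 per decade, KPS about 0.77
per 10 points) have plausible magnitude. Hospital frailties are
`u_h ~ N(0, sigma_u^2)` on the log-hazard scale — proportional hazards
between hospitals, and exchangeability of hospitals given case mix.

Priors are deliberately vague and configurable (`prior_config()`):
`N(0, 10^2)` for coefficients and interval log-hazards, half-Cauchy(2.5) for
`sigma_u`.

## Sampler and numerical choices

No general-purpose MCMC engine is available to this package, so it carries
its own Metropolis-within-Gibbs sampler:

* the coefficient block uses Gaussian independence proposals centred at the
  conditional mode found by iteratively reweighted least squares (the
  Poisson conditional is extremely close to Gaussian at registry sample
  sizes, so acceptance is near 1);
* each interval log-hazard and each frailty has a strictly concave 1-d
  conditional of the form `d*x - A*e^x - (x - m)^2/(2v)`, updated by
  independence MH from a Newton-mode Gaussian with 1.2x inflated SD;
* `log sigma_u` is slice-sampled;
* one exact Gibbs step each iteration moves along the likelihood-invariant
  ridge `u -> u - c`, `log lambda -> log lambda + c`, which otherwise mixes
  slowly (the frailty mean trades off against the hazard level).

Defaults are 4 chains, 1,000 warmup + 1,000 kept iterations, an explicit
integer seed, and a hard convergence gate: if any split-R-hat is 1.01 or
more the fit is returned flagged (`converged = FALSE`, with a warning)
rather than silently summarized. Degenerate-input guards: deaths recorded at
day 0 get 0.5 days of exposure; intervals containing no person-time are
pinned at hazard `exp(-30)` (nothing else conditions on them); `sigma_u` is
floored at 1e-4, below which the model is numerically indistinguishable from
no frailty.

`method = "laplace"` replaces MCMC by the Poisson GLMM of `lme4::glmer`
(`nAGQ = 0`) and draws from the Gaussian approximation of the posterior. It
agrees with the MCMC on regression coefficients to within a few hundredths
at registry scale and is the intended engine for repeated-simulation
studies (the null-calibration acceptance test runs 50 registries with it).

## Risk standardization

Per posterior draw, `S(t | x) = exp(-exp(x beta) * Lambda0(t))` with the
exact piecewise-linear cumulative baseline and `u = 0`. Expected counts per
hospital are the posterior **median of the per-draw sums** of patient event
probabilities (consistent with summarizing posteriors by medians); the
plug-in alternative — summing posterior-median patient probabilities — is
available via `summary = "plugin"`. Whether the original analysis used one
or the other is not documented; the two differ negligibly away from extreme
skew, and both are exposed.

Observability follows the indicator definitions: a patient counts at horizon
h only if death occurred by h or potential follow-up (surgery to lookup
date) reaches h; patients lost to follow-up before h are excluded because
their outcome is genuinely unknown.

One subtlety matters for late survival. A patient treated close to the
lookup date (potential follow-up < 730 days) is observable only if they
died — so they can never contribute an observed survivor, and conditional
on being observable their survival probability is zero. Summing the
unconditional `S(730)` over such patients would bias every hospital's O/E
ratio downward (about 0.81 instead of 1 in the null world, enough to
spuriously flag hospitals as under-performing). `expected_events()`
therefore counts expected survivors only over patients whose potential
follow-up reaches the horizon; observed counts are unaffected because all
observed survivors are in that subset. The registry's own numbers behave
this way (a hospital with 12 full-follow-up patients and 0.89 expected
survivors).

## Funnel limits: exact versus interpolated

Control limits for O/E at expected count E come from `Poisson(E)`:

* **exact** — integer quantile limits; by construction the probability of a
  false flag is at most alpha. At small E the lower limit collapses to 0,
  so a hospital with 0 observed events can never be flagged low.
* **interpolated** (default) — smooth gamma-quantile limits
  `qgamma(a/2, E)/E` and `qgamma(1-a/2, E+1)/E`, the continuous bridge
  between adjacent Poisson CDF steps. The curves narrow monotonically,
  coverage is near nominal for moderate E (about 5% outside at the 95%
  level for E between 4 and 43, verified by enumeration), but at very small
  E the lower limit stays positive, so 0 observed against, say, 0.89
  expected falls below the 99% lower limit — anti-conservative there.

The reference analysis flagged exactly such a hospital, which plain integer
Poisson limits cannot do; its construction for small expected counts is
undocumented. Both methods therefore ship, the method tag is recorded in
every output, and the choice is the user's. Flagging uses strict
exceedance: a ratio exactly on a limit is "within".

## The synthetic registry

`generator_config()` encodes the world the pipeline is validated against: 14
hospitals with case volumes 81-358 (2,409 patients), age ~ Normal(61.4,
12.2) truncated at 18, KPS on the 10-100 ladder with the registry's overall
distribution, treatment years 2011-2014 with the registry's yearly mix,
per-hospital biopsy fractions 16-73%, missing age/KPS at the registry's
overall rates, administrative censoring at 2016-03-01, and true effects set
to the published point estimates (age log 1.54 per decade, KPS log 0.77,
years log 0.94/0.80/0.78). The frailty SD defaults to 0.15 — not a published
quantity; it spans roughly a +/-35% hazard range across 14 hospitals, a
modest, realistic degree of unexplained between-hospital variation.

The baseline hazard shape (rising to about one year, then declining) was
fixed once on clinical grounds; its overall scale and late-interval level
were then calibrated by `calibrate_baseline()` so the marginal cohort hits
the registry's anchors: median overall survival 10.2 months and 2-year
survival 13.5% (30-day mortality lands at 5.1% against 5.2% observed). The
calibrated hazards are frozen as defaults and a test re-derives them.

What the generator does **not** emulate: loss to follow-up other than
administrative censoring (the real registry has a hospital with only 12 of
102 patients observable at 2 years — impossible under purely administrative
censoring), referral patterns, within-hospital time trends, and any direct
effect of surgery type on the hazard. A green test therefore establishes
correctness of the machinery under the stated world, not robustness to
informative censoring.

## Hospital-factor regressions

`patient_level_logistic()` accepts patient records or a binomial-aggregated
per-hospital table; the two give identical maximum-likelihood fits (an
algebraic identity, asserted by tests). Case volume enters as the natural
log of the number of patients. Two volume definitions exist in the
aggregate table: all registered patients versus complete cases. The fit on
complete-case counts reproduces the published association exactly (log OR
-0.389, P = 0.031, boundary volume 180 patients per 4 years at the pooled
30-day mortality); the all-registered definition gives -0.339 and P = 0.068
and demonstrably is not what was fitted. The complete-case definition is
therefore the default, with `volume_definition = "total"` available.

A published summary states a 3.9% relative mortality decrease per 10%
volume increase; that matches the small-change approximation
`slope * delta = 0.39 * 0.10`, while the exact convention
`exp(slope * log 1.1) - 1` gives 3.65%. `relative_effect()` returns both.

## Known limitations

* The sampler is tailored to this model family (log-linear Poisson with one
  Gaussian random intercept); it is not a general MCMC engine.
* Laplace fits understate posterior uncertainty for `sigma_u` (kept at its
  point estimate) and for small-count hospitals.
* Funnel limits assume pure Poisson variation; no overdispersion inflation
  is offered, matching the reference methodology.
* Expected counts for hospitals with zero observable patients at a horizon
  are omitted (logged), not imputed.
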