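---
title: "Estimating behavioral responses to health shocks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating behavioral responses to health shocks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A *health shock* is a sudden, substantial deterioration of physical or
mental health. Whether people respond to such an event by adopting
healthier habits — quitting smoking, eating better, exercising — is a
long-standing question in health economics. `shockdml` implements a
complete analysis pipeline for this question on long individual-by-wave
panels in which health is measured by the SF-12 component summary scales
(PCS for physical, MCS for mental health; both range 0–100 and are
normalized to mean 50, SD 10 in the norm population) and behaviors are
binary indicators observed biannually.

The shock definition is relative: individual $i$ is treated at reference
year $t$ in domain $d$ when the component score fell by **more than 25%**
relative to its level two years earlier,

$$T_i = \mathbb{1}\!\left(\frac{S_{i,t} - S_{i,t-2}}{S_{i,t-2}} < -0.25\right),$$

with the strict inequality meaning a drop of exactly 25% is *not* a
shock. The indicator is undefined — never imputed to 0 — when either
score is missing or the baseline is non-positive.

Because the survey data this design targets are access-restricted, the
package pairs the estimator with a synthetic panel generator whose ground
truth is known, so every stage is testable end to end.

## The estimator

The target is the average treatment effect (ATE) of a shock in the
window $(t-2, t]$ on a behavior measured at $t+s$, conditioning on a
~40-variable covariate set $X$ measured at $t-2$ (including the lagged
scores and the pre-shock level of the behavior itself). The estimator is
augmented inverse-probability weighting (AIPW),

$$\hat\tau = \frac{1}{N}\sum_i
\left[\frac{T_i Y_i}{\hat\pi(X_i)} - \frac{T_i-\hat\pi(X_i)}{\hat\pi(X_i)}\hat g(1,X_i)\right]
- \left[\frac{(1-T_i) Y_i}{1-\hat\pi(X_i)} + \frac{T_i-\hat\pi(X_i)}{1-\hat\pi(X_i)}\hat g(0,X_i)\right],$$

which is doubly robust: consistent when either the propensity model
$\pi(X)$ or the outcome models $g(T,X)$ are correct. Nuisances are
estimated by machine learners under **cross-fitting**: the sample is
partitioned into $K$ splits, models are trained out-of-split and
predicted in-split, so no observation is predicted by a model trained on
it. The whole procedure is repeated over $R$ fresh partitions and the
**median** of the $R$ estimates is reported, damping partition luck.

Key knobs (defaults in parentheses):

* `K` (5) — number of cross-fitting splits. The reference procedure
  leaves K unstated; 5 is standard double-ML practice and keeps folds
  large at realistic sample sizes.
* `R` (15 in `ddml_ate`; 3 in the desk-scale CLI defaults) — resamples.
* Random-forest learner: 500 trees, `mtry = floor(sqrt(p))`, maximum
  depth tuned over {3, 4, 6, 8, 10, 12, 14, 16, 18, 20} by 3-fold CV
  log-loss, for each split in every resample. The forest is a bagged
  CART probability forest compiled from source (no tree learner is
  assumed to exist in the environment). `tune = FALSE` with a
  `fixed_depth` is offered as a fast path for large simulation studies.
* LASSO alternative: L1-penalized logistic regressions (glmnet), penalty
  chosen by 3-fold CV.
* Propensities are clipped to [0.01, 0.99]. The reference description
  notes AIPW's robustness to extreme weights but states no guard; the
  clip protects the pure-IPW reduction and degenerate toys, and the
  bounds are recorded with the predictions.

### Inference

Per resample $r$, the influence-function variance is
$\hat\sigma^2_r = N^{-2}\sum_i(\psi_{i,r} - \hat\tau_r)^2$. Across
resamples the median rule
$\hat\sigma^2 = \mathrm{median}_r\{\hat\sigma^2_r + (\hat\tau_r - \hat\tau)^2\}$
is used, consistent with reporting the median point estimate; intervals
are 90% throughout ($\hat\tau \pm 1.645\,\hat\sigma$). Individual-level
effects are the per-row summands averaged across resamples with the
arithmetic mean, so subgroup averages of individual effects reproduce
subgroup means of the per-resample estimates exactly.

## The synthetic world

`generate_panel()` simulates annual rows for 2001–2019 with biannual
score waves (even years from 2002). Its defaults *are* the stated world
of the target design, calibrated once and frozen:

* **Scores.** Latent health per domain is a permanent individual
  component plus a wave-level AR(1) (persistence 0.75 physical, 0.70
  mental per two years), normalized to unit variance at baseline.
  Scores are $50 + \sqrt{100 - \sigma^2_\varepsilon}\,L + \varepsilon$,
  $\sigma_\varepsilon = 2$, clipped to [0, 100] — hence baseline mean 50
  and SD 10 by construction.
* **Shock events.** From the second wave on, a large latent drop
  (uniform 1.5–3.5 latent SDs, decaying through the AR recursion) occurs
  with hazard $\mathrm{logit}^{-1}(\alpha_d + w'X_i)$. The weights $w$
  load on age, BMI, education, unemployment, disability, income and the
  *pre-window* values of the behaviors, so assignment is confounded in
  exactly the directions the conditioning set can see. The intercepts
  are calibrated so that the 25%-rule flags 5.3% (physical) and 7.7%
  (mental) of individuals at the first reference wave — inside the
  target band of 5–8% with the mental rate higher by roughly two
  percentage points. Flags also fire on ordinary fluctuation (about 2
  points of the rate), which is what makes small-threshold sensitivity
  sweeps attenuate: at a 1% threshold most "treated" individuals never
  experienced a genuine deterioration.
* **Outcomes.** Not smoking (even years from 2002), healthy diet (even
  years 2004–2014) and doing sports (odd years) follow logistic models
  in the static covariates and the behavior's own two-year lag (state
  dependence 2.6 / 1.8 / 2.0 log-odds). Intercepts are calibrated by
  `calibrate_intercepts()` (damped log-odds iteration at n = 30,000) to
  pre-shock prevalences 0.70 / 0.51 / 0.26.
* **Treatment effects.** The configured effect $\delta$(outcome, domain,
  lag) is added on the *probability* scale (clipped to [0, 1]) for
  individuals flagged in the outcome's reference window, and both
  potential outcomes are drawn with a **common uniform** per
  (individual, year). Hence the ground-truth ATE recorded in the
  TruthTable equals $\delta$ exactly up to rare clipping, and null
  effects are *exactly* zero. Effects attach to the flag — the analysis
  concept of treatment — not to the latent event, and only to the fixed
  reference window, mirroring the experiment-replication logic of the
  fixed-t design.
* **Attrition.** An absorbing annual dropout hazard (7.5% baseline,
  +0.4 log-odds after a recent health-drop event, −0.25 for lagged
  non-smoking) plus 3% transient item non-response, which the attrition
  outcome deliberately also captures.

### What a green test does and does not establish

Identification holds in the synthetic world *by construction*: outcomes
depend on static covariates and their own lag, never on concurrent
latent health, and the drop hazard consumes only pre-window information.
So conditioning on the t−2 set satisfies conditional independence
exactly, the oracle ATE is sharp, and parameter-recovery tests genuinely
probe the estimator rather than the generator. The flip side: the
generator cannot detect failures that arise when real outcomes respond
to the *same* latent health that defines treatment (dynamic
confounding), and its covariate correlations are invented — the real
survey's joint distribution is not public. Green recovery tests certify
the estimator's implementation, not the causal credibility of any
real-data application.

One deliberate exception: because the drop hazard at *intermediate*
waves responds to earlier behaviors, the default world carries subtle
differential pre-trends — placebo estimates under the default
configuration are not all null, just as in the motivating study, which
found some significant placebo cells and responded with full-history
conditioning. The placebo-null acceptance property is therefore stated
for a generator without behavior feedback
(`confounding_weights` restricted to static covariates), where ~90% of
90% intervals cover zero.

### Placebo design

Placebo samples shift the shock window to $(2010, 2012]$ and measure
outcomes strictly before it. Conditioning mirrors the main design —
covariates and scores at t−2 plus the last pre-window value of each
behavior — rather than variables predating every outcome: this is what
the timing structure of the motivating design implies, and it is the
set under which the no-pre-trend world is exactly identified. The lag
grid stops before the analyzed behavior's own conditioning year (t−4
for the even-year behaviors, t−5 for sports), so nothing serves as
outcome and control at once.

## Numerical choices and degenerate inputs

* Shock indicators with non-positive or missing baselines are excluded
  and counted, never set to 0 — treatment status must be honest under
  attrition. Individuals with non-computable status are excluded from
  both arms.
* Cross-fitting redraws the partition (fresh sub-seed, logged) when a
  training fold lacks an arm; 20 failures abort.
* Depth tuning breaks ties toward the smaller depth; a single-class
  training target returns the smallest depth with a warning.
* Threshold-sweep cells with fewer than 30 treated units are flagged and
  not estimated: rare-event cells produce unstable estimates, and
  refusing is more honest than reporting noise.
* The ASMD uses the pooled-SD form $|\bar x_1 - \bar x_0| /
  \sqrt{(s_1^2 + s_0^2)/2}$ with $p(1-p)$ variances for binaries (the
  standard definition; the reference text prints none), flag at 0.1.
  The 2×2 chi-squared uses the closed form without continuity
  correction.
* All randomness flows through hierarchical seeds (master → resample →
  fold), so any single resample is reproducible in isolation; panels
  are byte-identical given a seed.
* Education strata split at the sample median years of education by
  default (the reference analysis never states its cut); SPC² is
  computed on the resample-averaged individual effects, with aliased
  columns dropped and reported as zero.

## Known limitations

* The forest is a plain bagged CART probability forest — no honesty,
  no out-of-bag tuning shortcuts; depth tuning at full scale is
  expensive (tuning for each split in every resample at R = 15 is an
  hours-long reference configuration; the CLI's desk defaults use
  R = 3 with a fixed depth).
* Influence-function intervals ignore clustering; the unit of analysis
  is the individual and each analysis uses one row per individual, so
  there is nothing to cluster over within one estimation sample, but
  estimates across lags are correlated and no joint inference is
  offered.
* The generator's covariate joint distribution, attrition law and
  effect profile are stylized; they match published margins
  (prevalences, shock rates, attrition pattern) but not unpublished
  microstructure.
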