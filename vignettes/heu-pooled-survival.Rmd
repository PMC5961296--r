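---
title: "Pooled survival analysis of HIV-exposed uninfected children: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled survival analysis of HIV-exposed uninfected children: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heusurv)
```

## The scientific problem

Children born to HIV-infected mothers who themselves escape infection —
HIV-exposed uninfected (HEU) children — die more often in their first two
years than unexposed children in the same settings. Candidate explanations
are partly maternal (the mother's health, her survival, whether she receives
antiretroviral therapy) and partly infant-level (low birth weight, whether
and for how long the child is breastfed). Individual trials are too small
and too homogeneous to separate these factors, so the natural design is a
pooled analysis of individual participant data across many
prevention-of-mother-to-child-transmission (PMTCT) trials and cohorts.

`heusurv` implements that analysis end to end: data conventions and episode
splitting for time-dependent exposures, shared-frailty Cox models across
study clusters, descriptive survival statistics, and a counterfactual
*adjusted attributable fraction* (aAF) that converts hazard ratios into the
share of deaths a population-level intervention could avert. Because pooled
individual data of this kind are not publicly depositable, the package also
ships a synthetic multi-study cohort generator with known ground truth, and
every statistical component is validated against that ground truth or
against closed forms.

## Data model and conventions

The analysis input is one row per child (see `?"cohort-schema"`): study
label, region, sex, birth weight group (< 2500 g = low birth weight),
breastfeeding initiation and weaning age, maternal antiretroviral category
(none; single/double-agent peripartum prophylaxis; 3-drug ART for PMTCT;
3-drug ART for life), maternal antenatal CD4 group (above/below 350
cells/mm³), and ages in days at maternal death, child death and censoring.

`apply_categorization()` applies fixed conventions before any modelling:

* **Time scale.** Child age in days; "24 months" is 730 days and
  "6 months" 183 days. Months-to-days conversion is configurable in
  `categorization_rules()`; 183 was chosen so that "6 months" rounds a
  365.25-day year consistently.
* **Follow-up cap.** Follow-up ends at 730 days; deaths recorded later are
  treated as alive-at-730 censorings. A death exactly at 730 days counts as
  an event.
* **Unknown feeding status.** Children whose breastfeeding initiation is
  unknown are excluded (the exclusion count is logged), because
  breastfeeding is both an exposure of interest and a time axis for other
  exposures.
* **Unknown weaning age.** A breastfed child with unknown weaning age is
  assumed breastfed until 183 days, study exit, or the mother's death,
  whichever comes first — the feeding guidance prevailing in the source
  studies.
* **Unknown ART windows.** A mother on 3-drug ART for PMTCT with unknown
  stop date is assumed on ART until weaning or 183 days, whichever first;
  ART-for-life extends through follow-up. Mothers with missing
  antiretroviral information are assigned the protocol category
  (single/double-agent PMTCT).
* **Missing categories.** Remaining missing categorical values become
  explicit `"unknown"` levels and are carried through modelling as ordinary
  categories, preserving the sample size.

`split_episodes()` expands each child into counting-process episodes
`(start, stop]` on which all covariates are constant. Episodes are half-open
with events at `stop`; a covariate change-point on the day of death is *not*
cut, so the death is attributed to the pre-change exposure value (the
conservative convention: a death the same day the mother dies is not counted
as post-maternal-death exposure time). A change-point at age 0 simply makes
the first episode carry the post-change value. Person-time is conserved
exactly: the episode lengths of a child always sum to
`min(death age, censoring age, 730)`, and the test suite asserts this
identity without tolerance.

Three expansion schemes exist: maternal vital status only (the main model),
adding time-dependent breastfeeding cessation (the weaning model, fitted
among ever-breastfed children), and the joint four-category classification
of current breastfeeding by current maternal 3-drug ART (A = neither,
B = ART only, C = breastfeeding only, D = both).

## The shared gamma-frailty Cox model

Mortality is modelled on the hazard scale as

$$ h_{is}(t) = u_s\, h_0(t)\, \exp\{x_{is}(t)^\top \beta\}, $$

where $u_s$ is a study-level frailty shared by all children of study $s$,
$h_0$ a nonparametric baseline hazard, and $x_{is}(t)$ the (possibly
time-dependent) covariate vector. The frailty is Gamma with mean 1 and
variance $\theta$; $\theta$ measures between-study heterogeneity on the
hazard scale. The gamma family was chosen because it gives a closed-form
E-step and — crucially for the attributable-fraction procedure — a
closed-form marginal survival function.

`fit_frailty_cox()` estimates $(\beta, \theta, u, H_0)$ by
expectation-maximization:

1. **M-step.** Given frailties, maximize the Breslow partial likelihood with
   $\log u_{s(i)}$ as offsets, by Newton–Raphson with analytic score and
   information and step-halving. Ties are handled by the Breslow
   approximation. The baseline cumulative hazard is the Breslow step
   function $dH_0(t_k) = d_k / \sum_{j \in R(t_k)} u_{s(j)} e^{x_j^\top\beta}$.
2. **$\theta$-step.** Given each cluster's event count $D_s$ and cumulative
   hazard load $\Lambda_s = \sum_{j\in s} \int e^{x_j^\top\beta}\,dH_0$,
   maximize the gamma marginal-likelihood profile
   $\sum_s \{ D_s\log\theta + \log\Gamma(1/\theta + D_s) -
   \log\Gamma(1/\theta) - (1/\theta + D_s)\log(1+\theta\Lambda_s)\}$
   by one-dimensional search on $[10^{-8}, 20]$, with the $\theta = 0$
   boundary checked explicitly.
3. **E-step.** Replace each frailty by its posterior mean
   $\hat u_s = (1/\theta + D_s)/(1/\theta + \Lambda_s)$.

Iteration stops when the largest change in $\beta$ or $\theta$ falls below
`1e-6` (configurable in `frailty_control()`), or after 200 cycles with a
warning. Standard errors come from the observed information of the
penalized likelihood *jointly* in $(\beta, \log u)$ — the frailty block
carries the gamma penalty $u_s/\theta$ on its diagonal — so that
between-study uncertainty propagates into study-level covariates such as
region. With $\theta$ fixed at 0 the procedure reduces exactly to an
ordinary Cox model; the test suite verifies machine-precision agreement of
coefficients, standard errors and baseline hazard with the `survival`
package on a single-study fixture, and agreement within `1e-3` (β) /
`1e-2` (θ) with `survival`'s penalized gamma-frailty fitter on a
multi-study fixture — an independent implementation, not used at runtime.

Numerical safeguards: coefficients are capped at ±15 on the log-hazard
scale, which converts separation (a level with no events) into a warning
plus an enormous standard error rather than a failure; the information
matrix receives an escalating ridge only if a solve fails.

**Covariate handling.** All covariates are categorical with declared
reference levels (`model_spec()`); `"unknown"` levels are ordinary
categories. `univariate_screen()` fits one single-covariate frailty model
per candidate and reports per-covariate joint Wald tests;
`stepwise_descending_select()` starts from the candidates passing the 0.1
univariate screen plus the always-kept maternal-ARV covariate, forces
region and maternal CD4 into every model, and repeatedly drops the least
significant eligible covariate (joint Wald p ≥ 0.05) as a block — an
`"unknown"` level never leaves the model separately from its covariate.
Wald tests were chosen because the marginal likelihood ratio is expensive
under the EM scheme and the selection rule only needs a ranking.

## Prediction and attributable fractions

For a child with covariate path $x_i(\cdot)$ the conditional cumulative
hazard is $H_i(t) = \int_0^t e^{x_i(s)^\top\beta}\, dH_0(s)$, accumulated
over the path's episodes against the fitted Breslow baseline. Marginal
survival integrates the frailty analytically via the gamma Laplace
transform:

$$ S_i(t) = (1 + \theta H_i(t))^{-1/\theta}, $$

with the continuous limit $e^{-H_i(t)}$ used below $\theta = 10^{-8}$.
Marginal (population-averaged) prediction is the default because the aAF is
a population quantity; `type = "conditional"` uses the child's own study
frailty instead.

`expected_deaths()` computes $D(t) = N - \sum_i S_i(t)$ with every child's
covariate path extended to the horizon — *past actual censoring, holding
the last observed category* — because $D(t)$ is a full-population
expectation, not a description of observed follow-up. `compute_aaf()` then
evaluates

$$ \mathrm{aAF}(t) = \frac{D(t) - D_{cf}(t)}{D(t)}, $$

where $D_{cf}$ repeats the computation after assigning every child the
nonexposed level of the factor(s) while all other covariates keep their
factual values. The default factor set (`aaf_factors()`) mirrors the four
risk factors of interest with these counterfactuals:

* low birth weight → everyone ≥ 2500 g;
* never breastfed → everyone breastfed, previously never-breastfed children
  receiving the default path (birth to 183 days, or maternal death if
  earlier) — the same rule used for unknown weaning;
* maternal ARV category → everyone on **ART for life**. This is deliberately
  *not* the model's reference level (no ARVs): the factor quantified is
  "mother not on lifelong ART", so its nonexposed state is the protective
  extreme;
* maternal death → every mother alive throughout follow-up;
* combined → all four reassignments at once.

The decomposition $D = D_{cf} + \text{attributable deaths}$ holds exactly,
a factor with a zero coefficient or zero prevalence contributes exactly
zero, and the aAF is invariant to duplicating the cohort; all three are
asserted in tests. At the true generating parameters the aAF reproduces the
closed-form attributable fraction of a binary factor under constant hazards
to machine precision.

`bootstrap_aaf()` attaches percentile 95% intervals by resampling children
with replacement *within study strata* (study sizes preserved) and re-running
the entire pipeline — episode split, frailty fit, aAF — on each resample.
Children rather than studies are the resampling unit: with ~20 clusters,
study-level resampling would give far too few distinct resamples for stable
percentile intervals. The default is `B = 500`; resamples without events are
skipped and counted, and more than 20% skips aborts. Bootstrap refits
warm-start from the full-data estimates with a slightly relaxed tolerance
(`1e-4`) and no standard errors, which changes third-decimal details only
but cuts the cost several-fold.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` define the generating model used for
validation: per-study gamma frailties; a piecewise-constant baseline hazard
of death by age; multiplicative covariate effects, including the
time-dependent indicators for maternal death, current breastfeeding and
current maternal 3-drug ART; independent maternal-death (exponential),
weaning (log-normal) and ART-window processes; and censoring from
study-level administrative caps plus exponential dropout. Death ages are
drawn by piecewise-exponential inversion on the refinement of baseline
breakpoints and per-child change-points, so the generating hazard is exactly
the model's hazard — no discretization. Maternal death terminates
breastfeeding at the same change-point, mirroring the imputation rule used
on real data.

The defaults describe the pooled population the package targets: 20 studies
of ~960 children; low birth weight 12.1%, never breastfed 30.2%, maternal
ARV mix 22.8 / 61.4 / 11.7 / 4.0%, antenatal CD4 > 350 in 57.9%; hazard
ratios 2.9 (low birth weight), 2.5 (never breastfed), 11.1 (maternal death,
time-dependent), 0.5 (ART for life), 0.05 (Asia vs Africa), 1.43 (CD4 <
350); frailty variance 0.25; a declining baseline hazard calibrated so
cumulative mortality reaches roughly 2% by 3 months and 5–6% by 24 months;
maternal mortality ~1.6% by 24 months; weaning ages log-normal with median
181 days; administrative caps of 365/550/730 days and ~14% dropout by 730
days. Optional masks emulate incomplete source data (unknown feeding
status, unknown weaning dates, missing ARV information) for pipeline tests.

What the generator does **not** emulate: study-specific enrollment
calendars and eligibility, calendar-time trends in ART availability,
correlation between covariates (covariates are independent given study),
competing risks, or informative censoring. Passing recovery tests on this
generator therefore demonstrates the estimator's correctness under the
model's own assumptions — not robustness to their violation in real data.

`true_attributable_fraction()` supplies the generator's ground-truth AF: it
draws a large quasi-population of covariate paths, evaluates each path's
survival *exactly* (piecewise-constant hazard integration plus the gamma
closed form), and contrasts factual with counterfactual assignments using
common random numbers. Monte-Carlo noise therefore enters only through the
covariate distribution, and the reported `mc_se` is the delta-method
standard error of the ratio.

## Validation experiments and their sizes

The acceptance-level suite (in `tests/testthat/test-acceptance.R`, with the
same computations re-run from scratch by `scripts/acceptance.R`) covers:

* exact reproduction of printed-count arithmetic (per-study crude death
  proportions, post-maternal-death mortality, cohort composition
  percentages);
* machine-precision reduction to an ordinary Cox fit at $\theta = 0$ and the
  closed-form AF identity;
* hazard-ratio CI coverage over 100 replicate cohorts of 20 studies × 250
  children at the default generating effects, requiring 88–99 of 100
  nominal-95% intervals to cover each true hazard ratio;
* aAF recovery on one 8 000-child cohort against the analytic generator
  truth, within three bootstrap standard errors (B = 40);
* bootstrap CI coverage for the aAF over 100 replicates of a 1 000-child,
  10-study, one-factor design with B = 100, again within the 88–99 band;
* exact conservation and invariance identities.

The replicate counts and cohort sizes are the package's own choices,
balancing the Monte-Carlo resolution of a coverage probability (a binomial
with n = 100 resolves ~3 percentage points) against the cost of refitting
a frailty model a few thousand times; larger designs change the bands'
width, not their meaning.

## Known limitations

* The EM's convergence slows as $\hat\theta$ grows; very heterogeneous
  small-cluster designs can hit the 200-iteration cap at the `1e-6`
  tolerance (a warning, with estimates typically within `1e-5` of the
  fixed point).
* Standard errors treat $\hat\theta$ as fixed at its maximizer; this is the
  usual penalized-likelihood convention and matches the reference
  implementation, but slightly understates uncertainty for very few
  clusters.
* No left truncation, recurrent events, competing risks or
  proportional-hazards diagnostics; the terminal event is death and entry
  is birth, by design.
* The aAF procedure attributes deaths under the fitted proportional-hazards
  model; it is a model-based counterfactual, not a causal estimate robust
  to confounding beyond the adjustment set.
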