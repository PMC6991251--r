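---
title: "Per-protocol target trial emulation with stabilized IPW and marginal structural models"
author: "ipwmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-protocol target trial emulation with stabilized IPW and marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ipwmsm)
```

## The estimation problem

`ipwmsm` emulates the randomized trial one would ideally run to compare two
drug regimens — here labelled **HI** (reference: single-class therapy) and
**AI** (comparator: the newer class, with or without the reference class) —
using only longitudinal dispensing records, enrollment spans, dated events
and covariates. Assignment happens at the *index date* (the first fill,
day 0), and the estimand is *per-protocol*: the counterfactual cumulative
risk of the outcome had everyone initiated and **continuously adhered** to
one regimen. Participants are right-censored when they deviate (supply
gap, class switch, no refill), when outcome capture becomes unreliable
(insurance disenrollment, pregnancy), at death (for nonfatal outcomes),
and at the administrative end of the study.

Follow-up is discretized into 90-day quarters, `t = 0, 1, ..., 9` (2.5
years). Writing `Y(t)` for the event indicator in quarter `t`, `a` for the
regimen, `V` for baseline covariates and `L(t)` for time-varying
covariates, the package estimates the discrete-time counterfactual hazards
`h(t, a) = P(Y(t) = 1 | at risk at t; regimen a forced)` by weighting the
observed person-quarters with stabilized inverse-probability weights, then
fits two logistic marginal structural models (MSMs):

* a **saturated** MSM — one parameter per `(t, a)` cell, whose weighted
  MLE has the closed form `h(t, a) = sum(w Y) / sum(w)` over the at-risk
  rows of the cell. Survival follows by the product-limit identity
  `S_a(t) = prod_{k <= t} (1 - h(k, a))`, and the headline risk
  differences are `RD(t) = [1 - S_AI(t)] - [1 - S_HI(t)]` at `t = 4`
  (1 year) and `t = 8` (2 years), with HI as the reference regimen;
* a **proportional-hazards** MSM — quarter indicators plus a single
  regimen coefficient `beta`; `exp(beta)` is a discrete-time odds ratio
  that approximates the hazard ratio when quarterly hazards are small
  (2–3% here) and is reported as the hazard ratio.

The area-between-curves test assesses `T = sum_{t=1..10} RD(t) = 0` with
a two-tailed p-value from a participant-level bootstrap,
`p = 2 * pnorm(-|T| / SE_boot)`.

## Exposure and censoring rules

A fill is assumed to supply at most `supply_days` (180 by default; 365 as
a sensitivity setting) and any remaining supply is discarded at the next
fill (no stockpiling). The regimen-defining class is the comparator class
for AI participants (reference-class fills neither sustain nor violate an
AI regimen) and the reference class for HI participants, for whom any
comparator-class fill is a violation. A supply lapse is classified as a
`gap` when any insulin fill occurs later, `no_fill` when none does, and —
for AI participants whose reference-class supply continues past the lapse
— a `switch`. `other`-class fills (inhaled/animal preparations) always
violate the regimen. Disenrollment is a coverage gap of more than 90
days, dated at the last covered day before the gap (exposure and outcome
capture are unreliable once coverage lapses).

Quarters are 0-based half-open windows `[90t, 90(t+1))`. The terminal
row of follow-up is the last quarter with positive at-risk time; a
censoring day falling exactly on a quarter boundary therefore terminates
follow-up at the end of the preceding quarter. When an event and a
censoring day fall in the same quarter the event wins if its day is on or
before the censoring day; among same-day censoring causes the fixed
precedence is event > death > disenrollment > switch > gap/no fill >
pregnancy > administrative end. These tie rules are conventions of this
implementation — observational databases rarely pin them down — and they
are exercised directly by the unit tests.

**Risk sets.** Terminal censoring rows carry `at_risk = FALSE` and are
excluded from hazard estimation; the weights (below) make the remaining
rows representative. Administrative-end rows whose censoring day sits
exactly on the quarter boundary stay in the risk set: their final quarter
was fully observed, and dropping them would empty the last-quarter
stratum by construction.

## Weights

For each censoring cause `c` (regimen interruption, then disenrollment,
then — for nonfatal outcomes — death, each conditional on remaining
uncensored by the prior causes) a pooled logistic *denominator* model
`P(uncensored by c in quarter t | arm, t, V, L(t))` is fit with quarter
indicator terms, and a *numerator* model saturated in `(arm, t)` — fit in
closed form as cell means, the MLE of the saturated logistic model.
Numerators deliberately exclude baseline covariates (a flagged choice;
the covariate-conditional numerator is available through
`fit_mechanism()` if wanted). The treatment mechanism contributes
`P(A = a)/P(A = a | V)` at the index date. The stabilized weight is the
running product

`sw(t) = sw(t-1) * prod_c [P_num,c(uncensored at t) / P_den,c(uncensored at t)]`,

truncated from above at 20 (no lower bound). Probabilities are clipped to
`[1e-6, 1 - 1e-6]`; denominator probabilities at the clipping floor are
counted and surfaced as a positivity warning. Pregnancy censoring is
treated as noninformative (no weight model): it ends well under 1% of
follow-up in the motivating setting, and modelling it would add a
mechanism with almost no events.

Quarter enters all pooled models as indicators rather than a trend,
matching the saturated-in-time spirit of the MSMs.

## Covariate-set selection (discrete Super Learner)

`super_learner_select()` implements the *discrete* Super Learner: V-fold
cross-validation over candidate logistic covariate adjustment sets, with
folds partitioning participants (never splitting one participant's rows),
mean held-out negative Bernoulli log-likelihood as the loss, ties broken
by candidate order, and the winner refit on the full data. A
convex-combination learner is deliberately out of scope: selecting the
best-predicting adjustment set is the use case here, and it keeps the
selection auditable (`sl_report`). When the pipeline uses Super Learner
selection, the selection is performed once on the observed data and the
bootstrap conditions on the selected sets — re-running selection inside
every replicate would multiply the cost several-hundred-fold for a
second-order refinement.

## Inference

Confidence intervals are 95% percentile intervals from a nonparametric
bootstrap that resamples *participants* and re-runs the entire pipeline —
propensity fits, weight assembly, both MSMs — on every replicate
(default `B = 500`). Replicates are drawn as participant multiplicities,
which is algebraically identical to materializing the resampled rows for
every estimator used (all are weighted estimating equations) and is what
makes the re-runs affordable; the per-replicate fits warm-start from the
full-data coefficients and run to convergence. A replicate with an empty
`(t, a)` stratum is dropped and counted; more than 20% dropped is an
error directing the user to the proportional model. The proportional MSM
also reports a model-based (inverse Fisher information) standard error
for `beta`, which ignores the weight-estimation step and is therefore
approximate; the bootstrap is the reference method. The area test's
p-value uses the normal approximation on the bootstrap SE by default,
with a percentile-based p behind a flag.

All weighted logistic fits share one Fisher-scoring core, written against
the design matrix with the quarter-indicator block solved by Schur
complement, and a compiled (C++) implementation used on the bootstrap hot
path; both are asserted against `stats::glm` to coefficient precision
`1e-7` in the test suite. Strata losing all response variation under a
resample are handled by clamping their intercepts at `|a| = 18`
(probabilities within `1e-8` of the boundary), which leaves every other
coefficient at full precision.

## The synthetic-data generator

Because per-protocol EHR cohorts cannot be shared, the package ships a
generator whose mechanism contains exactly the structures the analysis
claims to handle: baseline-confounded treatment choice (logistic in
`V`), quarterly refill/switch/stop behaviour, informative disenrollment,
an AR(1) time-varying covariate driving both censoring and the outcome,
and discrete-time outcome hazards. `true_counterfactual_risks()` is the
oracle: it forces a regimen, disables every censoring process, and
averages per-participant conditional cumulative risks over Monte-Carlo
draws of the covariate paths (a Rao-Blackwellized estimate — identical
in expectation to drawing events, with smaller Monte-Carlo error).

Within a simulated quarter the order is: refill decisions, then
disenrollment, then death, then the nonfatal outcome; death always
precedes the outcome and the two never co-occur in one quarter. Once a
censoring process fires, outcome capture stops from the terminal quarter
onward — events after therapy interruption or coverage loss are not
observed, which is precisely the capture problem per-protocol censoring
models. This makes the generator's law exactly consistent with the
builder's risk-set convention: the quarter-`t` censoring status is
independent of the quarter-`t` event given `(arm, V, L(t))`, so the IPW
pipeline targets the oracle without within-quarter timing bias.
Dispensings are emitted at quarter starts (which suffices to exercise the
180-day rule); a participant who stops refilling resumes three quarters
later with probability `resume_prob`, producing a censorable `gap`, and
otherwise never fills again (`no_fill`).

Preset parameters were fixed once, at design time, to give realistic
study conditions: ~15% comparator initiation; a per-quarter
stop-refilling probability of 8% so that roughly 57% of participants
interrupt therapy within 10 quarters (interruption should dominate the
censoring mix, as it does in per-protocol analyses of insulin
initiation); `resume_prob = 0.7` (gaps outnumber permanent
discontinuations roughly 2:1); 1.5% quarterly switching; 2% quarterly
disenrollment; and a 2% quarterly outcome hazard. The `confounded`
scenario's coefficients (0.8 on treatment, 0.35 on the outcome, 0.3–0.4
on censoring, all per SD) were chosen by a design-time calibration to
represent *strong* confounding — the crude comparator-arm risk is biased
upward by ~0.03–0.05 by 10 quarters — and have not been revisited since.
The `proportional_effect` scenario puts `log(1.5)` on the outcome and no
covariate effects on the outcome at all, so the marginal discrete-time
odds ratio is exactly 1.5 (no non-collapsibility gap) while the
covariate-driven treatment and censoring still exercise the weighting.

What the generator does **not** emulate: realistic marginal covariate
distributions, coding systems, within-quarter dispensing dates, seasonal
or site structure, and informative pregnancy censoring. Passing the test
battery therefore demonstrates that the estimator recovers known truths
under the assumed structure (sequential exchangeability given `V` and
`L(t)`, correct model forms, positivity) — not that those assumptions
hold in any particular real database.

## Validation battery and problem sizes

The test suite runs, among others: exact accounting checks against a
published follow-up table; exact (1e-10) equivalence of the unit-weight
saturated MSM with the discrete Kaplan–Meier estimator; hazard-ratio
recovery of 1.5 across 20 seeded cohorts of n = 20,000 (Wald CI coverage
at least 17/20); counterfactual-risk recovery on the confounded scenario,
|IPW − oracle| < 0.01 at every quarter averaged over 10 cohorts of
n = 20,000 while the crude estimator's bias exceeds 0.01; type-I error of
the area test within [0.03, 0.08] over 200 null cohorts (n = 5,000,
B = 200); weight stabilization (per-quarter mean in [0.9, 1.1]) and
truncation by construction; and supply-rule monotonicity (switching 180
to 365 days never shortens follow-up). Bootstrap coverage is additionally
spot-checked at n = 2,000, B = 100 over 20 replicates. These sizes are
the package's standard validation conditions; all are configurable.

## Known limitations

* The hazard ratio is a discrete-time odds ratio; with large quarterly
  hazards it drifts from the true hazard ratio.
* Truncation at 20 trades a small downward bias in late-quarter risks for
  variance; with strong positivity violations the truncated-weight count
  in the diagnostics is the warning sign.
* Model-based SEs for `beta` ignore weight estimation; use the bootstrap.
* One time-varying covariate is supported in the generator (the builder
  and weighting accept any number).
* Sequential exchangeability, correct model specification and positivity
  are assumptions; no diagnostic in this package can verify them on real
  data.
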