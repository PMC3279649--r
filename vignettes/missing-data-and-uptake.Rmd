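---
title: "Handling missing outcomes and incomplete intervention uptake"
author: "trialmnar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing outcomes and incomplete intervention uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmnar)
```

## The problem

Online trials can randomise thousands of participants cheaply, but often
observe the primary outcome for fewer than half of them and deliver the
intervention to only some of those allocated to it. Both problems bite at
once: a complete-case estimate may be biased by selective response, and an
intention-to-treat estimate dilutes whatever effect the intervention has
among the people who actually used it. This package implements a sequence
of analyses for a two-arm trial with outcomes at two follow-up times
(analysed as `log(units/week + 1)`, so arm contrasts exponentiate to
ratios of geometric means), complete baseline covariates, a record of
which contact attempt elicited each outcome, and server-logged website
use.

The sequence moves through progressively weaker assumptions:

1. **Covariate-dependent MCAR** — complete-case OLS.
2. **MAR given the other outcome** — GEE and a bivariate normal mixed
   model use responders' first-follow-up outcomes to correct dropout that
   depends on them.
3. **MAR given website use** — multiple imputation with compliance
   auxiliaries (MI2) additionally allows response to depend on how much
   of the website a participant used.
4. **MNAR, user-specified** — a pattern-mixture model indexed by
   arm-specific mean offsets between unobserved and observed outcomes.
5. **MNAR, data-estimated** — a selection model that identifies the
   outcome–response association from the repeated email attempts.
6. **Causal uptake effects** — a structural mean model with randomised
   arm as the instrument, under the exclusion restriction, with IPW, ATR
   and MI corrections for the missing outcomes.

## Models and estimation choices

### Complete cases and the joint MAR models

The estimand throughout is the arm coefficient `beta` in
`E[y2 | z, x] = alpha + beta z + gamma' x`. The GEE fit stacks each
participant's observed outcomes, allows every coefficient to differ by
follow-up time (time-by-covariate interactions), and uses an unstructured
working correlation — identical to exchangeable with two times — with a
common working variance; standard errors are sandwich-robust with an
`n/(n - p)` small-sample factor, so misspecified variances cost nothing
asymptotically. The mixed model adds multivariate normality with an
unstructured covariance allowed to differ by arm (heavy drinkers' variance
need not match controls'), estimated by REML. Rather than a general
mixed-model optimiser, the implementation profiles the mean coefficients
out by GLS and optimises only the log-Cholesky factors of the per-arm
covariances; with two outcomes that is six parameters, and the profiled
surface is well behaved. Participants with neither outcome observed
contribute nothing to either fit. Website-use counts can be stacked as
extra normal responses (after `log(1 + count)`, rescaled to the outcome
SD so the equal-variance working model stays sensible), which is how the
joint models admit compliance information.

### Multiple imputation

Imputation is by chained equations, separately per arm (so every
outcome–covariate association may differ by arm), with the other outcome
and all baselines as predictors — MI1 — or additionally the four
`log(1 + count)` website-use transforms — MI2. Parameters are drawn from
the standard Bayesian posterior (scaled inverse-chi-square variance,
conditional normal coefficients), and each missing cell receives the
observed value of one of the `pmm_k = 5` donors with closest predicted
mean (type-1 predictive mean matching; the donor count is a conventional
choice, not an estimate, and is configurable). Ten chained cycles per
imputation are far more than two incomplete variables need; `M = 50`
imputations by default. Analyses of the completed data are pooled by
Rubin's rules with Barnard–Rubin degrees of freedom. Covariates enter the
imputation model even when the analysis model is unadjusted: imputation
should always condition on at least as much as the analysis.

### Pattern-mixture sensitivity analysis

MNAR is explored by asserting that non-responders' mean outcome differs
from responders' by `delta0` (control) and `delta1` (intervention) on the
log scale — parameters the data cannot identify, chosen by judgement. The
fit decomposes the target coefficients into a complete-case part and an
offset part: `theta_ADD` is the OLS coefficient vector of the constructed
variable `delta_z (1 - r2)` regressed on the design over *all* randomised
participants, which is exactly what makes the fitted mean marginal over
response patterns, and the two parts are independent so their variances
add. For unadjusted analyses this collapses to the closed form
`exp(beta_CC + delta1 pi1 - delta0 pi0)` in the arm-specific missingness
fractions, which the package also exposes as an aggregate-data calculator
(usable straight from a published wave table). The default grid spans
`exp(delta)` of 0.5–1.75 common to both arms and 0.5–1.5 in a single arm,
with the common-1.5 and single-arm-1.25 settings flagged as the moderate
analyses; single-arm offsets move the estimate far more than common ones,
which is the central caution this analysis is designed to surface. No
adjusted-model aggregate shortcut is provided: covariate imbalance between
responders breaks the closed form, so adjusted sensitivity analysis
requires record-level data.

### The repeated-attempts selection model

If response to the *k*-th contact attempt follows
`logit p_k(y) = lambda_k + eta' u + delta_z y`, with the outcome
association `delta_z` common across attempts but the intercepts free,
then `delta_z` is identified: late responders stand in for
never-responders. The observed-data likelihood multiplies the normal
outcome density by the sequential attempt outcomes; never-responders
contribute an integral over the unobserved outcome, evaluated by
Gauss–Hermite quadrature (40 nodes by default; doubling the nodes moves
the log-likelihood by under 1e-8 at realistic sizes, and the integrand is
computed by log-sum-exp so extreme parameter proposals cannot underflow
it). Estimation starts from the exactly decoupled `delta = 0` solution —
a responders-only regression plus an attempt-level logistic fit, which is
also the module's principal correctness oracle — and maximises the joint
likelihood by BFGS with numerical derivatives; standard errors come from
the inverse observed information. Covariate effects on response are held
common across attempts and arms. Early refusals truncate the
never-responder product at the attempts actually made. Conditional
likelihood estimation, which can fail to converge, is deliberately not
implemented; an inverse-probability-weight export from the fitted
response model exists but is flagged experimental because naive weighted
analyses ignore the substantial uncertainty in estimated weights.

### Structural mean models

The causal model is that allocation's effect is proportional to
compliance `d`: binary (complier = more than one login *or* more than 10
pages in month one — a deliberately low cut-off, since the exclusion
restriction must be credible for everyone labelled a non-complier) or
quantitative (pages in month one, capped at 300 because additional use
beyond that is not expected to add benefit, per 100 pages). Control-arm
website use is ignored: the information-only control site is taken to
have no causal effect, which avoids a second, poorly identified causal
parameter. Estimation is just-identified IV (arm instruments compliance,
covariates exogenous), so the binary no-covariate case reduces exactly to
the Wald ratio and perfect compliance reduces exactly to ITT — both are
tested identities. For missing outcomes: IPW weights intervention-arm
complete cases by the ratio of fitted response probabilities given
covariates to those given covariates and compliance (stabilised weights;
control weights are 1 because compliance does not vary there — a
documented asymmetry, not an oversight), with fitted probabilities
floored at 0.01; ATR regresses outcome on compliance, the stage-1
compliance residual and covariates, algebraically identical to IV on
complete data, with its second-stage SE flagged as a possible
underestimate and a seeded bootstrap available; MI reuses the MI2
imputations and pools the IV estimates.

## The synthetic-trial generator

`default_dyd_config()` encodes the study conditions the package is
validated under: arms of 1880/1866; baseline covariates matching the
motivating trial's summary table (age 37.5 (10.9), 45% male, AUDIT-C 8.4
(2.1), EQ-5D 0.85 (0.18), confidence 2.8 (1.2), baseline log-outcome 3.80
(0.83)); a trivariate normal outcome structure reproducing correlations
0.45 (baseline–1 month), 0.41 (baseline–3 months) and 0.53 (1–3 months)
with 1-month mean 3.30 and 3-month control mean 3.18; website use drawn
from a login-category mixture with negative-binomial page counts
calibrated to 78% compliers and ~65 intervention-arm pages (the published
summaries give only means, SDs and login categories, so the family is a
modelling choice and configurable); and a three-attempt sequential
response process calibrated to 38%/46% three-month response, with a
separate 1-month response model at 50%/60% that permits non-monotone
patterns. The default causal effect is 0.1 per 100 capped pages — chosen
once so that the implied ITT effect (~0.06 on the log scale) sits in the
range the motivating trial reported — applied at 3 months only, since the
published 1-month means were identical across arms. All randomness flows
from one master seed through fixed per-stage seeds, so enabling a later
stage (e.g. refusals) never perturbs earlier draws.

Three hooks exist purely to make estimator failure modes testable, all
off by default: `delta_r` makes attempt-level response depend on the
realised 3-month outcome (MNAR; zero gives MAR by construction),
`eta_pages`/`eta_d` make it depend on website use, and `engagement_sd`
adds a latent engagement propensity that raises both page counts (in both
arms) and the 3-month outcome, creating a compliance–outcome correlation
that randomisation cannot remove — the scenario in which complete-case IV
fails but IPW and ATR do not.

What passing tests on these data do **not** show: the generator's
outcomes are (conditionally) normal and its response process is exactly
the selection model's form, so the validation demonstrates correctness of
the estimators under their own assumptions, not robustness to the
skewness, digit preference and hard zeros of real consumption data. The
predictive-mean-matching imputation exists precisely because real
outcomes are not normal, but the simulations cannot certify that
advantage.

## Numerical notes and limitations

* GEE iterations stop when the relative coefficient change is below 1e-8
  (cap 200); the mixed-model REML surface is optimised to reltol 1e-12;
  the selection-model likelihood to reltol 1e-10 by default.
* Variables with no observed rows (e.g. a follow-up entirely missing)
  drop out of the estimating equations; their coefficients are reported
  as unidentified rather than invented, and the remaining fits reduce to
  the correct sub-model (tested).
* The mixed model's covariance is parameterised by log-Cholesky factors,
  so iterates cannot leave the positive-definite cone; a singular
  proposal is penalised, not fatal.
* Imputation determinism: per-(imputation, arm) seeds mean the control
  arm's imputations are invariant to any permutation of intervention-arm
  records (tested), and a fixed seed reproduces the imputation set
  exactly.
* The attempts model conditions on baselines only (not the 1-month
  outcome) in its adjusted form; extending the selection model to the
  repeated-measures structure is out of scope.
* Simulation-based test sizes (e.g. 200 replicates of 1000 per arm for
  parameter recovery, with MI at M = 5 and 20 quadrature nodes inside the
  loops) are the package's own trade-off between Monte-Carlo precision
  and a test suite that runs in minutes; the defaults users see
  (M = 50, 40 nodes) are more conservative.
* Arm-level weights for control-arm missingness in the IPW structural
  mean model are intentionally 1; if control response depended on control
  website use, that dependence would be uncorrected (documented
  limitation of the stabilised-weight construction).
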