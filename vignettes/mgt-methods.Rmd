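---
title: "Simulating and analyzing the Maastricht Gambling Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing the Maastricht Gambling Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgtkit)
```

## The task and its dependent variables

The Maastricht Gambling Task (MGT) is a computerized binary lottery. Each
trial shows six boxes, of which 1 to 5 are pink and the rest blue; each color
carries a reward drawn from {5, 25, 50, 75, 100} points, and a token is
hidden uniformly at random behind one of the six boxes. The participant bets
on a color: a hit pays that color's reward, a miss pays nothing. The full
space of configurations is 5 pink-box counts x 5 pink rewards x 5 blue
rewards = 125 trial types, each presented twice per run (250 trials), with
one run per stimulation condition and three conditions per session.

Choosing a color with `k` boxes and reward `x` yields `x` with probability
`p = k/6`. The risk taken on that choice is the standard deviation of this
two-point payoff distribution,

$$\mathrm{Var}(X) = p\,(x - E[X])^2 + (1-p)\,(0 - E[X])^2,
  \qquad \mathrm{Risk} = \sqrt{\mathrm{Var}(X)} = x\sqrt{p(1-p)},$$

the primary dependent variable. Two companions are *choice optimality* (CO),
a binary indicator that the chosen color had the higher expected value, and
*response time* (RT) in seconds. All three are averaged over the two
presentations of each trial type within a run, so the unit of analysis is
one participant x session x stimulation x trial type (125 rows per run; CO
averages onto {0, 0.5, 1}).

```{r}
types <- enumerate_trial_types()
nrow(types)
lottery_stats(types[types$trial_code == "P1_100_005", ], "pink")
```

Two numerical edge cases deserve note. First, the enumerated space contains
exact expected-value ties (for instance 25 x 1/6 = 5 x 5/6); no "higher EV"
option exists there, so either choice scores CO = 1, and `ev_tie()` flags
those types for sensitivity analyses that prefer to exclude them. Second,
response-time outliers are removed with 1.5 x IQR fences whose quartiles use
linear interpolation between order statistics (`quantile()` type 7): removal
counts depend on the interpolation rule, so the rule is fixed and the filter
reports an audit count. The filter runs once over the fully assembled
averaged-RT table by default (`scope = "global"`), because a single removal
count over all runs is the natural audit unit; per-participant scope is a
configuration option, and neither choice is asserted to be what any
particular historical analysis did.

## The study design being emulated

The synthetic cohort reproduces a two-session, double-blinded
probiotics/placebo design crossed with three theta-burst stimulation
conditions (sham, SPL, VMPFC) per session: 60 participants (31 placebo, 29
probiotics, 36 labeled women), 6 runs each, and 5 runs from distinct
participants lost to recording failures. The bookkeeping is exact: 60 x 6
runs x 125 types = 45,000 planned averaged observations, minus 5 x 125 for
the dropped runs = 44,375.

```{r, eval = FALSE}
scored <- score_trials(simulate_cohort(cohort_design(), seed = 1))
nrow(scored) # 44375
```

## Two simulation routes with known ground truth

**Agent route.** The task specifies no choice process, so the generator uses
an explicit stand-in: a mean-variance softmax agent with utility
`U = ev + b * risk` per color and `P(pink) = plogis(lambda * (U_pink -
U_blue))`. `b` (risk appetite, utility points per risk point) and `lambda`
(inverse temperature) are population parameters with between-participant
heterogeneity; response times are lognormal with additive condition effects
on the log scale (a session-2 speed-up, a probiotics-by-session slow-down),
chosen so simulated data move in the directions the design anticipates.
These defaults are simulator configuration — they make the synthetic data
MGT-shaped, and no magnitude is claimed to reproduce any particular
empirical estimate. This route exercises the full task engine and scoring
path and is what the cardinality tests run on.

**Generative-model route.** For testing estimation, `simulate_lmm_dataset()`
draws trial-type-averaged risk directly from the mixed model that the
analysis fits: treatment-coded fixed effects of session x group x
stimulation (reference cell: placebo, session 1, sham) plus a participant
random intercept (variance 1.56), a trial-type-within-participant random
intercept (192.99, one draw per participant x trial code shared across that
participant's six runs), and residual noise (16.88). The default fixed
effects place the reference-cell mean at 25.33 risk points with a
session-2 x probiotics interaction of 0.27 — the coefficient the design's
critical hypothesis lives on. Those variance components imply an intraclass
correlation of (192.99 + 1.56) / (192.99 + 1.56 + 16.88) = 0.92: almost all
variance in risk-taking sits between trial types and between people, not in
the experimental factors, which is exactly why the nested random-intercept
structure matters.

What the generator does *not* emulate: learning or habituation across
repetitions (repetition labels are assigned but drive no effect by default),
serial dependence within a run, RT-risk coupling, heart-rate time series, or
any physiological stimulation mechanism. Passing tests therefore validate
the pipeline's arithmetic and its statistical calibration under the stated
generative model, not behavioral realism beyond it.

## The mixed models

`fit_lmm()` fits

```
risk ~ session * group * stimulation + (1 | participant:trial_code) + (1 | participant)
```

by maximum likelihood via `lme4::lmer()`, mirroring the model used for all
three behavioral outcomes (CO is modeled linearly on its {0, 0.5, 1} scale,
not with a logistic link). `fit_repetition_model()` adds the block-order
factor fully crossed up to the four-way interaction.
`fit_hr_lmm()`/`fit_scale_lmm()` use REML with a participant-only intercept,
the specification used for heart rate (`hr ~ session + group + stimulation +
time + session:group`) and the control scales (`response ~ session *
group`).

Numerical policy: lme4's default optimizer, with one bobyqa retry (up to
1e5 evaluations) if the first fit flags convergence trouble; singular fits —
a variance component estimated at zero, routine in reduced designs where the
participant variance is tiny — are recorded in the fit's notes but are not
failures. Non-convergence after the retry is reported in the `converged`
flag, never swallowed. Inference is asymptotic: Wald z statistics and
normal-theory confidence intervals, defensible at the 4 x 10^4 observations
the design produces, and matching the use of z ratios in the contrast
tables. The ICC is the variance ratio above; marginal and conditional R^2
follow the Nakagawa & Schielzeth variance decomposition.

`contrast_analysis()` builds estimated marginal means on the session x
group x stimulation grid via emmeans and reports the study's planned family:
session-2 minus session-1 within each group x stimulation cell, probiotics
minus placebo within each stimulation x session cell, and the consecutive
stimulation contrasts (SPL - sham, VMPFC - SPL) within each group x session
cell — 20 rows, Bonferroni-adjusted within whatever family one call
requests (`p_adj = min(1, m p)`). Standardized coefficients divide by the
response SD; predictor contrasts are left unstandardized, and the method is
stamped into the output since more than one convention exists.

## Parameter recovery as the verification surface

`recovery_experiment()` closes the loop: simulate from the generative model,
refit, and summarize bias, RMSE, CI coverage and rejection rate per
coefficient. The packaged experiments use a reduced design — 15 participants
per group and 25 trial types (4,500 observations per replicate) — with 100
replicates for recovery of the 0.27 interaction and 500 replicates under the
null for type-I-error calibration. These sizes were chosen so the full
verification suite runs on a laptop in minutes while leaving Monte-Carlo
error well below the effects of interest (the interaction estimate's SE at
this design is about 0.4, so 100 replicates pin the mean to about 0.04);
the design scales back up by passing `cohort_design()` unchanged. The fixed
effects of a linear mixed model are unbiased under this generative model, so
recovery failures would indicate implementation defects, not statistical
ones — that is what makes the harness a useful acceptance surface.

## Reproducibility contract

Every simulator is a pure function of its inputs and a single integer seed;
internally derived seeds (per participant-session plans, per recovery
replicate) are drawn from one stream seeded at entry, so one root seed
reproduces an entire pipeline run. `run_pipeline()` writes a manifest with
stage-by-stage row counts (which it also verifies against the design's
expected counts), the dropped-run registry, every analysis option, and file
checksums; rerunning the same configuration reproduces the checksums
byte-for-byte.

One bookkeeping quirk is handled explicitly: payment-trial selection
nominally draws a trial number "between 11 and 261", but 10 practice plus
250 task trials give only 260 positions; `select_payment_trial()` accepts
11-260 and rejects 261 along with practice-trial indices.
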