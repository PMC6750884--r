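---
title: "Modelling adaptive state-space and action-sequence control in a two-stage task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptive state-space and action-sequence control in a two-stage task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostagerl)
```

## The task and what the package computes

The two-stage instrumental task starts each trial in `S0`, where a lever
press (`L`/`R`) leads to one of two stimulus-signalled stage-2 states
(`S1`/`S2`); a second press then either earns a pellet or nothing. Reward
is doubly conditional: only one stage-2 state pays at any moment, and
only through its *discriminative* action (`R` in `S2`, `L` in `S1`). The
rewarding state reverses with probability 0.14 after every earned
outcome, sessions stop at 60 outcomes, and probe sessions replace the
deterministic stage-1 transition (`L -> S2`, `R -> S1`) with an 80/20
common/rare one.

The package simulates this task, simulates and fits a space of
reinforcement-learning agents to trial-by-trial choices, compares the
agent families by approximate model evidence, and runs the
stay-probability regressions that diagnose which controller produced the
choices. Because the motivating experiments' trial-level data are not
publicly deposited, a synthetic-cohort generator stands in for them: it
is first-class, tested code, and every downstream stage is validated
against it.

## Agent families

Eight families tile the hypothesis space of state-space representation
(collapsed vs true two-stage) and action repertoire (single presses vs
cached sequences `L->R`, `R->L`):

| family | stage-1 options | stage-1 valuation |
|---|---|---|
| `FLAT` | `L, R` | one merged state, values reinforced by the most proximal outcome |
| `MF` | `L, R` | cached values, SARSA(λ) update |
| `MB` | `L, R` | planning through a learned transition estimate |
| `MB-MF` | `L, R` | `w`-weighted hybrid |
| `H` | `L->R, R->L` | cached sequence values only |
| `H-MF` / `H-MB` / `H-MB-MF` | `L, R, L->R, R->L` | union of sequence values and MF/MB/hybrid single-action values |

A selected sequence commits the agent to its second press unless it is
*interrupted* (probability `p_int`), in which case the ordinary stage-2
policy resumes. Because the selection is latent, the likelihood of an
observed pair `(a1, a2)` marginalises over the modes consistent with
`a1`: single action, sequence-run-to-completion (which forces
`a2 = second element`), or sequence-interrupted.

Two assumptions deserve emphasis.

**Credit assignment is marginal.** The sequence value update is weighted
by the posterior responsibility that a sequence was *selected* (completed
or interrupted), computed from the observable actions. The same weighting
is used when simulating, so the simulator and the fitted likelihood
describe one generative model — the latent mode is treated as unobserved
by the credit-assignment process itself. (`rl_agent(updates = "hard")`
switches to 0/1 known-mode weights for sensitivity analyses.) Selection
responsibility, rather than completion responsibility, matters: rewarded
rare-transition trials can never contain a completed sequence (the forced
second press is wrong for the rare state), so completion-weighted credit
would never reinforce sequences on exactly the trials that dissociate
them from planning.

**Learning persists within a subject.** Values carry across consecutive
sessions of a subject and re-initialise only at subject boundaries, in
the simulator and the likelihood alike. Lag-based *analyses* still break
at session boundaries (the first trial of a session has no predecessor).

## Parameters

All rates and probabilities are unitless; inverse temperatures are in
units of 1/value with rewards in {0, 1}.

* `alpha1`, `alpha2`, `alpha_seq` — learning rates for cached stage-1
  values, stage-2 values and sequence values; base models share one rate
  (`separate_rates` frees them).
* `lam` — eligibility weight of the SARSA(λ) stage-1 update; fixed at 1
  when the `eligibility` toggle is off (reward reinforces the stage-1
  cache directly, the convention for this task class).
* `beta1`, `beta2` — softmax inverse temperatures, stage 1 and stage 2.
* `w` — model-based weight of hybrid single-action values (fixed 1 for
  pure MB members, 0 for pure MF).
* `p_int` — sequence interruption probability; free by default in
  sequence families. The pure-sequence family must keep `p_int > 0` or
  carry a lapse floor, otherwise a stage-2 press deviating from the
  selected sequence has probability zero; `model_spec()` enforces this.
* `b_disc` — stage-2 discrimination-tendency bias toward the only action
  ever rewarded in each stage-2 state (`disc_bias` toggle).
* `eps` — uniform lapse floor in `[0, 0.5)` (`lapse` toggle).
* `q0 = 0.5` — initial value level, the midpoint of the reward range, so
  both actions start symmetric.
* `t_common0 = 0.9` — initial transition estimate toward the trained
  contingency: the deterministic training experience smoothed by a
  pseudo-count prior (nine contingent observations to one), updated at
  rate `alpha_T = 0.2` thereafter.

Fitting works on transformed scales (logit for rates and probabilities,
log for inverse temperatures) with weakly-informative priors: standard
normal on the transformed scale, `N(0, 2)` for `b_disc`. The priors keep
the evidence proper without strong shrinkage and are overridable through
`prior_spec()` since no canonical values exist for this task.

## Fitting and model comparison

`fit_map()` maximises log-likelihood plus log-prior with 10 restarts (the
first at the prior mode, the rest drawn from the prior; BFGS, relative
tolerance 1e-10) and measures curvature by central finite differences
with step 1e-4 on the transformed scale. Model evidence is the Laplace
approximation at the MAP, summed over subjects for a group comparison
(fixed-effects-over-subjects aggregation — a single group number per
model); hierarchical empirical-Bayes group priors are deliberately out of
scope. If the Hessian is not positive definite, a BIC-style penalty
substitutes and the result is flagged. Pseudo-r² is
`1 − nll/(n·log 2)` with `n` counting two decisions per non-aborted
trial. A subject with no usable trials yields the prior mode and log
evidence 0 exactly.

The conjugate-Gaussian check in the test suite confirms the machinery is
exact for quadratic posteriors (1e-8). For genuinely skewed posteriors
the Laplace value deviates from brute-force quadrature by its intrinsic
approximation error — about 0.1–0.3 nats for the two-parameter flat
learner at 20 trials, shrinking as O(1/n). Model comparisons here rest on
evidence *differences* across hundreds of trials per subject, far above
that error scale.

## Behavioural analyses

`annotate_trials()` derives the lagged fields (previous reward, stay,
previous transition, same stage-2 state, previous discrimination
correctness); aborted trials are dropped from the lag chain entirely.
`filter_stage1()` keeps trials whose predecessor ended in a correct
discrimination (the default, because an incorrect previous discrimination
mechanically inflates stage-2 "stays" in a different state);
`filter_stage2()` additionally requires a changed stage-2 state.
`stay_regression()` fits a mixed-effects logistic regression with all
fixed effects varying across subjects (uncorrelated slopes; nested
session intercepts for multi-session analyses) and reports Wald 95%
intervals (`estimate ± 1.96·SE`). Predictors are effect-coded (±0.5),
making the reward main effect orthogonal to the reward-by-transition
interaction — the decomposition the controller fingerprints rely on. If
the mixed fit fails, a flagged fallback fits per-subject ordinary
logistic regressions and summarises across subjects; separation is
flagged, never silent.

## The synthetic cohort

Defaults mirror the experimental design: 8 subjects, 40 deterministic
training sessions with an 80/20 probe inserted after sessions 20 and 30
and at the end, 60-outcome session caps with a 2000-trial guard, and a
developmental regime switching from the flat controller to the
hierarchical model-based controller after session 10 (a hard switch by
default, to keep tests crisp; a gradual per-trial mixture is available
and both controllers keep learning under it). Per-subject parameters
draw from `Beta(3,3)` for rates, log-normal with median 3 (sdlog 0.4)
for inverse temperatures, `Beta(2,8)` for `p_int`, `Beta(2,2)` for `w`
and `N(1, 0.5)` for `b_disc` — chosen once as mid-range, discriminating,
non-degenerate behaviour, and overridable. Every (subject, session) pair
receives a seed derived from the master seed, so the ground-truth sidecar
regenerates the dataset bit-exactly.

What the generator emulates: the task contingencies, reversal dynamics,
session caps, probe transition statistics, the developmental sign flip of
the per-session reward effect, and optional aborted trials (for the
exclusion rules). What it does not: reaction times (the column is carried
but not modelled), magazine-entry dynamics, satiety or motivational
drift, and any within-session non-stationarity of parameters. Passing
tests therefore validate the pipeline's statistical machinery on data
with the assumed structure, not the behavioural realism of any particular
parameter set.

## Problem sizes used by the validation suite

Simulator fidelity checks use 100,000-trial runs; the likelihood is
checked against exhaustive latent-mode enumeration on 1,000 random small
sessions; model recovery uses ten replicate cohorts (8 subjects × 300
probe trials) per generating family across the seven two-stage families;
parameter recovery uses 20 subjects × 500 trials; fingerprints use three
to five replicate cohorts per controller with median-based direction
assertions; CI calibration uses 100 replicates of n = 5000. These sizes
were chosen to put Monte-Carlo error well below each criterion's margin
while keeping the suite runnable on a laptop.

## Known limitations

* The pure-sequence family exhibits a small positive reward-by-transition
  interaction under mid-range learning rates, even though sequence
  selection ignores transitions: rewarded rare-transition trials require
  an interruption and cluster just after reversals, when the agent still
  holds the wrong sequence, so they select moments of low repetition
  probability. The textbook "reward main effect only" pattern is
  recovered as learning rates shrink. Direction tests on this family
  should therefore lean on the reward main effect.
* The interaction between hierarchical and planning control makes the
  stage-1 reward main effect of the `H-MB` family small (≈ +0.2 log-odds
  at mid-range parameters); single 2,400-trial cohorts estimate it with
  SE ≈ 0.2, so sign checks aggregate replicates.
* Evidence is a per-subject Laplace approximation; absolute magnitudes
  should not be compared across packages that use hierarchical
  group-level evidence.
* Reversed-contingency sessions are simulated faithfully, but the fitting
  layer assumes the standard contingency when orienting the initial
  transition estimate; fit probe-session data recorded under the standard
  mapping.
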