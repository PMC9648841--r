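---
title: "Costed attentional control in the sustained attention task: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costed attentional control in the sustained attention task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satpomdp)
```

## The task and the model

The sustained attention task (SAT) confronts a rodent with repeated trials in
which a brief light signal may or may not appear at an uncertain time; at the
end of each trial the animal reports "signal" or "no signal" and is rewarded
for hits and correct rejections.  `satpomdp` models one trial as a partially
observable Markov decision process over `N = N0 + N1 + 1` steps.  The latent
stage `X_n` is `pre` (no signal yet), `on` (signal present) or `post` (signal
over).  A trial contains a signal with probability `p1`; given a signal, its
onset is uniform over the `N1` steps after the `N0` guaranteed pre-signal
steps, so the arrival hazard

\[
\lambda_n = \frac{p_1/N_1}{1 - p_1 (n - N_0 - 1)/N_1}
\]

increases over the trial.  An ongoing signal turns off with probability `q`
per step and is always off before the decision step, which truncates the
duration distribution below the geometric mean `1/q`.

The agent controls a binary attentional state `Y_n` in {weak, strong} through
its action `a_n`: observations are Gaussian with mean 1 while the signal is
on and mean 0 otherwise, with standard deviation `sigma_w` under weak and
`sigma_s <= sigma_w` under strong attention.  Strong attention is costly:
`kappa <= epsilon <= 0` are the rewards (costs) of choosing strong from the
weak state (a switch) and from the strong state (maintenance).  At the
decision step the agent also reports; a correct report earns one unit of
reward.  At a trial boundary a strong state survives into the next trial
except with a small decay probability `delta`.

Because the stage is hidden, planning happens in the belief MDP: the state is
the posterior `b_n` over (pre, on, post) — the likelihood of each observation
is applied at the current step and the belief is then pushed through the
stage transition — augmented by the known attentional state.  The report rule
is fixed by Bayes: report "no signal" exactly when `b(pre) > 0.5`.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `p1` | assumed signal probability | 0.5 | frequent-signal regime |
| `q` | per-step signal offset probability | 0.2 | mean signal length well below the trial |
| `N0`, `N1` | pre-signal / arrival steps | 3, 6 | short trial, `N = 10` |
| `sigma_w`, `sigma_s` | observation SD by attention | 1, 0.5 | strong doubles the per-step d' |
| `kappa` | switch cost | -0.1 | moderately costly relative to the unit reward |
| `epsilon` | maintenance cost | -0.014 | much cheaper than switching |
| `delta` | boundary decay of strong attention | 0.001 | rare spontaneous disengagement |

The rare-signal and sequential regimes lower the maintenance cost to
`epsilon = -0.005` and use assumed signal probabilities of 0.1–0.15.

## Discretization and numerical choices

The belief simplex is covered by a regular lattice with spacing
`delta_b = 0.02` (1326 points; `make_grid`).  Values are read between lattice
points by barycentric interpolation, which is exact for affine functions of
the belief; actions, being categorical, are read at the nearest lattice
vertex during simulation.  Observations are marginalized over a uniform
trapezoid quadrature of 201 nodes on `[-5 sigma_w, 1 + 5 sigma_w]` — the
evidence is a three-component Gaussian mixture, so a dense rule integrates it
essentially exactly — and each updated belief scatters its evidence mass onto
the corners of its containing lattice triangle, after which rows are
renormalized.  Beliefs are renormalized after every update and components
below 1e-15 are clamped to zero.  Ties between action values within 1e-12 go
to the cost-free weak action, and a belief with `b(pre) = 0.5` exactly is
reported as "signal" (the no-signal report requires strictly more than 0.5).
Halving `delta_b` to 0.01 while doubling the quadrature changes single-trial
optimal values by less than 1e-2 everywhere (tested).

## Solvers

The single-trial (episodic) policy comes from backward induction: at the
decision step the attentional action is weak — it has no informational or
future value — and the terminal value is `max(b(pre), 1 - b(pre))`.

For continuing trials the objective is the average reward per step `g*`.
Because every trial starts with certainty in `pre`, the only state carried
across trials is the attentional one, so the cross-trial problem is an
embedded two-state average-reward MDP.  `solve_average_reward` exploits this:
it alternates a greedy backward pass through the trial (given continuation
values for starting the next trial weak or strong) with exact policy
evaluation of the induced trial policy — the map from continuation values to
start-of-trial values is affine, and three backward passes identify it — and
solves the two-state gain/bias equations in closed form.  This is Howard
policy iteration on the embedded chain; it terminates exactly in a handful of
sweeps, where plain relative value iteration would crawl because the
`delta = 0.001` boundary decay makes the strong state nearly absorbing and
the chain mix over a ~1000-trial timescale.  The unichain property needs
`delta > 0`.

`fixed_policy` evaluates the always-weak and always-strong comparators with
the same machinery and the same 0.5 report threshold.

## Exact policy statistics

`policy_stats` propagates the joint distribution over (lattice belief, latent
stage, attentional state) through the trial, using the believed model for the
filter and the generative model for observation frequencies.  It returns the
per-step probability of choosing strong, the expected number of strong steps
per trial, hit and false-alarm rates, d', and the reward rate, without
Monte-Carlo error at the grid resolution.  Both trial-start attentional
states are propagated and combined under the stationary distribution of the
policy's own cross-trial chain (or a forced weak/strong start).

## Which policy the parameter sweeps use, and why

`sweep_parameter` re-solves the model along a grid of one parameter and
supports both solution modes.  The default, used by the breaking-point
analyses, is the episodic mode with occupancy measured from a weak trial
start.  This is a deliberate choice.  Under the continuing objective with
`delta = 0.001`, the strong state is nearly absorbing, and the bias advantage
of starting a trial strong (~0.03–0.05 units) exceeds the maintenance cost
per trial at every offset probability `q` in [0, 1]: once engaged, camping in
the strong state is weakly optimal almost everywhere, so stationary strong
occupancy saturates near the trial length and even *increases* with the
switch cost (switching back becomes prohibitive).  Those maintenance-driven
plateaus say nothing about when attention is worth *engaging*, which is what
the sweeps are meant to expose.  The episodic mode isolates that within-trial
structure: occupancy falls to exactly zero once a single step of improved
evidence is no longer worth the switch cost.  With the default configuration
the breaking points are at `sigma_s = 0.6` (noise quality), `|kappa| = 0.15`
(switch cost), and high `q` (brief signals); with
`|epsilon| = |kappa| = 0.1`, strong attention is chosen at exactly one step,
the penultimate one.  A breaking point is declared where the expected number
of strong steps per trial falls below 1e-6 — far below one engaged step per
million trials — and stays there.

Two caveats on the `q` sweep at the default resolution.  First, between
`q = 0.5` and `q = 0.8` the exact occupancy is of order 1e-3–1e-2 steps per
trial and its exact zero crossing moves with the lattice spacing (0.9 at
`delta_b = 0.02`, 0.7 at 0.01): beliefs that justify engagement remain
mathematically reachable but carry vanishing probability, and the barycentric
scatter leaks tiny mass across the policy boundary.  Second, episodic
occupancy is largest at `q = 0` (persistent signals reliably reward a late
engagement) and declines with `q`; the continuing mode instead rises from
~1.3 steps at `q = 0` (where maintenance does not pay) to a maintenance
plateau of ~7 steps.  Readers comparing engagement across `q` should bear in
mind which of the two effects — within-trial engagement or cross-trial
maintenance — they care about.

## The simulator and the manipulation experiments

`run_trials` executes a solved policy on sequentially sampled trials: latents
from the generative parameters, actions from the policy at the nearest
lattice belief, observations with the noise of the actual attentional
condition, filtering with the believed model, and attentional carry-over with
boundary decay.  Each trial draws from a deterministic substream of the root
seed, so trial `i` is reproducible regardless of how many trials surround it.
There is no lapse ("trembling-hand") process: every false alarm arises from
inference noise.

The optogenetic-style experiment decouples actual and believed observation
quality in seven conditions (`run_optogenetic_condition`).  In the
"mismatch obs." conditions the agent runs and believes the optimal policy
while the observation noise is clamped strong or weak; in the
"mismatch inf." conditions observations are generated under the optimal
policy's actions (a correctly calibrated agent drives the noise sequence)
while the report comes from filtering the same observations under an assumed
always-strong or always-weak noise model.  Summaries use
`d' = z(H) - z(F)` with rates of 0 and 1 replaced by `1/(2m)` and
`1 - 1/(2m)`; binomial standard errors accompany the rates.

## Sequential sessions and the phasic ACh proxy

`run_session` implements nonstationary estimation of the signal probability
with two levels (defaults 0.1 and 0.15) while the generative probability
stays 0.5: end-of-trial feedback sets the estimate to the high level after a
signal trial and the low level otherwise, and a mid-trial weak-to-strong
shift raises a low estimate immediately for the rest of the trial.  On a
mid-trial jump the belief is not re-filtered retroactively — the policy and
hazard simply switch from that step — because the jump models an immediate
policy change, not re-inference.  At these settings the solved policies
maintain strong attention across trials at the high estimate but not at the
low one, which is what generates trial-history effects.

The ACh proxy treats the strong action as the cholinergic report: per-step
indicators are aligned at the signal onset (non-signal trials at the
round-half-up average onset, step 7 by default), baseline-corrected by the
mean over the three preceding steps, and averaged within trial-history
classes.  The trace extends three steps into the following trial so that the
strong-to-weak shift triggered by end-of-trial feedback — the model's large
negative deflection on incongruent correct rejections, a deliberate
reproduction of the model's known overprediction there — is visible.

## What the generator does and does not emulate

The synthetic task generator reproduces the trial statistics the model
assumes: Bernoulli signal trials, uniform onsets, truncated-geometric
durations, Gaussian observations with attention-dependent noise.  It does not
emulate reaction times, lapses, satiety or fatigue drifts, vigilance
decrements over a session, or any sensory structure beyond the binary mean
shift — so passing tests certify the inference and planning machinery, not
fidelity to any particular animal's data.

## Problem sizes used in the tests

The test-suite and the acceptance analyses use the default discretization
(`delta_b = 0.02`, 201 quadrature nodes), a single refinement check at
`delta_b = 0.01` with 402 nodes, Monte-Carlo runs of 10,000 trials for the
manipulation and sequential experiments, and 50,000 trials for
generator-level goodness-of-fit checks.

## Known limitations

- All sweep anchors are properties of one short-trial configuration
  (`N = 10`); the solver scales as (grid points) x (quadrature nodes) per
  step and trial lengths beyond a few tens of steps would warrant a sparser
  observation rule.
- The two-level estimate dynamics are a deliberate simplification; continuous
  estimation of the signal rate is out of scope.
- Near policy boundaries the lattice introduces order-`delta_b` ambiguity;
  quantities that hinge on exact zero occupancy inherit that sensitivity (see
  the `q`-sweep caveat above).
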