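---
title: "Models and methods behind somtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind somtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somtrack analyses behavior from a social performance-tracking task in which
a participant (S) and two other players (O1, O2) repeatedly play short
"minigames" and receive integer performance feedback on a 1–15 scale. On
each trial the participant rates whether their own and one other player's
upcoming performance will exceed a staircased half-integer *rating marker*,
and decides whether to *engage* in a cooperative or competitive interaction
with that trial's *relevant other* or to *avoid* it. The scientific target
is **self-other mergence (SOM)**: the context-signed intrusion of one
player's performance history into ability estimates for another player.

This vignette explains the models, the generator, the estimators, and the
design decisions taken where the design was genuinely open.

## The performance-tracking model

Six latent estimates (three players × two minigames) follow a delta rule
with shared learning rate $\alpha \in [0, 1]$:

$$\mathrm{perf}_{t+1} = \mathrm{perf}_t + \alpha\,(\mathrm{feedback}_t -
\mathrm{perf}_t).$$

Because the update is convex, estimates can never leave the 1–15 feedback
range. On *false-start* trials (the participant's own performance was too
poor to yield feedback) the self estimate is carried forward unchanged and
no self prediction error exists.

Ratings and choices are softmax in a single inverse temperature $\beta$:

* P(positive rating) is the logistic of $\beta\,(\mathrm{perf} -
  \mathrm{marker})$, separately for S and O with their own markers;
* P(engage) is the logistic of $\beta \cdot EV_\mathrm{engage}$, where
  $EV_\mathrm{engage}$ is the estimate difference minus threshold in
  competition and the estimate mean minus threshold in cooperation, and the
  avoid option has value 0.

A positive rating is worth $\pm 0.25$ points depending on whether the
subsequent feedback beats the marker, so its expected value is
$(p - 0.5) \times 2 \times 0.25$, bounded in $[-0.25, 0.25]$; negative
ratings never pay. The trial's total expected value sums both rating EVs
and the EV of the chosen engage/avoid action, and the reward prediction
error is the realised total payoff minus that sum.

The session likelihood multiplies three equally weighted terms per decision
trial (S rating, O rating, engage/avoid). `fit_group()` minimises the
summed negative log-likelihood over **all sessions of one group jointly**,
giving a single $(\alpha, \beta)$ per group — per-participant fitting is
deliberately out of scope. Estimates for a main session are initialised at
the **last starter-session feedback** of each player and minigame; the
starter phase itself (16 trials, the first 4 without decisions) is used
only for initialisation and for building the marker staircase history, not
for the likelihood, because only in-scanner trials are modelled.

Numerical choices: probabilities are floored at $10^{-10}$ so the
likelihood is finite everywhere; $\beta$ is bounded above by 20 to prevent
softmax saturation pathologies; optimisation is bounded L-BFGS-B restarted
from a fixed 5 × 5 grid over $(\alpha, \beta)$, making fits deterministic.
If a record has no starter phase (truncated external data), initialisation
falls back to the first observed feedback with a warning.

## Quantifying SOM: the rating GLMs

For each participant-session, the binary ratings are regressed on
model-derived quantities with a logistic GLM, restricted to **engage
trials** (only there is the social context consequential). The interaction
model for the O rating uses

S-performance, O-performance, S-performance × context,
O-performance × context, context, marker-O,

and symmetrically for the S rating with marker-S. Context is coded +1
(cooperation) / −1 (competition). All regressors, including the
interaction terms, are z-scored over the included trials; interactions are
built as the product of the z-scored performance and z-scored context and
then re-standardised (re-scaling the product is one of two defensible
conventions; it makes interaction coefficients comparable across sessions
with different engage-rate imbalances). z-scoring is done within
participant-session, matching the per-session fitting. An intercept is
included: without one the context effect would absorb the base rate.

The SOM effect sizes are the interaction coefficients:
`som_StoO` (S-performance × context in the O-rating model) and
`som_OtoS` (O-performance × context in the S-rating model). Each comes in
a raw-beta and a variance-weighted flavor (coefficient / standard error,
i.e. the coefficient's t statistic). Baseline descriptive tests use the
variance-weighted values to de-weight noisy sessions; stimulation
contrasts use raw betas. Binned companion models (fit separately within
cooperation and competition, without context terms) exist for
visualisation; their coefficient difference tracks the interaction
coefficient closely.

With roughly 40–80 engage trials and six regressors, perfect separation
does occur. Sessions whose fit does not converge, or whose estimates or
standard errors are implausibly large, are flagged and excluded from group
tests with a logged count, rather than contributing unstable numbers.

## Group-level tests

* **Baseline**: one-sample two-sided t tests across participants on the
  variance-weighted SOM effects and on the context main effects, using the
  unstimulated (no-cTBS) session of every participant, groups pooled.
* **Stimulation**: a 2 × 2 mixed-design ANOVA on raw-beta `som_StoO`
  (between: dmPFC vs. vertex group; within: cTBS vs. no-cTBS), computed via
  `aov()` with a participant error stratum, plus paired t tests within each
  group. On this design the interaction F equals the squared pooled
  two-sample t on per-participant condition differences — asserted in the
  test suite. Participants missing a usable session are dropped
  complete-case with a logged count. Constant data are reported as F = 0.

## The synthetic task and agents

The generator reproduces the study's structural conditions: 88 main trials
in a fully crossed 2 (context) × 2 (partner) × 2 (minigame) design with 11
trials per cell in seeded pseudorandom order; a 16-trial starter phase
whose first four trials carry no decisions and cover both minigames twice
each; two sessions per participant with the *identical* feedback schedule;
and (by default) one schedule shared by all participants, as in the task.

Where the study's hand-built schedules are not published as formulas, the
generator substitutes mechanisms with the same statistical signature:

* **Feedback** follows a bounded random walk of a latent level (drift sd
  0.35 points/trial) plus observation noise (sd 1.2), rounded and clipped
  to 1–15. Starting levels are drawn near mid-scale (truncated normal,
  mean 8, sd 2). Interleaving the two minigames lowers the lag-1
  autocorrelation of the presented stream relative to the within-minigame
  series, as intended by the design.
* **Thresholds** equal the trial's payoff-relevant feedback quantity plus
  Gaussian noise (sd 2), so the engage payoff is centred near zero and
  decorrelated from ability levels (|r| < 0.1 in generated data),
  dissociating reward expectation from performance expectation.
* **Markers** start at 7.5 for every player and minigame (the mid-scale
  grid point; unbiased) and are clipped to [1.5, 14.5], because a marker
  outside the feedback range would make one response always correct.

Agents track performance with the same delta rule and rate via the same
softmax, with SOM injected as an additive, context-multiplied bias of the
**decision variable** centred on the scale midpoint: the O-rating decision
variable is $O\mathrm{perf} + w_{S \to O}\,c\,(S\mathrm{perf} - 8) -
\mathrm{marker}_O$ (and symmetrically for S ratings). This is the minimal
mechanism whose GLM signature is exactly the interaction coefficient the
pipeline estimates; whether SOM acts on the decision variable or the
stored estimate cannot be distinguished from the behavioral data, and the
generator documents the former. When the main phase begins, agents
re-anchor their estimates at the last starter feedback — identical to the
model's initialisation — so a zero-SOM agent *is* the fitted model, and
the recovery tests are exact rather than approximate.

Population defaults were chosen once to be realistic for this task:
$\alpha \sim N(0.3, 0.1)$, $\beta \sim N(0.8, 0.2)$ (truncated),
$w_{S \to O} \sim N(0.15, 0.1)$, $w_{O \to S} \sim N(0.10, 0.1)$ — small
positive biases of the size implied by modest group-level t values — and a
shared O-rating optimism term of 0.5 points × context, giving the context
main effect a real signal. The stimulation effect is an additive shift of
$w_{S \to O}$ (default 0.15) applied only in dmPFC × cTBS sessions, with
session order counterbalanced.

What the generator does *not* emulate: reaction times, fatigue or
session-order learning, the deception procedure, minigame stimuli, and the
exact deposited feedback schedules. Passing tests therefore demonstrate
estimator correctness and calibration under the modelled data-generating
process, not fidelity to every idiosyncrasy of real participants.

## Verification strategy and problem sizes

The test suite checks every closed-form quantity against hand computation;
the session likelihood against an independent straight-line
re-implementation (10⁻⁸); the fitted optimum against an 11 × 11 parameter
grid; logistic fitting against a from-scratch IRLS oracle (10⁻⁶); and the
mixed ANOVA against both a sums-of-squares oracle and the F = t² identity.
Calibration is checked by simulation: with no generated SOM, the
one-sample t test on `som_StoO` at n = 28 rejects at the nominal 5% rate
(200 replicates, binomial tolerance); with a strong SOM weight (0.5),
rejection probability exceeds 0.9. Parameter recovery uses 56 simulated
participants × 2 sessions from $(\alpha, \beta) = (0.3, 0.8)$, recovering
$\alpha$ within ±0.1 and $\beta$ within ±25%. Unit tests run on shortened
sessions (24–48 main trials) where only structure matters; all statistical
checks use full-length 88-trial sessions.

## Limitations

* One $(\alpha, \beta)$ per group, as in the source analysis; individual
  differences in learning are absorbed by the GLM stage.
* The variance-weighted effect is a t statistic, not an unbiased effect
  size; it is used descriptively, never for the stimulation contrast.
* The mapping-driven external-data adapter validates schema and schedule
  pairing but cannot guess a deposit's layout; a column mapping must be
  supplied.
* With fewer than ~30 engage trials the six-regressor GLM separates often;
  such sessions are excluded, which can reduce power in small simulations.
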