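---
title: "Modelling involuntary visuomotor feedback responses in jointly controlled reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling involuntary visuomotor feedback responses in jointly controlled reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dyadgame)
```

## The task and the question

Two people each hold a robotic handle and together move a *center cursor* —
displayed at the midpoint of their two hand positions — into their own
target, 25 cm ahead. The width of each person's target makes lateral cursor
deviations either task-relevant (narrow target, 1.05 cm) or task-irrelevant
(wide, 20 cm), giving a 2 (self relevance) x 2 (partner relevance) design.
On force-channel *probe* trials the hands can only move forward, and a brief
3 cm lateral jump of the cursor (Experiment 1) or of both targets
(Experiment 2) evokes a lateral force against the channel wall — the
*visuomotor feedback response* (VFR). Its earliest component (180–230 ms
after the visual event) precedes voluntary control, so its modulation across
conditions reveals what the involuntary sensorimotor circuits know about the
partner.

`dyadgame` implements the computational account of this task as a two-player
finite-horizon linear-quadratic dynamic game, the trial simulator that turns
policies into predicted VFRs, a synthetic dataset generator with the
experiment's trial structure, and the statistical pipeline used on the
empirical data.

## Plant model

Each hand is a planar point mass (m = 1.5 kg, viscosity b = 0.1 N·s/m)
driven through a first-order muscle filter with time constant 20 ms:

    m p̈_i = −b ṗ_i + f_i,        τ ḟ_i = u_i − f_i,

and the center cursor integrates the mean hand velocity,
ṗ_cc = (ṗ_1 + ṗ_2)/2. The base state stacks positions, velocities and
muscle forces of both hands plus the cursor and target positions (16
scalars; x = lateral, y = forward). Discretization is forward Euler at
dt = 10 ms (an exact matrix-exponential variant is available via
`build_dynamics(exact = TRUE)`; at this dt they differ at O(dt²)). Visual
feedback is delayed by 110 ms, implemented by augmenting the state with 11
exact history copies, so the full state has 192 entries. Each controller
observes, from the oldest slot, its own position/velocity/force, the
partner's position and velocity (not the partner's force), and the cursor
and target positions.

## Costs, hypotheses and the Nash solution

Controller *i* carries an individual quadratic cost with a terminal
cursor-to-target error penalty, a running control (effort) cost
R = r·I applied every step, and small terminal regularizers on its own hand
velocity and force. The lateral terminal weight is 40,000 when that
controller's target is narrow (relevant) and 100 when wide (irrelevant);
the forward weight is always 40,000 since everyone must reach forward. Under
a joint-cost policy, controller *i* minimizes J_i + α·J_j.

The four policy hypotheses are:

| label          | partner representation | α   |
|----------------|------------------------|-----|
| `no_rep_self`  | no                     | 0   |
| `rep_self`     | yes                    | 0   |
| `rep_equal`    | yes                    | 1   |
| `rep_weighted` | yes                    | 0.5 |

Representation policies solve the feedback Nash equilibrium by a backward
coupled-Riccati recursion: at each step the two gains satisfy the coupled
stationarity conditions given the next step's value matrices, found by
fixed-point iteration (tolerance 1e-10 on the gain change, at most 500
iterations, initialized from the previous step's gains; value matrices are
re-symmetrized each step to suppress drift). The no-representation policy
is each player's single-player LQR solved under the assumption that the
partner does not act. The test suite verifies the Nash property against an
independent batch least-squares formulation of the best response.

## State estimation

Each controller runs a Kalman filter whose prior combines the previous
posterior, the efference copy of its own command, and a prediction of the
partner's command — `−F_partner x̂_self` for representation policies, zero
otherwise. Gains come from the standard discrete-time covariance recursion
with diagonal sensory noise (defaults: position 2 mm, velocity 0.02 m/s,
force 0.02 N) and process noise (SD 1e-4) on the current base block.
Initial covariance is 1e-4·I. These noise scales are deliberately
human-like: cursor jumps are unmodelled by the internal model, so the
filter absorbs them gradually after the 110 ms delay, which is what gives
the simulated VFR its smooth rise. Setting the sensory SDs near zero makes
the post-jump posterior error collapse to machine precision within a few
steps of the delay — the estimator-convergence test uses exactly that
configuration.

## Trial simulation

`simulate_trial()` rolls the true plant and both estimator/controller pairs
forward for N = 90 steps (0.9 s). Jumps are injected as additive offsets on
the current cursor (or target) state once the true cursor passes 25% of the
forward distance (6.25 cm); history copies are not retro-edited, so the
offset reaches the sensory stream only after the full delay. Perturbation
jumps ramp over 25 ms and persist; probe jumps ramp out, hold 200 ms and
ramp back (250 ms end to end). On probe trials the lateral force column of
both plant input matrices is zeroed (the channel), lateral process noise is
suppressed (the channel physically blocks lateral motion), and the reported
applied force is the lateral component of B_i·u_i under the original input
matrix. The VFR is the left-minus-right (Experiment 1) or right-minus-left
(Experiment 2) force difference aligned at jump onset.

Two calibration choices were made once and fixed:

* **Horizon N = 90 (0.9 s).** With terminal-only accuracy costs, the
  optimal correction spreads over the remaining horizon; a long horizon
  makes corrections arbitrarily gentle. N = 90 corresponds to the
  experimental completion window (reach plus stabilization within
  ~1.4–1.6 s minus reaction and hold time) and yields involuntary-epoch
  responses of ~0.5–1.3 N in relevant conditions, the empirical scale.
* **Control weight r = 0.05** (with terminal velocity/force regularizers 20
  and 0.05). r sets where the relevance weights 100 vs 40,000 fall on the
  response saturation curve: much smaller r saturates both (no condition
  differences), much larger r suppresses responses entirely.

With these defaults the noise-free model reproduces the qualitative
fingerprints of the four hypotheses: self-cost policies show no
partner-relevance effect when the own target is irrelevant (exactly so
without a representation; to within ~2–3% for `rep_self`, where the Nash
best response and the partner prediction retain a small dependence on the
partner's policy even at α = 0); joint-cost policies respond more when only
the partner's target is relevant; the equal joint cost equalizes the three
relevant-involving conditions (within ~3%); and the weighted joint cost
responds less when the partner's target is also relevant.

## Synthetic data generator

`generate_dataset()` emulates the experimental structure: 24 pairs per
experiment, four blocked conditions per pair, and per block one lead-in
non-perturbation trial plus 10 randomized sets of 15 trials (8
non-perturbation, 2 left + 2 right perturbation, 1 left + 1 right + 1 null
probe) — 151 trials per block. Probe trials carry 1000 Hz lateral force
traces built from a smoothstep template rising between 140 and 180 ms after
visual presentation and holding a plateau, scaled so the involuntary epoch
mean of the left/right difference equals the participant's true epoch mean;
non-perturbation and perturbation trials carry final lateral hand
positions. Participant-level epoch means are the condition effects (by
default the model's own `rep_weighted` predictions, via `effect_model()`)
plus Gaussian between-participant variability.

Defaults chosen once: between-participant SD 0.21 N, so that with the
model's condition effects the expected common-language effect sizes of the
two planned comparisons sit near 92 and 63 — the empirical scale; per-trial
amplitude jitter 15%; white trace noise 0.25 N per sample; plateau template
(only epoch means matter downstream, the shape is otherwise
unconstrained). The generator reproduces the statistical structure the
analysis assumes — it does not mimic real kinematic idiosyncrasies,
learning across blocks, or non-Gaussian participant effects, so passing
recovery tests demonstrates correctness of the pipeline, not realism of
the traces.

## Response analysis

Recorded or synthetic probe forces are filtered with a 5th-order Butterworth
low-pass at 14 Hz applied forward and backward (zero phase; attenuation is
the squared single-pass response). Because the double pass uses zero initial
conditions, `lowpass()` removes the line through the trace endpoints and
odd-reflects both edges before filtering, making the DC gain exactly one and
suppressing edge transients. Traces are aligned so time zero is the visual
presentation instant (jump command plus the 42 ms display latency for
recorded data; the injection instant for simulated data). Epoch means use
half-open windows [180, 230), [230, 300), [300, 400) ms. The final lateral
hand deviation mirrors left-jump perturbation trials about the midline
before averaging, so corrections accumulate positively; null probes are
used as a drift check only and are not subtracted as a baseline.

## Statistics

Each epoch table (48 participants x 4 conditions) feeds a fully
within-subject 2x2 ANOVA (`stats::aov` with Error strata; every effect has
df = (1, 47) and equals the squared paired *t* of the corresponding
contrast, which the tests verify to 1e-10). Planned comparisons use a
non-parametric paired bootstrap: the participant-level differences are
recentered to mean zero and resampled with replacement (default 10^6
resamples); the two-tailed p is the proportion of resampled means at least
as extreme as the observed mean, with +1 continuity correction on numerator
and denominator, so the smallest attainable p is 1/(n_boot + 1). The
recentered-resampling variant was chosen among the cited bootstrap
flavours because it is exact for the mean under location shifts; the
Monte-Carlo calibration test shows its type-I error at n = 48 lies in
[0.04, 0.06]. Comparisons are Holm-Bonferroni corrected
(`stats::p.adjust`). The common-language effect size counts paired
differences in the direction hypothesized larger by the weighted
joint-cost model, ties half-weighted — on tie-free data a multiple of
100/48, matching the granularity of the reported values.

## Problem sizes and numerical notes

The packaged tests run the full 192-dimensional model (each Nash solve
takes well under a second), 8–20 trial batches for stochastic properties,
2–6 pair datasets for pipeline identities, one 24-pair dataset for the
study-size recovery check, 200 replicate epoch tables for the power study
(the generator's participant-level layer; the trace layer is exercised by
the exact-recovery identity), and 5,000 x 10^4-resample bootstraps for the
type-I study. Degenerate inputs are rejected early: non-integer
delay-to-step ratios, missing ANOVA cells, unpaired bootstrap inputs,
probe specs without a direction, and diverging simulations (state-norm
guard) all raise informative errors.

## Known limitations

* The coupled-Riccati fixed point is not globally guaranteed to converge
  for arbitrary games; a damping argument is exposed and non-convergence
  raises an error with the residual.
* Motor noise is additive; signal-dependent (multiplicative) noise and
  nonlinear arm dynamics are out of scope, as are infinite-horizon
  solutions.
* Reaction-time variability, display-delay simulation and the
  familiarization/washout blocks are not modelled; simulated trials start
  at the go cue.
* The `rep_self` equality prediction is exact only in the idealized
  account; the implemented Nash/estimator machinery leaves a small
  free-riding gap (see above).
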