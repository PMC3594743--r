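---
title: "An embodied basal-ganglia model of intrinsically motivated action discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An embodied basal-ganglia model of intrinsically motivated action discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiondiscovery)
```

## The scientific problem

Animals can discover action–outcome contingencies without food, water or any
other primary reward: a rat in a dark operant chamber will spontaneously poke
its snout into a hole that occasionally triggers a brief light flash, and
over days will come to respond at that "active" hole far more than at an
identical "inactive" one. This package implements an embodied computational
account of that behavior. A simulated differential-drive agent lives in a
square arena with two blocks; bumping the *active* (red) block can trigger a
light flash under a reinforcement schedule, bumping the *inactive* (white)
block never does. Everything the agent does emerges from a biomimetic core:
a rate-coded basal-ganglia action-selection circuit with thalamocortical
loops, a phenomenological model of outcome prediction that generates
*novelty salience*, a phasic dopamine signal computed as a *sensory
prediction error*, and a dopamine-dependent BCM rule for cortico-striatal
plasticity.

The model's central claims, which the test suite and `scripts/acceptance.R`
probe quantitatively, are:

* under a variable-interval (VI, mean 120 s) schedule, novelty salience —
  not cortico-striatal plasticity — carries most of the increase in active
  responding, and phasic dopamine *reduces* responding (dips dominate,
  depressing the D1 "GO" pathway and potentiating the D2 "NO-GO" pathway);
* under fixed-ratio (FR1) reinforcement the peak of responding falls on the
  first contingent day and declines steeply within sessions, and phasic
  dopamine produces a large transient potentiation of D1 synapses — the
  signature of a new action being encoded in the striatum.

## Model components

### Selection network

Each of three action channels (explore, interact-red, interact-white) runs
through leaky-integrator populations: sensory cortex, motor cortex,
D1- and D2-striatum, STN, GPe, GPi/SNr, VL thalamus, TRN and a brainstem
unit. Every unit obeys
$\tau\,\mathrm{d}a/\mathrm{d}t = -a + I$ ($\tau$ = 40 ms, forward Euler at
$\mathrm{d}t$ = 10 ms, guaranteed stable since $\mathrm{d}t \le \tau$) with
a piecewise-linear output $y = L(a, \epsilon)$ clipped to $[0, 1]$. The
D1–STN–GPi/SNr *selection* pathway is an off-centre/on-surround competition:
the channel with the strongest salience most suppresses its own GPi/SNr
output, releasing its thalamocortical loop and its brainstem unit; the
D2–GPe circuit balances total excitation and implements NO-GO control. An
action is expressed when its brainstem output exceeds $\phi = 0.5$; several
channels may pass threshold together, in which case wheel commands are
averaged ("motor blending"). Tonic dopamine $\lambda = 0.2$ scales
cortico-striatal transmission by $1 + \lambda$ (D1) and $1 - \lambda$ (D2).

The inter-nucleus gains follow the canonical rate-coded family (unit
projection weights, striatal output threshold slightly positive, tonically
active STN/GPe/GPi thresholds slightly negative), with the thalamocortical
and brainstem gains tuned against a *selection battery*
(`selection_battery()`): on an 11×11 grid of salience pairs the channel
with the larger salience must be the selected one whenever anything is
selected, co-selection is tolerated only below 0.2 salience separation, and
ties resolve by input noise. Two deliberate features of the tuned regime:

* motor cortex stays salience-proportional (no saturation), because the
  competition degenerates when both channels hit the output ceiling;
* the brainstem units carry a tonic excitability ($\epsilon_{bs} = -0.5$)
  that is normally cancelled by GPi/SNr inhibition, so expression is
  dominated by basal-ganglia *release* rather than raw cortical drive.

Motor cortico-striatal weights are set by a deterministic calibration pass
(`calibrate_motor_weights()`): a ladder of candidate weights is screened by
the battery and the smallest-violation candidate is kept. Sensory weights
start at exactly zero; any growth is learned bias.

### Prediction, novelty salience and habituation

The flash is a binary feature $y_f$. Its latent prediction $y$ is updated
only when an interaction with the active block completes: a flash gives
$y \leftarrow 1 - k(1 - y)$ (the first flash ever sets $y = 0.2$), an
omission with $y > 0$ gives $y \leftarrow k y$, with $k = 0.95$. The
prediction persists across days. Novelty salience is a tent map,
$S_{nov} = 0.5 - |y^* - 0.5|$: maximal when the outcome is least
predictable, zero for firm predictions. Intrinsic block salience starts at
0.45, shrinks by $\gamma_b = 0.95$ after each completed interaction with
that block, and re-initializes each day at $\gamma_a = 0.95$ times the
*previous day's starting value* — the source of overnight dishabituation.
Explore salience is drawn from Uniform(0, 0.8) (mean 0.4, sd 0.231).

### Phasic dopamine

At the moment a target interaction completes, a superior-colliculus-like
detector responds with $[y_f - y^*]^+$ and a canceling pathway with
$[y^* - y_f]^+$; their difference is exactly the sensory prediction error
$y_f - y^*$. Both are triangular pulses of width 0.2 s driving an SNc
integrator through gains $a^+ = 2$, $a^- = 1$, and the unnormalized output
$d = [a + 0.2]^+$ is the simulated dopamine level: resting at 0.2, bursting
without ceiling, dipping to zero at most. A fully predicted flash produces
no excursion.

### Plasticity

Cortico-striatal weights follow the rate-coded BCM form
$\dot w = \eta\, y (y - \theta_{BCM}) x$ with
$\theta_{BCM} = \langle y^2 \rangle\, C_{BCM}(d)$. The eight pair-timing
coefficients (D1/D2 × high/low dopamine × positive/negative timing) are
blended by $\alpha(d) = 4d/(1+4d)$, which makes $C_{BCM}$ *linear in
$\alpha$*; only the coefficients' signs and relative sizes are constrained
by the physiology, so the magnitudes here were chosen on a unit scale such
that:

* D1: strong LTP at high dopamine, depression-prone at low dopamine, with
  the zero crossing of $C_{BCM}$ near $d \approx 0.32$ — deep dips depress,
  large bursts potentiate, and the *small* bursts of a nearly-predicted
  outcome fall on the depression side. That last property produces the
  interior maximum of the D1 trajectory under FR1 without any extra
  mechanism: early surprising flashes drive the weight up, late predictable
  ones relax it toward an elevated equilibrium.
* D2: uniform LTP at low dopamine (dips potentiate NO-GO), depression at
  high dopamine, and a resting-level $C_{BCM}$ that approximately balances
  engaged MSN rates so that the post-pulse tail of an event window drifts
  little.

Plasticity is gated to a 1 s window opening at each phasic dopamine event,
with $\langle y^2 \rangle$ (an exponential moving average, time constant
5 s) frozen at event onset; between events the trajectories are flat.
With the phasic pathway disabled no events exist, so the no-dopamine
control's weights stay exactly at baseline. $\eta = 0.012$ is scaled so
that on the order of ten strongly surprising events produce the
response-contingent weight change. Updates apply to the motor and sensory
weights of the event's channel using the current pre/post rates.

### Arena and embedding

The arena is kinematic (no mass or friction): a 60×60 square, the two
blocks centred on opposite walls, a differential-drive agent with a 120°
field of view and 45-unit range. Each block-interaction subsystem is a
small FSM — orient, approach, controlled bump, back off, stop, slow
re-approach — whose completing contact is the operant response: at that
moment the schedule gate decides the flash (FR1: always; VI: only if the
exponential-interval timer has elapsed, premature responses go
unreinforced), the prediction is read out and updated, and the dopamine
event fires. Deselection mid-sequence aborts the bout without a response.
Speeds and stage durations were chosen so a full interaction takes roughly
5–10 s and per-session response counts land in the tens, the regime in
which the prediction model equilibrates over days rather than minutes.

## Deliberate design choices and deviations

* **Events at completion.** The flash gate, prediction update and dopamine
  event are all evaluated when the interaction sequence *completes*, not at
  the first bump. Tying the flash to the first bump while updating the
  prediction at completion decouples the two whenever a bout is aborted
  between bump and completion, leaving flashes that the internal model
  never learns about.
* **Explore redraw every 2.5 s.** The redraw interval of the explore
  salience is not specified by the underlying account; with per-second
  redraws the probability that a multi-second bout survives to completion
  was so low that responses (and hence flashes) became unrealistically
  rare. 2.5 s preserves interruptibility — a sufficiently high explore
  draw still aborts an ongoing bout (the maintenance boost from the
  thalamocortical loop is only about 0.2 in salience units) — while letting
  committed bouts usually finish.
* **Day-start salience bookkeeping.** Dishabituation multiplies the
  previous day's *day-start* value, not its habituated end-of-day value, so
  between-day recovery is genuine.
* **Eq.-level resolution of the SNc read-out.** The printed output
  branches are inconsistent at the boundary; the implementation uses the
  continuous rectification $d = \max(0, a + 0.2)$, which preserves the
  required lack of normalization above rest.

## What the simulations show (and what they do not)

Running `scripts/acceptance.R` (four conditions × 10 replicates, seeds
`base_seed + run - 1`, about half a minute on one CPU) reproduces the
qualitative structure of the in-silico study: no active/inactive asymmetry
during habituation (sign-flip permutation test, p ≫ 0.05); the VI peak
falls *after* the first contingent day while the FR1 peak falls *on* it;
within-session counts decline epoch-to-epoch, more steeply under FR1; under
VI with phasic dopamine D1 motor weights fall (≈ −20 %) while D2 weights
rise (≈ +10 %); under FR1 the D1 trajectory shows a transient maximum and
an elevated final value; without phasic dopamine all weights are exactly
flat. The peak-to-inactive ratio r_peak is ≈ 7 for VI with dopamine
(matching the reference value 7) and ≈ 9–10 without (reference 12), with
the ordering preserved.

Two quantitative discrepancies are known and deliberate rather than tuned
away. The FR1 ratios come out near 13–14 rather than 6 and 4: the FR1
active peak is pinned by the prediction's "novelty budget" (with k = 0.95
and a first-flash value of 0.2, salience collapses after roughly 25–30
reinforced responses, which one 15-min session comfortably delivers), while
inactive responding at late-phase habituated saliences is lower in this
arena than in the reference behavior, inflating the denominator. Both
orderings — less VI responding *with* dopamine, more FR1 responding *with*
dopamine — hold regardless.

The synthetic arena is a stand-in for a physically simulated robot: it has
no momentum, slip, sensor noise or camera model, the blocks are perceived
by geometric visibility rather than pixels, and bump detection is a
distance test. Passing tests therefore demonstrate properties of the
biomimetic core under an idealized embodiment, not performance on real
robot hardware.

## A short session

```{r example, eval = FALSE}
cfg <- default_config()
w <- calibrate_motor_weights(cfg$network)

ex <- run_experiment(cfg, schedule = "VI", pda = TRUE, n_runs = 3)
print(ex)
daily_counts(ex)
epoch_counts(ex, "red")
weight_change_summary(ex)
write_experiment(ex, "results/vi_pda")
```
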