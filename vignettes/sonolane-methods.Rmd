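---
title: "Simulating auditory substitution of lane position: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating auditory substitution of lane position: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the pipeline answers

Keeping a car in its lane draws on two visual information sources: the
proximal road (just ahead of the hood), which tells the driver *where the
car sits laterally in the lane*, and the distal road, which previews
*upcoming curvature*. In the classical two-level account of steering, a
**compensatory** feedback process consumes the proximal information and
determines lane-keeping *accuracy*, while an **anticipatory** feedforward
process consumes the distal preview and determines steering *stability*.

A sensory-substitution driving experiment occludes the proximal road and
replaces it with sound: the vehicle's lateral deviation from the lane
centre is encoded in the binaural balance of white noise (louder in the
ear toward which the car drifts). Three groups train for 40 one-minute
trials — normal driving (ND), visual occlusion (VO), and occlusion plus
the auditory substitution (SS) — bracketed by normal-vision pretest and
posttest sessions of 5 trials each, 15 participants per group. The
qualitative signature of interest: occlusion degrades accuracy (SDLP)
but not stability (SWV); with training, the auditory channel restores
accuracy to near the normal-vision level; and the substitution training
does not interfere with ordinary visually guided driving afterwards.

`sonolane` rebuilds that entire experiment *in silico* — course, vehicle,
encoder, synthetic drivers, metrics and inference — so the pattern can be
reproduced end-to-end from a single master seed, with no human data.

# Road course

The course is a chain of straight sections and circular bends:
straight lengths uniform on 50–150 m, bend curvature magnitudes uniform
on 1/180–1/80 m⁻¹ with strictly alternating left/right direction, lane
width 3.5 m. Two properties are deliberate simplifications:

* **Piecewise-constant curvature, no clothoids.** Only bends and straights
  are specified for the original course; transition spirals would add a
  parameter with nothing to calibrate it against.
* **Bend arc length** is not stated anywhere; we draw it from the same
  50–150 m range as the straights. At 80 km/h (22.22 m/s) this yields a
  curve roughly every 4–7 s — several curve negotiations per one-minute
  trial, matching the published example traces.

Each trial runs on a freshly generated course (1500 m minimum, more than
the 1333 m travelled per trial) seeded from the experiment's master seed,
so no agent can "memorize" a course and no course is shared between
trials — the original design's random courses imply the same.

Geometry queries are closed-form: pose at arc position `s` by exact
integration of the piecewise-constant curvature, and signed lateral
deviation (positive = left of centre in the direction of travel — one
convention, used everywhere) by local nearest-point projection seeded at
the previous arc position. Ties at segment joints resolve to the smaller
arc position.

# Vehicle

A kinematic bicycle (wheelbase 2.7 m, steering ratio 15): road-wheel angle
δ = steering-wheel angle / ratio, heading rate `v·tan(δ)/L`, constant
speed 80 km/h, semi-implicit Euler at the simulator's 1/60 s step.
Steering commands are clamped to ±2π rad and slew-limited to 2π rad/s
(commodity-car values; all exposed in `vehicle_params()`). No tire slip,
no lateral dynamics: at 80 km/h on curvature ≤ 1/80 m⁻¹ the lateral
acceleration stays below 0.5 g and a kinematic model is the standard,
fully deterministic choice. A consequence used by the tests: the per-step
displacement norm is exactly `v·dt`, and a constant road-wheel angle
traces an exact circle of radius `L/tan(δ)`.

# Binaural encoder

Per-ear level in dB relative to the maximum tolerable level:

* centre of lane: −50 dB in both ears;
* deviation `d` (positive leftward): left ear `−50 + 25·d`, right ear
  `−50 − 25·d` (gain 25 dB/m), so the interaural difference is `50·d`.

Clamping is unspecified in the original study; we clamp per-ear at
0 dB (the maximum tolerable level — it cannot physically be exceeded) and
−100 dB. With the default base and gain this leaves the mapping linear
and exactly invertible for |d| < 2 m, which covers the 3.5 m lane with
margin. dB values are amplitude-referenced (factor `10^(dB/20)`); the
reference is unstated there and this choice is stated explicitly
wherever it matters (rendering, RMS tests). `render_binaural()` produces
the diagnostic stereo waveform at 44.1 kHz with a zero-order hold per
1/60 s simulation frame — it is an offline rendering, not a presented
stimulus, so no click suppression is applied.

# Synthetic drivers

The original participants were human; the driver model is therefore the
package's own construction, designed to be the *simplest* mechanism
consistent with the two-level steering framework and the published group
pattern. Each agent computes, every 1/60 s:

```
sw_raw = FF(previewed curvature) − k_comp · d̂ − k_head · ĥ + motor noise
```

* **Anticipatory feedforward** `FF`: the steering-wheel equivalent of the
  curvature previewed 1 s ahead (`preview_time = 1` s, the tangent-point
  fixation lead reported for human drivers), passed through a first-order
  lag (`tau_ant = 0.8` s). The lag serves two purposes: it converts the
  stepwise curvature profile into human-like smooth steering, and its
  group delay cancels most of the preview lead so that, after the 0.2 s
  reaction delay (a fixed-length command delay line), the feedforward is
  applied where the curve actually is.
* **Compensatory feedback**: `k_comp` (rad of steering wheel per metre)
  acts on the best available deviation estimate `d̂` — visual in ND,
  decoded from the binaural levels in SS, absent in VO (the term is
  simply zero there, leaving only heading stabilization; this is what
  produces the sustained VO deficit).
* **Heading feedback** `k_head` keeps the car aligned with the road in
  every condition.

**Sensory noise is correlated over time.** Each channel's estimation
error is an Ornstein–Uhlenbeck process with a 1 s time constant and the
stationary SD given by the `sigma_*` parameters. This matters: white
estimation error at 60 Hz lies far above the ~1 rad/s control bandwidth
and would be filtered away almost entirely, making occlusion and
substitution indistinguishable. Slowly drifting error is both the
perceptually realistic model and the mechanism that lets channel quality
shape SDLP. Motor noise drifts faster (`tau_motor = 0.1` s, tremor-like).

**Learning to use the audio channel** is modelled as exponential decay of
the audio-decoding noise SD across training trials,
`σ(t) = σ_min + (σ₀ − σ_min)·exp(−λ t)`, the simplest monotone schedule
matching the published training curve; nothing in the original report constrains
the functional form beyond that. In addition the agent weights the audio
estimate by its current reliability, `w(t) = σ_min/σ(t)`: a freshly
trained listener leans on the noisy cue only weakly (behaving almost like
a VO driver, as the original study's first-training-trial group comparison
showed), and reliance grows as precision does. A useful side effect of
reliability weighting is that the audio channel's contribution to
steering *velocity* stays constant across training, keeping SWV free of
condition effects, as observed.

**Individual differences**: each participant's parameters are drawn once
from the population spec (`default_population()`): normal jitter of
roughly 10–15 % of the mean per parameter, clipped at validity bounds,
deterministic given the group seed and participant index.

**Default values and how they were chosen.** Gains `k_comp = 0.15` rad/m
and `k_head = 3` rad/rad place the compensatory loop's natural frequency
near 1.3 rad/s with heavy damping — stable under the 0.2 s delay and
settling a 1 m offset well within 10 s. The noise SDs
(`sigma_visual = 0.10` m, `sigma_audio` 0.85 → 0.12 m,
`sigma_curv = 8e-4` m⁻¹, `sigma_heading = 3e-3` rad,
`sigma_motor = 0.02` rad) and the learning rate (0.09 per trial) were
tuned **once**, by hand, until the default population reproduced the
qualitative published pattern — ND ≈ 0.33 m SDLP, VO ≈ 0.9 m, SS starting
near VO and converging to within a few percent of ND, SWV statistically
indistinguishable across groups — and then frozen. They are a calibrated
part of the study conditions, not free dials; no parameter was adjusted
to any individual test outcome afterwards.

# Performance metrics

* **SDLP**: standard deviation of the signed lateral deviation over the
  whole trial. Sample SD (driving-literature convention); at 3600 records
  the 1/N-vs-1/(N−1) distinction is below 0.02 %.
* **SWV**: per curve-negotiation window, the maximum absolute
  steering-wheel velocity; averaged across the trial's windows. Velocity
  by central finite difference at 60 Hz, no smoothing; units deg/s (no units are
  stated in the original report). A window is the maximal run of records
  whose centerline projection lies in an arc segment — no lead-in/lead-out
  margin, since none is specified. A trial with no completed window
  yields a missing SWV rather than zero.

Lower is better for both. Off-road excursions (beyond three lane widths)
flag the trial but do not abort it; metrics are computed regardless, as
they were for human participants.

# Inference

For each metric, two 3 (condition, between) × 2 (within) mixed
repeated-measures ANOVAs: training (first vs last training trial) and
interference (last pretest vs first posttest trial). Implementation is
the classical sums-of-squares decomposition with the df conventions that
match the published reports of this paradigm — interaction on (2, 42) df for 3 × 15
participants, within-subject effects Greenhouse–Geisser corrected (Box's
ε̂; identically 1 for a two-level within factor), partial η² as
`SS_effect/(SS_effect + SS_error)`. A significant interaction (α = 0.05)
triggers simple main effects — within effect per group on (1, 14) df;
between effect per within level on (2, 42) df using that stratum's
one-way error — and pairwise group comparisons from the stratum's pooled
error (t on 42 df, two-sided), adjusted by Shaffer's sequentially
rejective procedure. For three groups Shaffer's logical constraint gives
divisors 3, 1, 1: after the smallest p-value is rejected at α/3, not all
of the remaining pairwise nulls can hold simultaneously, so each is
tested at α. These error-term and df choices are the ones consistent with
every published df of the design; the published analyses do not
spell them out further.

The pipeline's calibration is verified by simulation: under a null
generative model (all groups identical), the interaction test rejects at
the nominal 5 % rate (checked over 200 replicate experiments against a
±2 SE band).

# What the generator does and does not emulate

The synthetic population reproduces: the occlusion deficit and its
persistence in VO, the SS training curve converging to ND, flat SWV
across conditions, pre/post stability, and between-participant
variability of plausible magnitude. It does **not** emulate: pretest
familiarization (agents start already asymptotic on the visual skill, so
the published early-pretest improvement has no counterpart), the
published VO *posttest* elevation (our VO agents carry nothing over into
normal-vision trials — no mechanism for it was specified), the small
published decrease of SWV from first to last training trial, fatigue,
attention, gaze behaviour or speed control. Passing tests therefore show
that the published *group-comparison* pattern follows from the two-level
control architecture plus condition-gated channels — not that human
learning dynamics are captured in detail.

# Numerical and reproducibility choices

* Fixed step 1/60 s throughout; no adaptive integration.
* Every random stream (course, participant parameters, per-trial noise)
  derives from the master seed via `derive_seed()`, a pure integer mixer;
  streams are collision-free across the protocol (tested) and results are
  bit-identical across runs with the same master seed.
* Projection searches locally around the previous foot point (±250 m in
  the R path; the current segment's neighbourhood in the compiled path),
  with ties at joints broken toward the smaller arc position.
* The closed-loop trial runner exists twice: an R reference path and a
  compiled (Rcpp) fast path used for the full protocol. Both are kept in
  RNG lockstep and the test suite asserts their trajectories agree to
  10⁻⁹ at zero noise; the noisy compiled logs are checked against the
  vehicle-level invariants (exact per-step displacement, heading law,
  slew limit).
* Problem sizes in the shipped tests: the full protocol run used for the
  qualitative checks is the study-sized 45 agents × 50 one-minute trials
  (8.1 M simulation steps, ~25 s compiled); distributional course checks
  use ≥1000 segments; the type-I calibration uses 200 replicate null
  experiments.

# Known limitations

The vehicle model is the package's own standard kinematic choice; the
original simulator's dynamics are unpublished, so only qualitative
closed-loop behaviour can be matched. The driver model's absolute SDLP
and SWV levels are calibrated, not derived; comparisons should be read
within the simulation, not against human magnitudes. The encoder's
clamping levels and dB reference are explicit package choices where the
source is silent. Human F and p values are not reproducible targets —
the human data are unavailable — and the pipeline accordingly aims at
the qualitative pattern, not the printed statistics.
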