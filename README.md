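# sonolane

Closed-loop simulation of auditory sensory substitution for lane keeping.

## What this package is for

Lane keeping relies on two visual streams: the proximal road informs the
driver of the car's lateral position in the lane, the distal road
previews upcoming curvature. In the two-level model of steering, a
*compensatory* feedback process uses the proximal stream and sets
lane-keeping **accuracy**, while an *anticipatory* feedforward process
uses the distal preview and sets steering **stability**. A
sensory-substitution driving study occludes the proximal road and
replaces it with sound — the car's signed lateral deviation *d* (m,
positive leftward) is encoded in the binaural balance of white noise,

    L(d) = −50 + 25·d   dB,      R(d) = −50 − 25·d   dB,

so the interaural difference is 50·d dB — and asks whether drivers can
learn to steer accurately from the sound alone.

`sonolane` rebuilds that experiment end-to-end with synthetic
participants: a procedural winding course (straights 50–150 m, bends
with |κ| ∈ [1/180, 1/80] m⁻¹, alternating direction, 3.5 m lane), a
constant-speed (80 km/h) kinematic-bicycle vehicle stepped at 1/60 s, the
binaural encoder above, two-level driver agents whose sensory channels
are gated by condition — normal driving (ND), visual occlusion (VO),
occlusion + substitution (SS) — the two standard performance metrics,

* **SDLP** — standard deviation of lateral position over a trial (m), and
* **SWV** — mean per-curve maximum steering-wheel velocity (deg/s),

and the inferential pipeline: 3 × 2 mixed repeated-measures ANOVAs with
Greenhouse–Geisser correction, simple main effects, and Shaffer's
sequentially rejective pairwise comparisons. The full protocol — 3
groups × 15 agents × (5 pretest + 40 training + 5 posttest) one-minute
trials — runs reproducibly from a single master seed.

Intended users: researchers in sensorimotor control, human factors and
sensory augmentation who want a fully specified, testable simulation of
the occlusion/substitution paradigm, or reusable components (course
generator, steering agents, SDLP/SWV, Shaffer-adjusted mixed ANOVA).

## Worked example

```r
library(sonolane)

# the visual-to-auditory conversion rule
encode_deviation(c(0, 0.5, -0.5))
#> # A tibble: 3 × 2
#>    left right
#>   <dbl> <dbl>
#> 1 -50   -50
#> 2 -37.5 -62.5
#> 3 -62.5 -37.5

# one trial: a trained sensory-substitution agent on a fresh course
course <- generate_course(seed = 42)
course
#> <road_course> 1611.9 m, 15 segments (7 bends), lane width 3.5 m

log <- simulate_trial(course, driver_agent(condition = "SS", trial_index = 39),
                      seed = 7)
trial_metrics(log, course)
#> # A tibble: 1 × 4
#>    sdlp   swv n_curves off_road
#>   <dbl> <dbl>    <int> <lgl>
#> 1 0.375  92.6        7 FALSE
```

At zero deviation both ears sit at −50 dB; half a metre leftward raises
the left ear to −37.5 dB and lowers the right to −62.5 dB. The trained SS
agent keeps SDLP at 0.375 m across the trial's 7 curves — close to a
normal-vision driver, which is the study's headline effect. A full
experiment is one call:

```r
exp <- run_experiment(sim_config(master_seed = 1))   # ~25 s, 2250 trials
condition_summary(exp$metrics)   # group means at the four analysis slices
tidy(exp$analysis)               # all ANOVA effect tables, broom-style
plot_learning_curves(exp$metrics)
```

On the default configuration the SDLP trial × condition interaction is
significant while SWV shows no condition effects, and Shaffer-adjusted
pairwise comparisons single out the SS recovery — the qualitative pattern
the paradigm predicts.

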