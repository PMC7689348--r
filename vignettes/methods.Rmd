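---
title: "Methods: gait, gaze and spatial-learning metrics in navpace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait, gaze and spatial-learning metrics in navpace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When people explore an unfamiliar environment on foot, walking itself
competes for attentional resources with encoding the space — cognitive-motor
interference (CMI). This competition grows with age: older adults often slow
down when the cognitive load of a task rises, which makes walking speed a
usable behavioral probe of interference. `navpace` implements a complete
analysis chain for experiments of this kind: participants repeatedly search
for an invisible goal zone in an instrumented room while whole-body
kinematics (optical motion capture, 120 Hz) and gaze (mobile eye tracking,
60 Hz) are recorded. The package turns those raw streams into three
per-trial variables —

* **walking speed**: median step speed over straight-ahead walking,
* **trajectory efficiency**: straight-line start-to-goal distance over the
  walked path length,
* **goal fixations**: proportion of fixations landing in the goal area,

— and from their trial courses derives the study's dependent variables: the
**criterion trial** (learning reached), **adaptation indices** (speed of
trial-to-trial change, anchored to the young group's mean trial course), and
the **percent change in walking speed** between the first and the reference
trial (a dual-task-cost-style score). A gated statistical layer compares age
groups and correlates the adaptation indices.

Because no participant recordings ship with the package, a synthetic-cohort
generator with full ground truth is a first-class module: every stage of the
pipeline is tested against what the generator programmed.

# Coordinate and signal conventions

All positions are meters in a fixed right-handed room frame: origin at a
room corner, x along the long (8.55 m) wall, y along the short (4.30 m)
wall, z up. Angles are degrees; heading 0° points along +x, 90° along +y.
Time is seconds from eye opening (trial start). The trial ends when the body
reference point first crosses the goal-zone border (Chebyshev distance to
the goal center equal to half the goal side); generated recordings store
this time in their metadata, and the analysis can also detect it.

The **body reference point** is the centroid of the four eye-tracker-frame
markers: its horizontal velocity defines heading, and its horizontal
projection defines step speed, the walked trajectory and the goal-border
crossing. It is the one body point that both the kinematic and the gaze
chain need, which is why it anchors all trajectory-related quantities.

# Kinematics

**Filtering.** All marker signals pass a second-order low-pass Butterworth
filter with a 10 Hz cutoff, applied forward and backward (zero phase). The
filter is designed with `signal::butter`; the zero-phase pass is applied to
an odd-reflection-padded copy of the signal (pad of `8 * rate / cutoff`
samples) so start-up transients decay outside the returned span — a constant
signal comes back unchanged to ~1e-15. Velocities are central differences on
the filtered signals (filtering before differentiation).

**Heel strikes.** A strike is a downward-to-upward sign change of the
vertical heel velocity. Automatic cleaning replaces the manual validation a
laboratory would do: (i) the preceding downward swing must reach at least
5 mm/s peak velocity, (ii) candidate events inside detected standing periods
are discarded, and (iii) a 0.3 s per-foot refractory period keeps only the
first event of a cluster. Rule (ii) matters: after 10 Hz filtering, 1 mm
marker noise still leaves roughly 15–20 mm/s of velocity jitter, so a
stationary participant would otherwise generate sign changes that pass rule
(i). Standing periods are maximal intervals with horizontal body speed below
0.1 m/s lasting at least 0.5 s (conventional gait-literature values; both
configurable).

**Phases and steps.** The orientation phase runs from eye opening to the
first heel strike; the navigation phase from there to trial end. A step
spans two consecutive strikes of opposite feet (a same-foot double strike
breaks the sequence). Heading at the step boundaries is read from the
heading series after a 3-sample median smoothing, so a single noisy sample
cannot flip the classification; a step is **straight-ahead** when the
absolute wrapped heading change is strictly below 45° (a 45.0° change is a
turn). Step speed is the chord displacement of the body reference point over
the step duration.

**Per-trial walking speed** is the median of straight-ahead step speeds
after discarding the participant's first and last steps (gait initiation and
termination). A trial needs at least 2 eligible steps for its walking speed
to count as valid; the same rule is applied to the first trial and to the
reference trial.

# Gaze

Gaze is resampled from 60 Hz onto the 120 Hz marker time base — origins
linearly, directions by spherical interpolation so they stay unit norm. Gaps
longer than 200 ms are flagged invalid, never interpolated, and invalid
samples break fixation candidate runs (no bridging). Each sample's ray is
intersected with the room model (nearest forward hit over all surfaces; the
room has no ceiling surface, so upward rays miss and are invalid).

**Fixation detection** is dispersion-based: the dispersion series is the
Euclidean distance between successive intersection points, and the per-trial
threshold is `median + 2 * IQR` of that distribution. Maximal runs of
dispersions strictly below the threshold lasting at least 100 ms become
fixations. Two operationalizations deserve note:

* The phrase "below twice the inter-quartile range from the median" is read
  one-sided, `d < median + 2 * IQR`: dispersion is non-negative and
  fixations are the low-dispersion regime, so the lower band of a literal
  two-sided reading is vacuous. The factor (`dispersion_k`) is configurable.
* If the dispersion distribution is degenerate (a perfectly stationary
  trace has median and IQR both 0), values at or below the median also
  count as fixational; otherwise the strict inequality would reject a
  motionless trace outright.

The threshold is computed per trial — the dispersion distribution is a
property of one trial's recording, not of a participant or session.
Fixations are counted over the whole trial (orientation plus navigation); a
config switch (`fixations_navigation_only`) restricts them to navigation.

**Goal fixations.** A fixation's dominant surface (modal surface id over its
samples) decides membership: panels in the configured goal-area set count
directly; floor hits must additionally fall inside the goal-area floor
polygon (default: the 0.8 m goal zone inflated by 0.8 m per side — the
"panels and ground around the goal zone"). The default goal-area panel set
is every panel within 2.2 m horizontal distance of the goal center; both the
set and the polygon are configurable because the exact extent of "around the
goal zone" is a design choice.

# Learning metrics

**Trajectory efficiency** divides the straight start-to-goal-center distance
by the arc length of the walked polyline (filtered body-reference positions
at 120 Hz, truncated at the border crossing, no simplification). Because the
walk stops at the goal border, values slightly above 1 are possible on very
direct paths and are reported as-is.

**Criterion trial**: the first trial with efficiency strictly above 0.85,
confirmed strictly above 0.85 on the following trial. If no pair qualifies
the last trial is used with a warning — real cohorts reached criterion, but
the function must be total.

**Adaptation index**: with the control profile `C` (per-trial mean of the
young group's metric), multipliers are `M1 = 0`, `Mi = C1/Ci`, and the index
is `sum(Mi * Si)` over trials 1..criterion. Setting `M1 = 0` discards the
naive first trial. Two properties pin the arithmetic down: a participant
whose curve equals the control profile scores exactly `(n-1) * C1`, and
scaling all `C` and `S` by `k` scales the index by `k`. Control profiles are
extended to a ninth trial (two older participants) by carrying the last
value forward; criterion trials never reach that far, so the extension only
serves reference-trial bookkeeping.

**Change in walking speed**: `100 * (ws_ref − ws_first) / ws_ref`, positive
when the participant walked slower on first exposure. The reference is the
last trial when its walking speed is valid; otherwise the penultimate trial,
provided its efficiency exceeds the criterion (participants can start so
close to the goal on the last trial that only one straight step exists);
otherwise the score is missing. The first trial obeys the same validity rule
symmetrically — a missing value is preferred over a guess.

# Statistics

Group comparisons first test normality in both groups (Shapiro–Wilk) and
homogeneity of variance (Levene's test, mean-centered, via `car`), all at
alpha 0.05. If every gate passes, a pooled-variance Student's t-test is
used with Cohen's d (pooled SD); otherwise a Mann–Whitney U test (normal
approximation with continuity correction) with the rank-biserial correlation
`1 − 2U/(n1 n2)`. Zero-variance samples go straight to the U test with a
warning. Correlations are Pearson by default (Spearman by option), with
Bonferroni-corrected alphas declared per family — size 2 for the
adaptation-index pair, size 6 for a visuo-cognitive battery.

# The synthetic cohort

The generator's defaults are the study conditions the pipeline targets: two
groups of 14 participants, 8 learning trials (a 9th for two older
participants), an 8.55 m x 4.30 m room with 19 wall panels and an 0.8 m
goal zone in the northwest quadrant, four start poses cycled pseudo-randomly.

**Trajectory.** Each trial's path is a smooth curve from the start pose to
the goal border: a straight baseline plus one-sided smooth bulges
(`A * sin^2(pi*k*s)` lateral deviation, smallest feasible `k`), with the
amplitude solved so the arc length truncated at the border crossing equals
`dist(start, goal center) / directness`. The pipeline's trajectory
efficiency therefore equals the programmed directness by construction
(within solver tolerance, well under 1%). Amplitude search plus a
containment check raise an error when a directness is geometrically
infeasible from a start pose. The body advances along this path at the
programmed speed after a 0.6 s half-cosine ramp.

**Gait.** Heel strikes alternate feet at the programmed step frequency from
0.45 s after walk onset until the border crossing. Each heel's height is a
rectified-sinusoid swing (`step_height * sin^2` between consecutive
strikes), which puts a downward-to-upward vertical-velocity crossing exactly
at each programmed strike — the simplest signal with unambiguous events.
Measurement noise is additive i.i.d. Gaussian on every marker coordinate
(default 1 mm).

**Learning dynamics.** Directness and goal-fixation probability follow
saturating-exponential trial courses (older: lower start, slower time
constant); cruise speed is constant across trials except the programmed
trial-1 slowdown — older template mean 20%, young 0%, between-participant SD
25 percentage points, i.e. a between-group effect of d = 0.8 on the change
score. Slowdowns are truncated at ±75 points to keep speeds physical.

**Gaze.** Fixation durations are log-normal (median 0.30 s, log-SD 0.4);
each fixation targets the goal area with the programmed per-trial
probability; targets switch instantaneously (the resampling step inserts the
transition samples that become high-dispersion pairs). During a fixation the
ray tracks the fixed surface point from the moving eye, plus 3 mrad angular
noise. Targets are sampled with two realism constraints: successive targets
are at least `saccade_min_separation` apart (so saccades are detectable),
and candidates whose geometric noise amplification (ray length over cosine
of incidence) exceeds 6.5 are resampled — people do not fixate the floor at
grazing distance, and such targets would smear the surface point far beyond
any dispersion threshold. Ground truth records the realized first/last
sample of each fixation, its target surface and its goal flag.

**Seeding.** Every participant draws parameters from a dedicated substream,
and every (participant, trial) pair generates from its own derived seed, so
a trial subset (e.g. only trials 1, 7, 8) is bit-identical to the same
trials of a fully generated cohort. Identical seeds give identical cohorts.

**Coupled mode.** For studying the correlation between the adaptation
indices, the generator has a mode in which the per-participant walking-speed
and directness modulation amplitudes are drawn from a bivariate normal with
a chosen correlation `rho`, while the remaining between-participant
variation is frozen: the cruise speed is common to both groups and the
directness recovery is steep after trial 2, keeping the criterion trial at 3
for the whole amplitude range. Both choices are deliberate: a between-group
speed gap or participant-to-participant criterion-trial variation would add
variance components shared (or unshared) by the two indices and the pooled
correlation would no longer reflect the programmed coupling — the adaptation
index grows roughly linearly with the criterion trial, so a mixture of
criterion trials dominates everything else. In coupled mode the estimated
AI–AI correlation recovers `rho` up to a few percent of measurement
attenuation.

# What the synthetic data does and does not show

The generator emulates the statistical structure the analysis assumes —
detectable heel strikes, a fixation-saccade gaze process, learning curves
crossing the efficiency criterion, group differences of realistic effect
size — with simple parametric shapes: constant cruise speed, sinusoidal-
bulge paths, rectified-sinusoid heel swings, instantaneous saccades,
i.i.d. Gaussian noise. It does not model biomechanics (no joint kinematics,
no double support), vestibular/idiothetic sensing, search strategies,
smooth pursuit, blinks, or temporally correlated tracker noise. Passing
tests therefore demonstrate that the pipeline recovers what it is defined to
measure under its own assumptions — not that those assumptions exhaust real
recordings. The fixation-recovery score, for instance, counts a programmed
fixation as recovered when a detected fixation overlaps at least half of it;
with noisy real data a dispersion threshold occasionally splits a long
fixation in two, and the split halves still count as recovery while their
outer boundaries stay sample-accurate (median boundary error 0 samples in
the test conditions).

# Numerical choices and problem sizes

* Zero-phase filtering pads by `8 * rate / cutoff` samples; series shorter
  than filter warm-up raise an error.
* Path amplitude is solved by `uniroot` to 1e-3 m on the amplitude (length
  error well below 0.1%); the path polyline uses 351 support points.
* Exactly-45° heading changes are not straight; efficiency exactly 0.85
  does not meet the criterion (both strict, per the definitions).
* Ties in the dominant-surface vote resolve to the alphabetically first
  surface id.
* The test suite exercises the statistical layer at the study's own sizes:
  2000 null replicates for the type-I error of the gated comparison, 500
  replicates each for the power and null rates of the change-score
  comparison (generating and analyzing, per replicate, the trials that
  determine the score: first, last, and penultimate when the last is
  invalid), and 100 full-cohort replicates for the coupled-correlation
  recovery. These sizes give Monte-Carlo standard errors of about 0.5-2
  percentage points on the checked rates.

# Known limitations

* Delimited-text recordings only; C3D files must be exported first.
* The goal-area extent ("around the goal zone") is configurable but its
  default is a judgment call; proportions of goal fixations shift with it.
* Walking speed uses chord displacement per step; on strongly curved steps
  it underestimates arc speed by up to ~1% (the straightness filter removes
  the worst cases).
* The criterion-trial fallback (no pair of consecutive trials above
  criterion) returns the last trial with a warning; downstream indices then
  integrate the whole curve, which is only meaningful for cohorts that
  mostly reach criterion.
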