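---
title: "Quantifying behavioral avoidance in immersive VR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral avoidance in immersive VR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batvr)
```

## The measurement problem

Specific phobia is defined by avoidance, yet avoidance is usually assessed
by questionnaire. `batvr` implements an objective alternative: a fully
automated immersive-VR session in which a spider (aversive stimulus) and a
turtle (neutral stimulus) are embedded in three tasks that progressively
reduce the participant's degrees of freedom:

* **Search task** ("fishing"). The participant fishes for two minutes in a
  4.6 m x 4.3 m field after a 10 s wait; the two animals sit centered on
  the left and right border planks. Because the animals are irrelevant to
  the task, where the participant chooses to stand is a pure avoidance
  readout. The task readout is the difference between the minimum
  horizontal pelvis distance to the spider and to the turtle over the
  120 s window; positive values mean the spider was kept farther away.
* **Forced-choice task** ("path choice"). A book must be carried past a
  central table five times; the spider and turtle flank the two possible
  paths, and the book's lateral position (centered, slightly or far
  offset; schedule center/right/left/far-right/far-left) makes one path
  cheaper. Animal sides swap after trials 1 and 3. Outward and return
  journeys are scored separately: each of the ten legs gets the
  exponential cost weight of the chosen side (0 shorter path, 1 equal
  paths, 2 shorter detour, 4 longer detour), signed positive when the
  chosen side is the turtle's. The avoidance score is the sum, ranging
  from -14 (spider side on every leg) to +14 (spider always avoided).
* **Approach task** ("touch the enemy"). After a 10 s countdown the
  participant walks to a table (1.1 m high) and touches the presented
  animal; two spider and two turtle presentations alternate. The readout
  is the time to touch (countdown end to touch) of the first spider trial
  minus the first turtle trial, truncated at 20 s on the upper side.

Within-task detail analyses follow the same contracts: glance counts and
body-orientation angles per stimulus, per-side heart-period (RR) and pupil
means in the search task; path-thirds durations, right-hand
acceleration-change counts (truncated at 100), and pre-touch pupil
(0.5 s) and RR (1 s) windows in the approach task.

Participants are partitioned by a clinical interview and the Fear of
Spiders Questionnaire (FSQ): `phobic` (positive diagnosis), `fearful`
(no diagnosis, FSQ > 8), and `non_fearful` (FSQ <= 8). The cutoff sits
exactly at eight: a score of 8 is non-fearful, 9 is fearful.

## Coordinate and timing conventions

All geometry lives in meters in a right-handed frame with the origin at
the midpoint of the starting long side: `x` spans the field width
(so left/right side membership is `sign(x)`), `z` the depth, `y` is up.
Yaw is in degrees, 0 facing +z, counter-clockwise positive viewed from
above. All streams share one clock in seconds from session start, which
turns every analysis window (10 s wait, 120 s search, 0.5 s and 1 s
pre-touch) into plain interval arithmetic. The participant's position is
the **pelvis** sensor throughout (distances, side occupancy, gate
classification, path thirds): the occupancy definition is explicitly
pelvic, and using a single body point avoids sensor disagreement.
Orientation uses pelvis yaw; a `fishing_orientation()` angle of 0 means
the hips face the stimulus frontally, 180 the back is turned.

## Signal preprocessing

**Pupil.** The chain is: (1) outlier removal — a sample is discarded iff
it is more than 3 scaled median absolute deviations (scaled MAD =
1.4826 x MAD, the normal-consistency constant) from the moving median of
a centered 100-sample window, shrunk at the edges; the inequality is
strict, so a zero-MAD (all-equal) window flags nothing; (2) linear
interpolation of missing runs (outliers and closed eyes), with leading and
trailing gaps taking the nearest valid value; (3) resampling onto a
regular 110 Hz grid by nearest-neighbour lookup; (4) rescaling to
`[0, 1]` by `(v - min)/(max - min)`, with a constant series mapping to 0.
Rescaling is applied per task segment (the segment handed to
`preprocess_pupil()`), so pre-touch means remain comparable within the
approach task regardless of slow drift in other tasks. Blinks are simply
invalid/missing samples; no separate velocity-based blink detector is
used.

**Glances.** A glance at an object is a maximal run of gaze focus on it
after merging interruptions strictly shorter than 200 ms, which are
treated as continuous viewing. Each focus sample covers the interval to
the next sample; the merge is idempotent and is verified against a
brute-force scan in the tests.

**Hand kinematics.** The irregular right-hand track is cubic-spline
resampled to 10 Hz per axis; the number of acceleration changes is the
count of strict sign changes of the second finite difference, summed over
the three axes, truncated at 100. Zeros are ignored, and second
differences below 1e-9 m count as zero so that an exactly straight path
yields 0 despite floating-point residue. Counting per axis and summing is
one of several defensible readings of "sign changes of the second
derivative" for a 3D signal (a magnitude signal or a principal axis would
be alternatives); the per-axis sum was chosen as the simplest
total-variation-like count and is fixed by the tests' oracle.

**RR intervals.** The package consumes beat-timestamped RR series (R-peak
detection is upstream). Intervals outside (0.25, 3.0) s are dropped on
construction. Windowed means render the series as a step function sampled
at 250 Hz — mirroring the storage rate of the upstream export — rather
than beat-weighted averaging; windows before the first beat return a
flagged missing value.

## Statistical layer

Group comparisons follow the scale level of each readout: ANOVA with post
hoc pooled-variance t tests and Pearson correlations for the (continuous)
search and approach readouts; Kruskal-Wallis with Mann-Whitney post hocs
and Spearman correlations for the (ordinal) avoidance score. Effect sizes
follow the conventions of the effect-size toolboxes common in this field:
eta-squared for one-way ANOVAs, Glass' delta (standardizing by the second,
reference group's SD) for two-sample t tests, Hedges' g1 (bias-corrected,
`J = 1 - 3/(4 df - 1)`) for one-sample t tests, and Cohen's U3 for
Mann-Whitney tests. U3 admits variants; here it is fixed as the
proportion of the second sample strictly below the first sample's median,
ties counted half. U is counted over pairs (`sum(a_i > b_j) + ties/2`)
and reported with the `max(U, n1*n2 - U)` convention; p values are exact
for `n1*n2 <= 400` without ties, otherwise normally approximated with tie
and continuity correction.

Repeated-measures designs (glances, orientation, per-side physiology,
path thirds, acceleration changes, pre-touch windows) use a mixed
univariate decomposition with one between factor (group) and one to three
within factors, Type III sums of squares under sum-to-zero contrasts so
that the unbalanced group sizes (15/6/10) are handled, subjects-within-
groups error for between effects and factor-by-subjects strata for within
effects. The SS machinery is delegated to `car::Anova` on a multivariate
linear model; the package computes the effect sizes from the extracted
table: partial eta-squared `SS_e / (SS_e + SS_err(e))` and generalized
eta-squared `SS_e / (SS_e + sum of all error SS in the design)`, which
guarantees `ges <= pes` with equality exactly in single-error-term
(purely between) designs. Note a standard caveat: Type III components
partition the total SS only in balanced designs, so the internal
partition checks draw balanced designs; unbalanced fits are still
validated for the effect-size inequalities.

Partial Spearman correlations (used to control the questionnaire
correlations for FSQ or spider valence) apply the first-order recursion
`(r_xy - r_xz r_yz)/sqrt((1 - r_xz^2)(1 - r_yz^2))` on tie-averaged
ranks, equivalent to correlating rank-regression residuals; p values use
a t reference with `n - 3` degrees of freedom. The questionnaire family
is guarded by a Bonferroni threshold of `0.05/(3 x 54) = 0.00031`
(three behavioral readouts by 54 subjective scales).

Exclusion rules are applied per analysis and logged: participants who
never entered the spider's half are excluded from the orientation
analyses; a participant whose eye is closed throughout the 0.5 s
pre-touch window is excluded from the pre-touch pupil analysis; missing
RR data excludes from the pre-touch RR analysis.

## The synthetic cohort

Because no participant data ship with the package, `generate_cohort()`
produces complete synthetic sessions whose structure mirrors the study
conditions: 15 phobic, 6 fearful, and 10 non-fearful participants, all
sensor streams (90 Hz motion for three sensors, ~110 Hz gaze with timing
jitter, blinks and artifact spikes, beat-event RR series), the event log,
and counterbalanced layouts. One latent aversion scalar per participant
(group means 2.0 / 1.0 / 0.0, SD 0.4, floored at 0) drives every
modality:

* search walk: a bounded drift-diffusion walk with exponential repulsion
  from the spider plank (`gain x aversion x exp(-d)`), a spider-glance
  hazard and a spider-half yaw bias scaling with aversion, RR decreased
  and pupil increased on the spider half;
* forced choice: per-leg logistic choice with utility
  `-0.7 x weight(side) - 2.2 x aversion x [side = spider side]`, so zero
  aversion prefers the cheap path and large aversion approaches the
  all-turtle policy;
* approach: walk speed `v0 exp(-(0.2 + 0.9 frac^2) x aversion_eff)` with
  multiplicative log-normal trial variation, so hesitation concentrates
  in the last third; the second spider presentation multiplies the
  hesitation by `1 - habituation` (default habituation 0.4), emulating
  faster repeated approach; hand tremor amplitude, a pre-touch pupil ramp
  (last 3 s) and an RR dip (last 5 s) scale with the same effective
  aversion.

FSQ totals are drawn rank-preservingly within group from ranges honoring
the cutoff-8 partition (non-fearful 0-8, fearful 9-40, phobic 60-108);
valence ratings and a few ancillary questionnaire scales are generated
with plausible aversion loadings. Gain constants were chosen once for
realistic magnitudes (e.g. smooth turtle approaches yield a few tens of
acceleration sign changes while strong tremor plus long approaches exceed
the cap of 100, and phobic approach differences occasionally exceed the
20 s cap); they target a phobic vs non-fearful separation on the order of
Glass' delta 1.5 and make no claim to reproduce any particular dataset's
test statistics.

What the generator deliberately does **not** emulate: biomechanics (limb
kinematics beyond smooth sway plus tremor), rendering or scene detail,
questionnaire item structure, pupil foreshortening/illuminance effects,
or heart-rate variability structure beyond slow modulation. Passing
recovery tests therefore shows that the pipeline measures what the
generator encodes — direction and approximate strength of
aversion-driven effects — not that it reproduces any empirical dataset.

## Verification strategy and problem sizes

The test suite cross-checks every nontrivial operation against an
independent oracle: glance segmentation against a literal scan-and-merge
(1,000 random focus sequences), Mann-Whitney U against double-loop pair
counting (500 draws), acceleration counts against an explicit
finite-difference loop (100 smooth-plus-jitter trajectories, plus
translation and time-reversal invariance), the moving-median MAD filter
against a literal sliding window, the mixed ANOVA against a
direct-summation decomposition and 200 random balanced designs (SS
partition to 1e-8, `ges <= pes`), and partial Spearman against
rank-regression residuals to 1e-12. Simulation-level checks run 1,000
null cohorts (aversion means all zero, 3 per group, physiology off) and
require each group test to reject at most 7% at alpha = 0.05, and 100
default-size cohorts requiring phobic > non-fearful on all three readouts
at p < 0.05 in at least 90% of replicates with median Spearman
readout-FSQ correlations of at least 0.5. These sizes keep the default
suite within a desktop-scale run while leaving the estimates' Monte Carlo
error well inside the asserted margins.

## Known limitations

* A single latent aversion scalar with task-independent gains makes the
  fearful group intermediate on every readout. Real intermediate-fear
  participants can dissociate across tasks — avoiding strongly when
  avoidance is cheap and task-irrelevant but not when the stimulus is the
  task target. Emulating that would need task-specific gain profiles
  (the `gains` list allows it, but the defaults do not attempt it).
* The gate-crossing classifier assumes one decisive passage per leg;
  pathological trajectories that hover exactly on the gate line fall back
  to the first detected crossing.
* Path thirds split the start-table axis by distance, not by floor area;
  both readings are defensible, and the axis-projection version keeps the
  partition property (durations sum to the time to touch).
* The avoidance-score sign convention anchors positive values to
  avoidance (the `[-14, 14]` range statement); the opposite convention is
  available via `sign_convention = "avoid_negative"`.
* Type III SS do not partition the total in unbalanced designs (see
  above); reported F and effect sizes remain valid.
* The 250 Hz step rendering of RR windows differs from beat-weighted
  averaging by at most one beat fraction at the window edges.
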