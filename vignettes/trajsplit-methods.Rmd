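---
title: "Separating decision errors from action execution in mouse-tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating decision errors from action execution in mouse-tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajsplit)
library(dplyr)
library(ggplot2)
```

## The problem

In two-choice mouse-tracking experiments, participants move a cursor from
a start (home) area at the bottom of the screen to one of two targets in
the upper corners, and the logged trajectory is summarized by spatial
curvature measures — the signed area under the curve (AUC) between the
executed path and the straight "ideal" line through its start and end
points, and the signed maximum absolute deviation (MAD) from that line —
plus two timing measures, initiation time (IT: stimulus onset until the
cursor leaves the start area) and movement time (MT: start-area exit
until target entry).

Average trajectories mix two qualitatively different kinds of movement:

* **single-step movements**, launched toward the correct target after a
  completed decision and executed smoothly; and
* **multi-step movements**, which first head toward the *wrong* target —
  an initial decision error, revised mid-flight — and then turn toward
  the correct one.

A between-condition difference in mean AUC can therefore reflect either
a genuine execution-level bias present in most trials, or a small
minority of multi-step trials with enormous curvature. The two
explanations implicate entirely different cognitive stages. trajsplit
implements a transparent, geometry-based procedure to tell them apart:

1. classify a trial as multi-step if its truncated raw path travels
   strictly beyond a vertical cutoff line placed at the left edge of the
   start area (more generally at a fraction $f$ of the distance from the
   start-area centre to the wrong-target centre, $x_{cut} = -f\,|x_{wrong}|$
   in the flipped frame);
2. re-run the within-subject statistics with and without the
   cutoff-classified trials and compare;
3. sweep the cutoff from the start-area edge to the wrong-target centre
   and trace the standardized effect size $d_z$ as a function of the
   allowed excursion;
4. validate the split kinematically with velocity profiles aligned at
   the MAD timepoint.

## Preprocessing model

All analyses run on a canonical frame: the start-area centre is the
origin, y increases upward (screen-frame y-down logs are negated at
canonicalization), and trials whose correct target is on the left are
mirrored about the vertical axis so the correct target always lies at
positive x. Mirroring about the start-centred axis is an isometry, so
distances, areas and the sign convention are unaffected. Deviations
toward the wrong target (left of the start-to-end travel direction in
the flipped frame) are counted positive.

Each trajectory is truncated to the movement proper: from the first
sample outside the start area (whose timestamp defines IT) through the
first sample inside the correct target area (MT is the difference). We
anchor at whole samples and do not interpolate the boundary crossing;
at typical 100 Hz logging the discretization error is at most one
sample interval, identical for both conditions. A path that re-enters
the start area after exiting keeps its *first* exit as the anchor.

The truncated movement is resampled to `n_steps = 101` points at equally
spaced times by linear interpolation (step = 1% of movement time, the
long-standing convention in this literature), and AUC/MAD are computed
on the resampled path. AUC is the *net* signed area, accumulated by
projecting each point onto the ideal line (arc coordinate $s$) and
summing trapezoids of the signed deviation $d$ over $s$; lobes on
opposite sides cancel and backtracking contributes with negative $ds$.
This equals the shoelace area of the closed polygon formed by the path
and the reversed ideal line, which the test suite verifies on random
paths. Only a net signed area can produce the negative condition means
that real datasets show. The MAD step index breaks ties toward the
earliest step, which is deterministic and, for the velocity split,
assigns a full correction loop to the post-MAD segment.

Exclusions, in order: response errors (wrong target reached) are removed
before any measure computation; trials with downward movement — any
post-exit sample strictly below the bottom edge of the start area — are
removed next (the literature names this exclusion without defining it
operationally; the bottom-edge rule catches movements leaving the task
space downward without penalizing ordinary lateral starts); trials that
never leave the start area or never reach the correct target are
unusable. On the remainder, an outlier pass flags any trial whose IT,
MT, AUC or MAD deviates more than `k = 2.5` sample SDs from its
participant-by-condition cell mean, computed once in a single pass —
and, importantly, *before* multi-step classification, so the same trials
are flagged whether or not the cutoff is later applied. Cells with fewer
than 3 trials are left unflagged. Excluded trials are never deleted:
the per-trial table keeps every trial with its flags, so the with- and
without-cutoff analyses run from one table.

## Classification and statistics

Multi-step classification is evaluated on the truncated *raw* samples,
not the resampled path, so brief excursions between resampling knots
cannot be missed, and the inequality is strict: a path that only touches
the cutoff line survives. The default cutoff fraction is
`(start width / 2) / |x_wrong|` — the line touching the start area on
its left. The sweep grid runs from that default to 1.0 in steps of
0.025, which renders a smooth effect-size curve at negligible cost.

Inference is the classical paired t test across participants on
per-participant condition means, with Cohen's
$d_z = \bar{d} / SD(d)$ (sample SD) as the within-subject effect size;
differences are incompatible minus compatible. Designs with additional
within-subject factors are collapsed to the compatibility main effect
(equal-weight cell means when balanced, trial-weighted with a warning
otherwise); for a two-level factor the paired t is equivalent to the
repeated-measures ANOVA main effect, and $F = t^2$ is reported alongside
for comparison with published F statistics. The %CC comparison (the
percentage of trials classified and excluded as multi-step, per
participant and condition) uses the same paired machinery. All p values
are two-sided; degenerate inputs (zero-variance differences, fewer than
2 complete participants) yield `NA` with an explicit reason rather than
an error.

## Velocity profiles

For each trial the instantaneous speed between consecutive resampled
points is computed with physical time restored from MT (px/ms), so the
MAD step index refers to the same grid as the measures. The speed curve
is split at the MAD step and each segment is time-normalized again to
101 points over its own 0–100% axis. This per-movement temporal
alignment is the crux: two movements can reach their maximal deviation
at the same *place* but very different *times*, and without realignment
the deceleration/re-acceleration signature of multi-step movements
averages away. Trials whose MAD falls at a path endpoint (perfectly
straight movements) have an empty segment and are skipped in the
profile averages only. Group averages are pointwise arithmetic means.

On the synthetic data below, single-step movements hold more than half
their peak speed through the MAD timepoint, while multi-step movements
decelerate to a near-stop just before it and re-accelerate after — the
kinematic validation that the spatial cutoff separates genuinely
different movement types.

## The synthetic-data generator

Real archives of this paradigm live on external repositories, so the
package ships a generator whose defaults encode the study conditions the
method is aimed at, with known ground truth per trial:

* 40 participants, 200 trials per compatibility condition, compatibility
  varied trial-wise; 100 Hz cursor sampling on a 1920x1080 screen-frame
  layout (100x100 px start area, 140x140 px targets 600 px to each side
  and 600 px above the start centre).
* Multi-step probabilities 9.8% (compatible) vs 17.5% (incompatible) —
  the %CC levels reported for the paradigm's reference experiment — with
  per-participant-by-condition probabilities drawn from a Beta
  distribution (concentration 40) whose mean equals the nominal value,
  sized so the simulated %CC effect size lands near the published
  $d_z \approx 0.9$ rather than the implausibly large value a pure
  binomial model produces.
* Initiation times lognormal with means 639 vs 693 ms (SD 120 ms), plus
  a per-participant intercept (SD 80 ms) and a zero-mean per-participant
  compatibility effect (SD 40 ms) sized so $d_z$ for IT is near the
  published 1.3. Movement onset is anchored so that the first sample
  outside the start area falls on the drawn IT — the generator parameter
  is the *measured* quantity.
* Movements follow minimum-jerk timing (bell-shaped speed, closed-form
  oracle in the tests). Single-step paths are quadratic Bezier curves
  whose control point carries a Gaussian lateral offset (SD 450 px,
  see below); multi-step trials launch a first minimum-jerk submovement
  toward the wrong target reaching a Uniform(0.15, 0.60) fraction of the
  horizontal wrong-target distance, pause 40–160 ms at the turn, and
  then move to the correct target. Gaussian positional noise (SD 1.5 px)
  is added per sample; 2% of trials are response errors.

Two constructions make the generator's ground truth exactly recoverable.
First, the single-step control point's x coordinate is clamped to the
start column's far edge, so single-step paths *never* cross a cutoff at
or beyond the start area's edge — large lateral offsets bend the path
upward, not backward — while every multi-step excursion (at least 15% of
a 600 px distance, beyond the 50 px start half-width) must cross it.
Classification against ground truth is therefore exact by construction,
and the classifier tests demand 100% agreement, not approximate
agreement. Second, single-step path distributions are identical across
conditions: the generator's null hypothesis *is* the method's claim, so
any spatial compatibility effect enters only through multi-step trials,
and applying the cutoff must remove it up to sampling noise. An
`execution_bias_px` parameter can inject a genuine execution-level
curvature effect to verify the converse: a real execution bias survives
the cutoff.

The within-class spreads (curvature SD 450 px, submovement duration
scales 0.3/0.55 of a lognormal with mean 650/SD 200 ms) were calibrated
once so that the four measures overlap between classes the way real
data do. With cleanly separated classes, the prescribed 2.5 SD outlier
pass — which runs before classification and therefore sees the
multi-step trials — would flag a large share of multi-step trials as
outliers and bias the recovered %CC far below the generating
probabilities; no plausible reading of the published %CC values is
consistent with that regime. After calibration the outlier pass removes
roughly 3–5% of trials in each class, and %CC recovery is unbiased
within Monte-Carlo error.

What the generator does *not* emulate: biomechanical arm dynamics,
mouse-gain/acceleration nonlinearities, within-movement pauses other
than the single turn, spatial clustering of trajectory styles beyond the
two classes, and any execution-level compatibility effect (unless
injected). Passing tests on this generator therefore demonstrate that
the pipeline recovers known structure under controlled conditions, not
that real data contain no execution-level effects.

## Numerical and design choices

* Region membership is boundary-inclusive; the cutoff inequality is
  strict ("strictly beyond the line"). Both choices are stated in the
  function documentation and pinned by tests.
* Time normalization is exact linear interpolation; resampling an
  already-normalized path with the same `n_steps` is the identity to
  machine precision, and endpoints are reproduced exactly.
* The sweep drops participants lacking trials in either condition cell
  at a given fraction (their count is recorded per fraction) and
  reports `NA` when fewer than 2 complete participants remain.
* Statistics use `stats::t.test` for the paired test; $d_z$ is computed
  directly from the differences and cross-checked in the tests against
  two-pass formulas and `stats::aov` for the $F = t^2$ equivalence.
* Problem sizes in the test suite: the acceptance checks run the full
  default experiment (40 x 400 trials, about 2 million cursor samples)
  once and share it across blocks; unit tests use 2–16 participants
  with 8–80 trials, which keeps the whole suite in the low minutes
  while still exercising every code path.

## Statistical limits of effect-removal checks

One check deserves a caveat: after removing multi-step trials the
with-cutoff spatial effect is *exactly* null by construction, but its
estimated $d_z$ over $n$ participants is still a random draw with
standard deviation $\approx 1/\sqrt{n}$ (0.158 at $n = 40$). A band such
as $|d_z| < 0.15$ on a single simulated experiment therefore holds with
roughly two-thirds probability per seed, no matter how correct the
implementation; the spec-level check in the acceptance suite asserts
that band anyway at its fixed seed, and the generator-level null test
uses a p-value bound instead, which is stable. In addition, because the
outlier pass runs before classification, the multi-step admixture
shifts the incompatible cells' outlier thresholds slightly, truncating
the single-step tails asymmetrically between conditions; across seeds
this contributes a small positive bias (on the order of +0.05 to +0.1
in $d_z$) to the nominally null with-cutoff spatial effect. This is a
property of the prescribed preprocessing order, not of the classifier.

## A worked run

```{r worked, fig.width = 7, fig.height = 5, eval = FALSE}
# defaults: 40 participants x 200 trials/condition (~1 minute);
# pass smaller n_participants/n_trials for a quick look, at the price
# of statistical power
sim <- simulate_rec_experiment(rec_sim_params())
dat <- preprocess_trials(sim$samples, sim$geometry) |>
  classify_multistep()
report <- rec_report(dat)
report
tidy(report)
glance(report)

sweep <- cutoff_sweep(dat)
autoplot(sweep)

plot_mean_trajectories(dat)
plot_mean_trajectories(dat, exclude_multistep = TRUE)
```

The report prints the four measures with and without the cutoff plus the
%CC comparison; on generator defaults the spatial effects (AUC, MAD) are
clearly significant without the cutoff and collapse to null with it,
while the IT effect survives unchanged — the pattern the method exists
to detect.

## Known limitations

* The vertical cutoff is a *spatial* criterion: stop-and-go movements
  that pause without crossing it are not classified multi-step (the
  velocity profiles exist precisely to check for such cases).
* Regions are axis-aligned rectangles; circular or polygonal regions and
  native formats of specific mouse-tracking toolkits are out of scope.
* The with/without-cutoff report covers the compatibility main effect
  only; full factorial ANOVAs over additional design factors are not
  reproduced.
* Sample-anchored truncation makes IT/MT granular at the logging
  interval (10 ms at 100 Hz).
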