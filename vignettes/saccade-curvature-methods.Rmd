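---
title: "Measuring distractor-evoked saccade curvature in double-step sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring distractor-evoked saccade curvature in double-step sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccurv)
```

## The paradigm and what the pipeline measures

In a double-step saccade task, an observer fixates a target 15° left or right
of the screen center, then makes two instructed saccades: a first horizontal
saccade to the screen center, and a second vertical saccade to a target 15°
above or below it. On most trials a brief (50 ms) task-irrelevant distractor —
a light, a localized sound, or both — appears at one of the four corners of a
square (±7.5° horizontally and vertically), either shortly before the first
saccade or between the two saccades. Because a salient stimulus registered in
the eye-centered oculomotor map competes with the saccade goal, the second
saccade's trajectory curves systematically away from an effective distractor
location. Comparing curvature between pre-saccadic and inter-saccadic
distractors, and between distractors that the first saccade carries into the
opposite visual hemifield (*inter-hemifield*) or not (*intra-hemifield*),
probes whether the distractor's eye-centered representation is remapped
across the first saccade.

`saccurv` implements the full measurement chain from 1 kHz gaze samples to
condition-level inference, plus a synthetic-data generator that emulates the
experiment so that every stage can be verified against ground truth without
any recorded data.

## The curvature statistic

A trial's second saccade is reduced to a single signed angle:

1. **Rotation.** Gaze samples between saccade onset and offset are expressed
   in a frame whose first axis points from the saccade start to the
   second-saccade target ("along") and whose second axis is the right-hand
   normal ("ortho"). All saccades thus point "upward"; a distractor placed
   clockwise of the saccade target always lies on the positive-ortho side.
2. **Monotonic resampling.** The orthogonal deviation is averaged in 50
   equal-width bins of the along coordinate spanning `[0, amplitude]`. This
   removes non-monotonic sample sequences (dynamic overshoot) and puts every
   trial on a common support. Empty interior bins are filled by linear
   interpolation; the bin count (≈ one bin per millisecond of a typical
   50-ms, 15° saccade at 1 kHz) is configurable.
3. **Baseline normalization.** The mean binned profile of the same
   participant's distractor-absent trials *of the same saccade sequence*
   (left/right fixation × up/down target) is subtracted. Saccade trajectories
   are idiosyncratic — each person curves each sequence differently — and the
   subtraction isolates the distractor's contribution.
4. **Sign convention.** For trials whose distractor was counterclockwise
   relative to the saccade target, the orthogonal coordinate is negated.
   After this step, positive always means "toward the distractor's screen
   position" and negative "away from it".
5. **Curvature angle.** For each interior grid point, the angular deviation
   from the straight chord connecting the first and last trajectory point is
   `atan(d / a)` (perpendicular deviation over along-chord distance). The
   statistic is the median of these angles. Points within 5% of either chord
   end are excluded because the angle is numerically unstable near the start;
   the margin is configurable.

```{r}
traj <- data.frame(grid = c(0, 2.5, 5, 7.5, 10), ortho = c(0, 0.5, 1, 0.5, 0))
curvature_angle(traj)
```

Two readings of the original procedure were genuinely open and are resolved
as follows. First, the resampling averages the *orthogonal* coordinate along
the *saccade-direction* axis — the only reading that yields a monotonic
progress coordinate (averaging along positions per orthogonal value cannot be
monotonic for a curved path). Second, the counterclockwise sign inversion is
applied to the orthogonal coordinate, since only that yields the stated
toward/away semantics; inverting the along coordinate would reverse the
apparent saccade direction instead.

## Saccade detection

Speed is computed from centered finite differences of position, smoothed by a
moving average over 20 consecutive samples (a trailing window, so that
detected onsets mark the first moved sample rather than anticipating it), and
thresholded at `median + 3 SD` of the trial's smoothed speed, with events
kept when they stay above threshold for at least 20 ms. Sub-threshold gaps
shorter than 10 ms are bridged, so dynamic overshoot is not double-counted.

The SD in the threshold is, by default, the robust scaled median absolute
deviation. The classic whole-trial standard deviation is dominated by the
saccade samples themselves: on simulated traces it puts the threshold near
300 deg/s and biases detected onsets ~10 ms late, whereas the MAD tracks the
fixation noise level. (The superficially attractive median-based variance
`median(v²) − median(v)²` is identically zero for a rectified speed series,
because squaring is monotone on positive values.) The classic estimator
remains available (`detection_params(sd_method = "classic")`), and the
threshold is always computed per trial (computing it per block is not
supported; the per-trial choice is surfaced in the configuration).

Because the trailing window integrates ~20 ms of speed before the threshold
is reached, the raw crossing lags the movement start by several
milliseconds. Each onset is therefore refined backward — by at most one
window — to the last sample whose *unsmoothed* speed still sat at the
baseline level (the trial's lower-quartile raw speed, whose noise is
uncorrelated sample-to-sample). On noiseless simulated traces detected
onsets then coincide with ground truth to within ±2 ms, and with 0.05°
position noise the median absolute onset error stays under 5 ms.

## Trial selection and condition taxonomy

A trial enters the analysis only if fixation stayed within 3.5° of the
fixation target for the 200 ms before the saccade targets appeared, the first
saccade started at the fixation target and landed within 3.5° of the screen
center, the second started at the center and landed within 3.5° of its
target, latencies stayed under 400/700 ms, and no tracker dropout (blink)
occurred. Each rejected trial carries exactly one primary reason.

Distractor-present trials are partitioned by timing: *pre-saccadic* if the
distractor ended in the last 150 ms before the first saccade onset (offset in
`[onset₁ − 150, onset₁)`; a distractor still on at saccade onset belongs to
neither window), *inter-saccadic* if it started after the first saccade
offset and ended at least 100 ms before the second saccade onset, and
*excluded* otherwise — in particular distractors too close to the second
saccade to influence its programming. Pre-saccadic trials are further labeled
*inter-hemifield* when the distractor's horizontal position lies between the
fixation position and the screen center, *intra-hemifield* when it lies on
the opposite side. The eye-to-distractor eccentricity differs between these
configurations (`eye_distractor_eccentricity()` reports 10.61° vs 23.72° in
planar screen coordinates; a flat-screen angular variant gives ≈23.6° for the
intra case — both are exposed, and neither matches the ~21° sometimes quoted
for this geometry, whose derivation is unclear).

## Inference

Per-trial curvature angles are aggregated participant-first: participant
means, then a group mean with SEM over participants (consistent with
individual-participant reporting; a trial-level SEM variant is deliberately
not used). Comparisons use a hierarchical bootstrap: 10,000 replicates, each
resampling trials with replacement *within* each participant (keeping every
participant's trial count), then averaging participant means. "Original
values" are therefore per-trial angles with the participant structure kept,
not participant means; resampling participant means instead is available via
`bootstrap_distribution(level = "participant")`. Two conditions are compared
by differencing their replicate vectors and taking
`p = 2 · min(P(d ≥ 0), P(d ≤ 0))`, floored at `2/(n_boot + 1)` so finite
resampling never reports zero. The condition-vs-no-distractor comparison uses
the same scheme. A per-participant median split of first-saccade latencies
(ties alternating between groups, keeping sizes within one) supports the
early/late analysis.

## The synthetic-data generator

`simulate_experiment()` emulates the experiment at the level the analysis
needs: 1 kHz screen-centered gaze in degrees, two-saccade sequences with
raised-cosine speed profiles and a main-sequence duration model
(`2.2 × amplitude + 21` ms), truncated-Gaussian latencies per distractor
modality (means from the reference experiment's printed values, e.g. first
saccades at 172/160/164/179 ms for visual/auditory/audiovisual/no
distractor, second saccades near 480 ms; truncation mirrors the online
400/700 ms abort rule), Gaussian position noise, and distractors drawn
uniformly within the −100…+300 ms onset range, aimed at the pre- or
inter-saccadic window of each trial with a safety margin of a few
milliseconds so that detection jitter cannot flip a trial's intended
condition.

Curvature is injected as a single orthogonal `sin(π·s)` bump — the typical
single-peaked morphology of curved saccades — whose height is calibrated so
that the pipeline's own statistic applied to the noiseless path returns the
requested angle (the monotone angle→height map is built once per geometry and
inverted with a spline; requests in ±10° are honored to well within 0.05°).
Three components compose additively in orthogonal displacement, so baseline
subtraction recovers the evoked component exactly: a per-participant,
per-sequence idiosyncratic bump (SD 1° by default), a trial-to-trial jitter
bump (SD 1.5°), and the distractor-evoked effect looked up per (modality,
realized interval, hemifield). The default effect map uses the reference
experiment's condition means (inter-saccadic −2.65/−0.52/−3.34° for
visual/auditory/audiovisual; pre-saccadic inter-hemifield
−0.76/−0.58/−1.05°; intra-hemifield −1.38/+0.24/−1.15°). Artifacts are
injected at 3% each — blinks as 80 ms runs of missing samples, fixation
breaks as 5° excursions during the pre-target hold, and inaccurate first
landings ~4–5.5° off center — and only flag trials; rows are never dropped,
so table sizes follow a closed form. Every trial carries a ground-truth
record (true saccade times, injected components, realized condition,
artifact flags), and a fixed seed reproduces all tables bit-identically.

Assumptions the original study does not constrain, chosen once for realism
and documented here rather than tuned: the gaze noise SD (0.05°, typical
video-tracker RMS), the within-participant latency SDs (30/50 ms),
between-participant latency SDs taken as the printed SEMs scaled by √8, the
trial-to-trial curvature SD (1.5° — real saccades scatter substantially from
trial to trial; without this the simulated SEMs would be unrealistically
tiny), and the trace support (250 ms before target onset to 80 ms after the
second saccade offset). The generator emulates the statistical structure the
analysis assumes — it does not model oculomotor physiology (no main-sequence
peak-velocity saturation, no pupil or drift dynamics, no head geometry:
sounds are treated as points on the screen plane and no waveform is
synthesized). Passing recovery tests on these data therefore demonstrates
the correctness of the measurement chain, not the validity of the paradigm
on real recordings.

## Numerical choices and degenerate inputs

Zero-amplitude saccades, degenerate chords, all-undefined velocity traces,
negative distractor durations and empty conditions raise errors rather than
propagating quietly. Trials whose second saccade has fewer than 5 samples are
skipped; baselines built from fewer than 5 trials are flagged. Bin assignment
uses a 10⁻⁹ relative tolerance so samples on bin edges stay stable under
rigid motions of the scene. Bootstrap and generator seeds are plain integers;
every stochastic stage restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test-suite's end-to-end checks run at 8 participants × 150 trials per
(modality × timing × sequence) cell for the null-pipeline check, the default
8 × 48 (plus 96 distractor-absent trials per sequence, mirroring the
experiment's 3:1 distractor-to-absent ratio) for effect recovery, and 1,000
simulated experiments at 2,000 bootstrap replicates for type-I calibration —
sizes chosen to keep each group-level SEM a small fraction of the injected
effects while remaining convenient to re-run.

## Known limitations

**The curvature statistic shrinks slightly under measurement noise.** The
median of per-point angular deviations is robust to outliers but not
noise-unbiased: symmetric position noise perturbs each bin's angle with a
scale that grows toward the chord start (`atan(σ/a)`), which shuffles the
rank order of the bin angles and pulls the median toward the dense cluster
of near-zero angles at the chord end. At the default 0.05° gaze noise this
attenuates recovered effect magnitudes by roughly 4% (noiseless recovery is
exact); simulations show the shrinkage declines only slowly as the interior
margin grows, so it is a property of the statistic rather than of the margin
choice. Condition comparisons and p-values are essentially unaffected —
every condition shrinks by the same fraction — but absolute curvature
magnitudes should be read as slight underestimates, in real recordings as
much as in simulation.

The detector is offline and per-trial; microsaccades, drift and pupil
artifacts are out of scope. The sequence-assignment heuristics (first saccade
must approach the center by >5°, second must leave it by >5° with ≥5°
amplitude) are designed for this two-saccade geometry and flag rather than
repair ambiguous trials. The early/late latency split and the hemifield
taxonomy assume the four-corner distractor layout; positions on the vertical
midline are rejected by design.
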