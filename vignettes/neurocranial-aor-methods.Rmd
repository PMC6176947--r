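---
title: "Measuring neurocranial kinematics and locating the axis of rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neurocranial kinematics and locating the axis of rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniokin)
```

## The model

A suction strike is modelled as the relative motion of two rigid
bodies: the **neurocranium**, carrying three or more tracked markers,
and a **body plane**, a reference body averaged from beads on the
fish's flank that moves with the fish but not with cranial expansion.
Both are observed as labelled 3D marker trajectories in millimetres at
a fixed frame rate.

Per-frame poses come from the closed-form orthogonal Procrustes
solution: subtract centroids, decompose the cross-covariance by SVD,
and correct the sign of the last singular direction so that the result
is always a proper rotation. The reflection guard matters in practice:
body-plane beads are nearly coplanar, and an unconstrained fit can
return a mirror image under noise. Markers are weighted equally — with
no information about per-marker tracking quality there is no principled
basis for anything else. Markers missing in a frame are dropped for
that frame (three present markers still give a pose); frames with
fewer are flagged invalid and never interpolated, since interpolation
would fabricate precision that the tracking does not have.

Kinematics are expressed in a **fish-based frame**: X anteroposterior
(positive caudal), Y dorsoventral (positive dorsal), Z mediolateral,
right-handed. The frame is built from the body plane — its normal is
the smallest principal axis of the body-bead reference configuration —
plus two world-frame hints: a long-axis hint (projected into the plane
to give X) and a dorsal hint that resolves which perpendicular is
"mediolateral with Y dorsal". The two-hint construction was a design
choice: a single caudal hint leaves the normal's sign ambiguous, and
any internal tie-break (e.g. picking the sign by a world axis) would
silently break equivariance when the fish swims upside-down or the
scene is re-oriented. Both hints are explicit, logged inputs.

A **joint coordinate system** (JCS) pairs a proximal copy of this frame
fixed to the body plane with a distal copy following the neurocranium;
both coincide at the zero pose. The relative rotation is decomposed as
Z–Y–X Euler angles: **elevation** (about Z, positive dorsal),
**yaw** (about Y, positive to the fish's left), **roll** (about X,
positive clockwise from an anterior view). The Z→Y→X order is a
documented convention, not a measured fact: elevation is the dominant
rotation and should be the unambiguous first angle, and for the angle
magnitudes seen in strikes (elevation ≤ ~40°, yaw/roll a few degrees)
the order changes angles by far less than tracking noise. A gimbal
flag is recorded if |yaw| comes within 1° of 90°, where the sequence
degenerates; fish strikes are nowhere near it.

## Zeroing, onset and summaries

All channels are referenced so that the zero frame has exactly zero
rotation and translation; the zero frame defaults to the frame before
the onset of neurocranial elevation, which is also time zero. Onset
detection needed a rule the data sources do not state: elevation must
exceed **0.5°** and stay above it for **3 consecutive frames** (both
configurable). The threshold sits below the angular equivalent of
~0.12 mm tracking precision over the 20–40 mm marker baselines this
toolkit targets, and the persistence window rejects single-frame
blips. A consequence worth knowing: because the profile is re-zeroed
at the onset frame, the reported peak elevation can sit below the
full rest-to-peak rotation by up to the onset threshold plus one
frame's increment.

Strike summaries use peak magnitudes over the expansive phase
(onset → peak), with yaw and roll taken as absolute values since their
direction is behaviourally arbitrary. Group statistics use the mean of
individual means, with the number of individuals as the sample size.
Durations are frame counts over the frame rate, with no sub-frame
interpolation.

## Locating the axis of rotation

The AOR is found by exploiting a simple identity: for a JCS at origin
$o$ and a motion that is pure rotation $R$ about a point $p$, the
measured translation is $(R - I)(o - p)$ — zero exactly at $o = p$ and
growing linearly with distance from the axis. For a rotation by
$\theta$ about an axis at distance $d$ from the JCS origin the
displacement magnitude is $2d\sin(\theta/2)$, which the test suite
verifies across $\theta \in (0°, 40°]$ and $d \in [0, 30]$ mm.

Candidate JCS origins are laid out on a grid of offsets from the
occiput at **1 mm** spacing (the sampling density is also the
worst-case localization error). The search sweeps anteroposterior
positions minimizing |Y-translation|, then dorsoventral positions at
the best AP position minimizing |X-translation|. Three details were
genuinely open and are resolved as follows:

- **Evaluation frame.** The translation can be read at the
  peak-elevation frame (default — maximal signal-to-noise), as the
  maximum over the expansive phase, or as the RMS over the phase; all
  three are selectable (`policy`).
- **Sweep interaction.** When the true AOR sits a dorsoventral
  distance $\Delta y$ off the sweep's starting level, a single AP pass
  lands $\tan(\theta/2)\,\Delta y$ away from the truth. The two sweeps
  are therefore alternated to a fixed point; each round contracts the
  residual by $\tan^2(\theta/2) \lesssim 0.13$, so convergence takes a
  few rounds. A joint exhaustive 2D mode over the full grid is kept as
  a cross-check (`method = "joint"`), and the test suite asserts the
  two agree.
- **Ties and degeneracy.** Equal minima resolve to the candidate
  closest to the occiput (deterministic and anatomically
  conservative); a minimizer on the grid boundary raises a warning
  (grid too small); a flat translation field is an error (no rotation
  to localize).

The default grid spans −10…+40 mm AP and −20…+20 mm DV around the
occiput, covering the AOR scatter reported for suction feeders of this
size. Estimates are reported in mm from the occiput and normalized by
the V5 centrum length so individuals of different sizes are comparable.

## The 2D Reuleaux estimator

For comparison, the classical planar construction: each landmark's
rest and peak positions define a chord; the perpendicular bisector of
every chord passes through the center of rotation; the intersection of
any two bisectors estimates it, giving $\binom{n}{2}$ estimates for
$n$ landmarks. Landmarks displaced less than 0.1 mm are dropped (a
zero-length chord has no bisector), and pairs whose bisectors are
within 1° of parallel are excluded — such landmarks lie nearly on a
line through the center, and the intersection amplifies tracking error
without bound as the angle closes. Error against a known center is the
mean ± s.e.m. of the per-estimate Euclidean distances.

The 2D method sees only the sagittal projection
(`project_to_sagittal()` drops the mediolateral coordinate), which is
exactly why it degrades under non-planar motion: yaw and roll displace
landmarks out of plane, the projected chords shrink and rotate, and
the bisector intersections scatter. The package's validation
reproduces this: on planar trials the construction is exact to
numerical precision, while on non-planar trials (7° yaw, 3° roll) its
mean error exceeds the 3D grid method's at every AOR offset.

## What the simulator emulates — and what it does not

`simulate_strike()` generates a strike as a smooth rest-to-peak
rotation of the neurocranium markers (and 2D landmarks) about axes
through a specified true AOR, with elevation, yaw and roll composed in
the same fixed Z–Y–X order as the analysis JCS and all three angles
following one schedule. The schedule is smoothstep
($3u^2 - 2u^3$, C¹, no overshoot) by default, linear optionally — the
validation quantities depend only on the final pose, so the schedule
shape is a convention. The default geometry emulates a ~200 mm fish:
four neurocranium beads 20–40 mm apart, five body beads on the flank
plane, six landmarks over a ~40 mm cranium, occiput at the origin,
5 mm centrum. The landmarks are deliberately placed on an arc around
the band of plausible AOR positions so no pair comes near collinear
with any AOR of interest — the placement the Reuleaux geometry itself
demands.

Noise emulates two documented imperfections of video tracking:
iid Gaussian error per marker coordinate (~0.1 mm in practice), and a
smooth bounded per-marker drift of the body beads standing in for
soft-tissue motion (pairwise distance variations below ~0.2 mm,
occasionally up to 1 mm). It does **not** emulate refraction gradients,
marker occlusion patterns, correlated (whole-limb) soft-tissue motion,
or a moving fish — body beads are static at rest plus jitter, with
world-frame invariance of every estimator property-tested separately.
Passing tests on simulated data therefore validate the estimators'
geometry and noise response, not the upstream tracking chain.

The validation design itself (`validation_trials()`) is the 3 × 2
layout used to compare the estimators: AORs at 0, 10 and 20 mm
posterior to the occiput, each with one planar trial (15° elevation
only) and one non-planar trial (15° elevation + 7° yaw + 3° roll),
noise off. With 51 frames per trial the whole suite analyzes in
seconds; the test suite uses 100 additional randomized planar strikes
(9–21 frames each) for the error-bound property, sizes chosen to keep
the default check fast while leaving every per-trial quantity
identical to longer runs (all acceptance quantities are
final-pose-driven).

## Numerical choices and limitations

- Collinearity of a marker configuration is tested on the
  second-largest singular value of the centered configuration
  (relative tolerance 1e-8): any planar set has a zero smallest
  singular value, so the smallest cannot be the criterion.
- Euler extraction clamps `asin` inputs to [−1, 1]; rotations are
  compared in matrix space where possible, since `acos`-based angle
  metrics lose half the available precision near zero.
- All randomness (noise, ensembles) flows from explicit integer seeds;
  the RNG state is restored afterwards.
- One AOR per strike is assumed, as both estimators require; if the
  true axis migrates during the strike, the estimate is an effective
  compromise and the translation minima will not reach zero.
  Instantaneous helical-axis tracking is out of scope.
- The sequential sweep reports its translation-vs-position curves so a
  user can inspect V-shape quality; geometry-sensitive estimates (e.g.
  far-dorsal AORs from shallow translation gradients) are reported as
  measured, with the boundary warning as the only guard.

```{r example}
trials <- validation_trials(n_frames = 21)
trial <- trials$nonplanar_10mm
res <- analyze_strike(trial$trajectories,
                      cranium_ids = trial$marker_groups$neurocranium,
                      body_ids = trial$marker_groups$body_plane,
                      occiput_mm = trial$layout$occiput_mm,
                      centrum_length_mm = trial$layout$centrum_length_mm)
res$aor
res$summary
```
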