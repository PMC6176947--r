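# craniokin

Tools for measuring three-dimensional neurocranial kinematics in
suction-feeding fishes and for locating the axis of rotation (AOR) of
neurocranial elevation from marker-based motion-capture data.

## The problem

Many fishes raise the neurocranium during a suction strike: the skull
rotates dorsally relative to the body about a roughly mediolateral axis,
flexing one or more joints of the anterior vertebral column. Two
questions drive the analysis of such recordings:

1. **How does the skull move?** Neurocranial motion relative to a
   body-fixed reference is decomposed into *elevation* (rotation about
   the mediolateral Z axis), *yaw* (dorsoventral Y axis) and *roll*
   (anteroposterior X axis), plus translations — the standard joint
   coordinate system (JCS) description used in skeletal kinematics
   (XROMM/VROMM workflows).
2. **Where is the axis of rotation?** The AOR is the point about which
   elevation is pure rotation with no translation. Its anteroposterior
   position indicates which intervertebral joints flex.

`craniokin` implements the full workflow from tracked marker
trajectories (frames × markers × XYZ, mm):

- **Rigid-body pose estimation** — per-frame least-squares rigid
  transforms by the closed-form orthogonal Procrustes (Kabsch) solution,
  with a reflection guard, equal marker weights, and flagged (never
  interpolated) gaps; tracking precision is reported as the mean
  standard deviation of intermarker distances, and body-plane
  non-rigidity as per-pair distance variation.
- **JCS kinematics** — a fish-based frame (X caudal, Y dorsal, Z
  mediolateral) built from the body plane; elevation/yaw/roll extracted
  as Z–Y–X Euler angles with anatomical sign conventions; profiles
  zeroed at the onset of elevation; strike summaries using peak
  magnitudes (absolute values for yaw and roll) and mean-of-means
  statistics across individuals.
- **AOR localization** — a grid of candidate JCS placements at 1 mm
  increments: sweeping anteroposterior positions minimizes
  |Y-translation|, then sweeping dorsoventral positions minimizes
  |X-translation|; translation vanishes at the AOR. A joint 2D
  exhaustive mode cross-checks the sweeps. Positions are reported in mm
  from the occiput and normalized to vertebral centrum lengths.
- **2D Reuleaux estimator** — the classical perpendicular-bisector
  construction from landmark positions at rest and peak, all C(n, 2)
  pairwise intersections, with near-parallel bisector pairs excluded.
- **A strike simulator** — smooth rest-to-peak rotations about a known
  AOR with configurable yaw/roll, tracking noise and body-bead
  soft-tissue jitter, providing exact ground truth for validating both
  estimators.

## Worked example

Simulate a non-planar strike (15° elevation, 7° yaw, 3° roll about an
AOR 10 mm caudal to the occiput) with realistic tracking noise, then
run the complete analysis:

```r
library(craniokin)
trial <- simulate_strike(motion_spec(true_aor_mm = c(10, 0, 0),
                                     peak_elevation_deg = 15,
                                     peak_yaw_deg = 7, peak_roll_deg = 3,
                                     planar = FALSE),
                         noise = noise_spec(marker_noise_sd_mm = 0.05,
                                            body_jitter_amplitude_mm = 0.1,
                                            seed = 42))
res <- analyze_strike(trial$trajectories,
                      cranium_ids = trial$marker_groups$neurocranium,
                      body_ids = trial$marker_groups$body_plane,
                      occiput_mm = c(0, 0, 0),
                      centrum_length_mm = 5)
res
```

```
Strike analysis
  tracking precision (neurocranium): 0.0729 mm
  body-plane distance variation: max 0.524 mm
AOR estimate (sweep method, peak policy): 10.00 mm caudal, 0.00 mm dorsal of the occiput
  normalized: (2.000, 0.000) centrum lengths; grid spacing 1 mm
Strike summary: peak elevation 14.78 deg, |yaw| 6.77 deg, |roll| 3.50 deg, expansive phase 82.0 ms (frames 8-49)
```

Reading the output: the intermarker precision (0.07 mm) and body-plane
distance variation (0.52 mm) quantify the injected tracking noise and
soft-tissue jitter; the grid search recovers the true AOR exactly on its
1 mm grid; and the peak rotations match the simulated 15/7/3° within the
noise (elevation reads slightly below 15° because profiles are zeroed at
the detected onset frame, not at absolute rest). `res$profile` holds the
per-frame channels and exports with `write_profile_csv()`.

A command-line front end (`inst/cli/craniokin`) wraps the same
functions: `craniokin simulate|analyze|reuleaux --config cfg.yml`, with
every tunable default echoed to the run log.

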