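#' Ground-truth motion specification for a simulated strike
#'
#' Describes a smooth rest-to-peak rotation of the neurocranium about a
#' fixed axis-of-rotation point, with optional yaw and roll composed in
#' the same fixed Z-Y-X order used by the analysis JCS, all about axes
#' through the true AOR.
#'
#' @param true_aor_mm length-3 AOR position in the fish frame, relative to
#'   the occiput (AP, DV, ML), mm. Typically `c(d, 0, 0)` for an AOR `d`
#'   mm posterior to the occiput.
#' @param peak_elevation_deg total neurocranial elevation, degrees (>= 0).
#' @param peak_yaw_deg,peak_roll_deg total yaw and roll, degrees; forced
#'   to 0 when `planar = TRUE`.
#' @param n_frames number of frames (>= 2), default 51.
#' @param frame_rate_hz recording rate, default 500 Hz.
#' @param interpolation `"smoothstep"` (default; C1 ease-in-out from rest
#'   to peak with no overshoot) or `"linear"`.
#' @param planar if `TRUE`, motion is pure elevation (yaw = roll = 0).
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(true_aor_mm = c(10, 0, 0), peak_elevation_deg = 15,
                        peak_yaw_deg = 0, peak_roll_deg = 0,
                        n_frames = 51, frame_rate_hz = 500,
                        interpolation = c("smoothstep", "linear"),
                        planar = peak_yaw_deg == 0 && peak_roll_deg == 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(true_aor_mm) == 3, n_frames >= 2,
            peak_elevation_deg >= 0, frame_rate_hz > 0)
  if (planar) peak_yaw_deg <- peak_roll_deg <- 0
  structure(list(true_aor_mm = as.numeric(true_aor_mm),
                 peak_elevation_deg = peak_elevation_deg,
                 peak_yaw_deg = peak_yaw_deg, peak_roll_deg = peak_roll_deg,
                 n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz,
                 interpolation = interpolation, planar = planar),
            class = "motion_spec")
}

#' Marker and landmark layout of the simulated fish
#'
#' World coordinates at rest, in mm; the fish frame coincides with the
#' world frame at rest (X caudal, Y dorsal, Z mediolateral) and the
#' occiput sits at the frame origin. Defaults emulate a fish of roughly
#' 200 mm standard length: neurocranium beads 20-40 mm apart anterior to
#' the occiput, four to six body beads on the flank defining the body
#' plane, six landmarks spread over a ~40 mm neurocranium for the 2D
#' method, and a 5 mm vertebral centrum.
#'
#' The default landmarks lie on an arc around the band of candidate AOR
#' positions so that no landmark pair is close to collinear with any AOR
#' of interest — the placement the 2D method's geometry requires.
#'
#' @param neurocranium `>= 3 x 3` matrix of bead positions (mm).
#' @param body_plane `>= 3 x 3` matrix of body-bead positions (mm),
#'   near-planar.
#' @param landmarks `n x 3` matrix of 2D-method landmark positions (mm),
#'   default 6 points.
#' @param occiput_mm occiput position (mm), origin of AOR coordinates.
#' @param centrum_length_mm V5 centrum length for normalization, mm.
#' @return object of class `marker_layout`.
#' @export
marker_layout <- function(
    neurocranium = rbind(c(-38, 12, 3), c(-25, 3, -5),
                         c(-12, 18, 4), c(-8, 5, -2)),
    body_plane = rbind(c(12, 6, 0), c(22, -4, 0), c(30, 10, 0),
                       c(42, 1, 0), c(18, 14, 0)),
    landmarks = rbind(c(-20.6, 25.7, 2), c(-16.5, 14.1, -3),
                      c(-32.3, 12.1, 4), c(-23.9, 2.4, 0),
                      c(-31.6, -5.9, -2), c(-20.1, -10.9, 3)),
    occiput_mm = c(0, 0, 0), centrum_length_mm = 5) {
  neurocranium <- as.matrix(neurocranium)
  body_plane <- as.matrix(body_plane)
  landmarks <- as.matrix(landmarks)
  stopifnot(nrow(neurocranium) >= 3, nrow(body_plane) >= 3,
            ncol(neurocranium) == 3, ncol(body_plane) == 3,
            ncol(landmarks) == 3, length(occiput_mm) == 3,
            centrum_length_mm > 0)
  assert_not_collinear(neurocranium)
  assert_not_collinear(body_plane)
  structure(list(neurocranium = neurocranium, body_plane = body_plane,
                 landmarks = landmarks, occiput_mm = as.numeric(occiput_mm),
                 centrum_length_mm = centrum_length_mm),
            class = "marker_layout")
}

#' Measurement-noise specification
#'
#' Emulates the imperfections of real video tracking: iid Gaussian noise
#' on every marker coordinate (tracking error, of order 0.1 mm in
#' practice) and a smooth per-marker soft-tissue drift of the body beads,
#' which are sutured to skin and do not form a true rigid body (pairwise
#' distance variations typically below 0.2 mm, at most about 1 mm).
#'
#' @param marker_noise_sd_mm sd of iid Gaussian noise per coordinate, mm.
#' @param body_jitter_amplitude_mm peak displacement of the smooth
#'   per-marker body-bead drift, mm.
#' @param seed integer seed making the generated noise reproducible.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(marker_noise_sd_mm = 0,
                       body_jitter_amplitude_mm = 0, seed = 1L) {
  stopifnot(marker_noise_sd_mm >= 0, body_jitter_amplitude_mm >= 0)
  structure(list(marker_noise_sd_mm = marker_noise_sd_mm,
                 body_jitter_amplitude_mm = body_jitter_amplitude_mm,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# rest-to-peak schedule in [0, 1], monotone non-decreasing
motion_schedule <- function(n_frames, interpolation) {
  u <- (seq_len(n_frames) - 1) / (n_frames - 1)
  switch(interpolation,
         smoothstep = 3 * u^2 - 2 * u^3,
         linear = u)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate a suction-feeding strike with known ground truth
#'
#' Generates marker trajectories for a smooth rest-to-peak strike: the
#' neurocranium beads and 2D-method landmarks rotate rigidly about axes
#' through the true AOR (elevation about the mediolateral axis, plus yaw
#' and roll for non-planar motion, composed in the fixed Z-Y-X order with
#' all three angles following the same schedule), while the body-plane
#' beads stay at rest, plus optional soft-tissue jitter. Gaussian tracking
#' noise is added last; ground truth is stored noise-free.
#'
#' @param spec a [motion_spec()].
#' @param layout a [marker_layout()].
#' @param noise a [noise_spec()].
#' @return object of class `simulated_trial`: list with `spec`, `layout`,
#'   `noise`, `trajectories` (a [marker_trajectory_set()] with markers
#'   `nc*`, `bp*`, `lm*`), `truth` (list: `rotations` 3x3xF,
#'   `translations` F x 3 — the noise-free world transform of the
#'   neurocranium relative to the body plane, identity at frame 1 —
#'   plus per-frame `elevation_deg`, `yaw_deg`, `roll_deg`),
#'   `aor_world_mm`, `landmarks_rest`, `landmarks_peak` (noise-free
#'   `n x 3`).
#' @examples
#' trial <- simulate_strike(motion_spec(peak_elevation_deg = 15))
#' trial$truth$elevation_deg[trial$spec$n_frames]
#' @export
simulate_strike <- function(spec = motion_spec(), layout = marker_layout(),
                            noise = noise_spec()) {
  stopifnot(inherits(spec, "motion_spec"), inherits(layout, "marker_layout"),
            inherits(noise, "noise_spec"))
  nf <- spec$n_frames
  s <- motion_schedule(nf, spec$interpolation)
  ele <- spec$peak_elevation_deg * s
  yaw <- spec$peak_yaw_deg * s
  rol <- spec$peak_roll_deg * s
  p <- layout$occiput_mm + spec$true_aor_mm   # AOR point, world coords

  nc_ids <- paste0("nc", seq_len(nrow(layout$neurocranium)))
  bp_ids <- paste0("bp", seq_len(nrow(layout$body_plane)))
  lm_ids <- paste0("lm", seq_len(nrow(layout$landmarks)))
  ids <- c(nc_ids, bp_ids, lm_ids)
  nm <- length(ids)
  pos <- array(NA_real_, dim = c(nf, nm, 3))
  rot <- array(NA_real_, dim = c(3, 3, nf))
  trans <- matrix(NA_real_, nf, 3)

  moving <- rbind(layout$neurocranium, layout$landmarks)
  mov_idx <- c(seq_along(nc_ids), length(nc_ids) + length(bp_ids) +
                 seq_along(lm_ids))
  bp_idx <- length(nc_ids) + seq_along(bp_ids)
  for (f in seq_len(nf)) {
    R <- compose_eyr(ele[f], yaw[f], rol[f])
    tr <- as.numeric(p - R %*% p)
    rot[, , f] <- R
    trans[f, ] <- tr
    pos[f, mov_idx, ] <- sweep(moving %*% t(R), 2, tr, "+")
    pos[f, bp_idx, ] <- layout$body_plane
  }
  lm_rest <- sweep(layout$landmarks %*% t(rot[, , 1]), 2, trans[1, ], "+")
  lm_peak <- sweep(layout$landmarks %*% t(rot[, , nf]), 2, trans[nf, ], "+")

  if (noise$marker_noise_sd_mm > 0 || noise$body_jitter_amplitude_mm > 0) {
    pos <- with_seed(noise$seed, {
      if (noise$body_jitter_amplitude_mm > 0) {
        tt <- (seq_len(nf) - 1) / max(1, nf - 1)
        for (m in bp_idx) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          freq <- stats::runif(1, 0.5, 1.5)
          phase <- stats::runif(1, 0, 2 * pi)
          amp <- noise$body_jitter_amplitude_mm * sin(2 * pi * freq * tt + phase)
          pos[, m, ] <- pos[, m, ] + outer(amp, dir)
        }
      }
      if (noise$marker_noise_sd_mm > 0)
        pos <- pos + stats::rnorm(length(pos), sd = noise$marker_noise_sd_mm)
      pos
    })
  }

  trj <- marker_trajectory_set(pos, ids, spec$frame_rate_hz)
  structure(list(spec = spec, layout = layout, noise = noise,
                 trajectories = trj,
                 truth = list(rotations = rot, translations = trans,
                              elevation_deg = ele, yaw_deg = yaw,
                              roll_deg = rol),
                 aor_world_mm = as.numeric(p),
                 landmarks_rest = lm_rest, landmarks_peak = lm_peak,
                 marker_groups = list(neurocranium = nc_ids,
                                      body_plane = bp_ids,
                                      landmarks = lm_ids)),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulated strike: %d frames @ %g Hz, AOR (%g, %g, %g) mm from occiput\n",
    "  peaks: elevation %g, yaw %g, roll %g deg (%s); noise sd %g mm,",
    " jitter %g mm\n"),
    x$spec$n_frames, x$spec$frame_rate_hz, x$spec$true_aor_mm[1],
    x$spec$true_aor_mm[2], x$spec$true_aor_mm[3],
    x$spec$peak_elevation_deg, x$spec$peak_yaw_deg, x$spec$peak_roll_deg,
    if (x$spec$planar) "planar" else "non-planar",
    x$noise$marker_noise_sd_mm, x$noise$body_jitter_amplitude_mm))
  invisible(x)
}

#' The six-trial validation design for the AOR methods
#'
#' Generates the 3 x 2 design used to compare the 2D and 3D estimators:
#' AORs at 0, 10 and 20 mm posterior to the occiput, each simulated once
#' with planar motion (15 degrees of neurocranial elevation only) and once
#' with non-planar motion (15 degrees of elevation plus 7 degrees of yaw
#' and 3 degrees of roll), noise off.
#'
#' @param layout a [marker_layout()].
#' @param n_frames frames per trial, default 51.
#' @param frame_rate_hz default 500.
#' @return named list of six `simulated_trial` objects
#'   (`planar_0mm`, `nonplanar_0mm`, ..., `nonplanar_20mm`).
#' @export
validation_trials <- function(layout = marker_layout(), n_frames = 51,
                              frame_rate_hz = 500) {
  offsets <- c(0, 10, 20)
  out <- list()
  for (d in offsets) {
    for (kind in c("planar", "nonplanar")) {
      spec <- motion_spec(
        true_aor_mm = c(d, 0, 0), peak_elevation_deg = 15,
        peak_yaw_deg = if (kind == "nonplanar") 7 else 0,
        peak_roll_deg = if (kind == "nonplanar") 3 else 0,
        n_frames = n_frames, frame_rate_hz = frame_rate_hz,
        planar = kind == "planar")
      out[[paste0(kind, "_", d, "mm")]] <-
        simulate_strike(spec, layout, noise_spec())
    }
  }
  out
}

#' Ensemble of randomized simulated strikes
#'
#' Draws `n` trials with AOR positions and peak rotations sampled
#' uniformly from the given ranges, under a single seed, for
#' property-style testing of the estimators.
#'
#' @param n number of trials.
#' @param seed integer seed; the whole ensemble is deterministic in it.
#' @param ap_range_mm,dv_range_mm ranges for the true AOR position
#'   relative to the occiput, mm.
#' @param elevation_range_deg range for peak elevation, degrees.
#' @param yaw_range_deg,roll_range_deg ranges for peak yaw/roll; ignored
#'   when `planar = TRUE`.
#' @param planar if `TRUE` (default) trials are pure elevation.
#' @param n_frames frames per trial.
#' @param noise a [noise_spec()]; its seed is re-drawn per trial from the
#'   ensemble seed.
#' @param layout a [marker_layout()].
#' @return list of `simulated_trial` objects.
#' @export
simulate_strike_ensemble <- function(n, seed = 1L,
                                     ap_range_mm = c(-5, 35),
                                     dv_range_mm = c(-10, 10),
                                     elevation_range_deg = c(5, 30),
                                     yaw_range_deg = c(0, 8),
                                     roll_range_deg = c(0, 4),
                                     planar = TRUE, n_frames = 21,
                                     noise = noise_spec(),
                                     layout = marker_layout()) {
  stopifnot(n >= 1)
  params <- with_seed(seed, data.frame(
    ap = stats::runif(n, ap_range_mm[1], ap_range_mm[2]),
    dv = stats::runif(n, dv_range_mm[1], dv_range_mm[2]),
    ele = stats::runif(n, elevation_range_deg[1], elevation_range_deg[2]),
    yaw = if (planar) 0 else stats::runif(n, yaw_range_deg[1], yaw_range_deg[2]),
    rol = if (planar) 0 else stats::runif(n, roll_range_deg[1], roll_range_deg[2]),
    sub_seed = sample.int(.Machine$integer.max, n)))
  lapply(seq_len(n), function(i) {
    ns <- noise
    ns$seed <- params$sub_seed[i]
    simulate_strike(
      motion_spec(true_aor_mm = c(params$ap[i], params$dv[i], 0),
                  peak_elevation_deg = params$ele[i],
                  peak_yaw_deg = params$yaw[i],
                  peak_roll_deg = params$rol[i],
                  n_frames = n_frames, planar = planar),
      layout, ns)
  })
}

#' Write a simulated trial's ground truth to a sidecar CSV
#'
#' @param trial a `simulated_trial`.
#' @param path output CSV path (columns: frame, truth angles, true AOR).
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(trial, path) {
  nf <- trial$spec$n_frames
  df <- data.frame(frame = seq_len(nf),
                   elevation_deg = trial$truth$elevation_deg,
                   yaw_deg = trial$truth$yaw_deg,
                   roll_deg = trial$truth$roll_deg,
                   aor_ap_mm = trial$spec$true_aor_mm[1],
                   aor_dv_mm = trial$spec$true_aor_mm[2],
                   aor_ml_mm = trial$spec$true_aor_mm[3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
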