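#' Anatomical coordinate system
#'
#' An origin plus a proper orthonormal axis triad fixed to a rigid body in
#' anatomically meaningful orientation. Columns of `axes` are the X
#' (anteroposterior, positive caudal), Y (dorsoventral, positive dorsal)
#' and Z (mediolateral) unit vectors, expressed in world coordinates at
#' the frame the ACS was constructed in.
#'
#' @param origin length-3 origin (mm, world coordinates).
#' @param axes 3x3 proper orthogonal matrix, columns = X, Y, Z axes.
#' @param parent_body label of the body the ACS is fixed to.
#' @return object of class `acs`.
#' @export
acs <- function(origin, axes, parent_body = "") {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3)
  if (!is_rotation(axes, tol = 1e-9))
    stop("axes must be proper orthonormal (det = +1)")
  structure(list(origin = origin, axes = axes, parent_body = parent_body),
            class = "acs")
}

#' Build the fish-based frame from body-plane and neurocranium poses
#'
#' Constructs the pair of coincident anatomical coordinate systems (the
#' proximal one fixed to the body plane, the distal one following the
#' neurocranium) aligned with the long axis of the fish. The X-axis is the
#' anteroposterior axis, positive caudal, obtained by projecting
#' `long_axis_hint` into the body plane; the Z-axis is the body-plane
#' normal (mediolateral); the Y-axis (dorsoventral, positive dorsal)
#' completes the right-handed triad.
#'
#' The plane normal is taken from the body's reference marker
#' configuration (its smallest principal axis) and carried through the
#' body pose; its sign — which of the two perpendiculars is "mediolateral
#' such that Y points dorsal" — is resolved against `dorsal_hint`. With
#' both hints supplied in world coordinates the construction is
#' equivariant under rigid motion of the whole scene.
#'
#' @param body_pose `pose` of the body plane at the frame of interest.
#' @param cranium_pose `pose` of the neurocranium at the same frame (kept
#'   for symmetry of the interface; the frame is anchored on the body
#'   plane).
#' @param long_axis_hint length-3 world vector pointing roughly caudal.
#' @param dorsal_hint length-3 world vector pointing roughly dorsal
#'   (default world +Y); must not be perpendicular to the plane's
#'   dorsoventral direction.
#' @param body_def [rigid_body_def()] of the body plane, source of the
#'   plane normal. If `NULL`, the body pose's local Z-axis is used as the
#'   normal.
#' @param origin world-coordinate origin for the frame (mm), typically the
#'   occiput; default the body pose translation.
#' @return list of class `fish_frame` with `proximal` and `distal` [acs()]
#'   objects (identical at construction) and the `normal` used.
#' @export
build_fish_frame <- function(body_pose, cranium_pose = NULL, long_axis_hint,
                             body_def = NULL, origin = NULL,
                             dorsal_hint = c(0, 1, 0)) {
  stopifnot(inherits(body_pose, "pose"))
  hint <- as.numeric(long_axis_hint)
  stopifnot(length(hint) == 3)
  if (!is.null(body_def)) {
    normal_ref <- plane_normal_reference(body_def$reference_positions)
    normal <- as.numeric(body_pose$rotation %*% normal_ref)
  } else {
    normal <- body_pose$rotation[, 3]
  }
  normal <- normal / sqrt(sum(normal^2))
  x <- hint - sum(hint * normal) * normal
  nx <- sqrt(sum(x^2))
  if (nx < 1e-8 * sqrt(sum(hint^2)))
    stop("degenerate frame: long-axis hint is parallel to the plane normal")
  x <- x / nx
  y <- cross3(normal, x)
  dh <- sum(y * as.numeric(dorsal_hint))
  if (abs(dh) < 1e-8 * sqrt(sum(as.numeric(dorsal_hint)^2)))
    stop("degenerate frame: dorsal hint perpendicular to the dorsoventral axis")
  if (dh < 0) {       # flip the normal so Y points dorsal
    normal <- -normal
    y <- -y
  }
  axes <- cbind(X = x, Y = y, Z = normal)
  if (is.null(origin)) origin <- body_pose$translation
  a <- acs(origin, axes, parent_body = "body_plane")
  structure(list(proximal = a,
                 distal = acs(origin, axes, parent_body = "neurocranium"),
                 normal = normal),
            class = "fish_frame")
}

# unit normal of a near-planar configuration, in the same coordinates as
# pts; canonical sign: positive component on its largest-magnitude axis
plane_normal_reference <- function(pts) {
  ctr <- scale(as.matrix(pts), center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  n <- sv$v[, 3]
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Joint coordinate system
#'
#' Pairs a proximal ACS (fixed to the body plane) with a distal ACS
#' (following the neurocranium). Both coincide at the zero pose; the JCS
#' then measures rotations (elevation about Z, yaw about Y, roll about X,
#' applied in that fixed order) and translations of the distal relative to
#' the proximal system.
#'
#' @param frame a `fish_frame` from [build_fish_frame()], or an [acs()].
#' @param origin optional world origin overriding the frame's (mm); this
#'   is how candidate JCS placements are generated in the AOR grid search.
#' @param rotation_order fixed Euler sequence label; only `"ZYX"`
#'   (elevation, then yaw, then roll) is implemented.
#' @return object of class `jcs` with `origin`, `axes`, `rotation_order`.
#' @export
joint_coordinate_system <- function(frame, origin = NULL,
                                    rotation_order = "ZYX") {
  a <- if (inherits(frame, "fish_frame")) frame$proximal else frame
  stopifnot(inherits(a, "acs"))
  rotation_order <- match.arg(rotation_order)
  if (is.null(origin)) origin <- a$origin
  structure(list(origin = as.numeric(origin), axes = a$axes,
                 rotation_order = rotation_order),
            class = "jcs")
}

# world motion of a body from frame `from` to frame `to`:
# x -> Q x + q, built from the pose series
frame_motion <- function(ps, from, to) {
  R0 <- ps$rotations[, , from]
  R1 <- ps$rotations[, , to]
  t0 <- ps$translations[from, ]
  t1 <- ps$translations[to, ]
  Q <- R1 %*% t(R0)
  list(Q = Q, q = t1 - Q %*% t0)
}

#' Decompose neurocranium motion relative to the body plane
#'
#' For every frame, the rigid transform of the distal (neurocranium) ACS
#' relative to the proximal (body plane) ACS is computed and expressed as
#' the three anatomical rotations — elevation (Z), yaw (Y), roll (X), in
#' degrees, fixed Z-Y-X order — and the three origin translations in JCS
#' axes (mm). All channels are referenced to `zero_frame`: that frame has
#' exactly zero rotation and zero translation. Sign conventions: positive
#' elevation is dorsal rotation of the head, positive yaw turns the head
#' to the fish's left, positive roll is clockwise seen from anterior.
#'
#' A warning flag is recorded when the yaw angle comes within 1 degree of
#' 90 degrees (gimbal proximity of the Euler sequence).
#'
#' @param jcs a [joint_coordinate_system()], placed at `zero_frame`.
#' @param cranium `pose_series` of the neurocranium.
#' @param body `pose_series` of the body plane.
#' @param zero_frame frame index defining the zero pose (default 1).
#' @return object of class `kinematic_profile`: a data.frame with columns
#'   `frame`, `time_s`, `elevation_deg`, `yaw_deg`, `roll_deg`, `tx_mm`,
#'   `ty_mm`, `tz_mm`, plus attributes `zero_frame`, `onset_frame`,
#'   `peak_frame` (NA until [detect_expansive_phase()] is applied; see
#'   [annotate_expansive_phase()]), `frame_rate`, `gimbal_frames`.
#' @export
measure_motion <- function(jcs, cranium, body, zero_frame = 1) {
  stopifnot(inherits(jcs, "jcs"), inherits(cranium, "pose_series"),
            inherits(body, "pose_series"))
  nf <- n_poses(cranium)
  if (n_poses(body) != nf)
    stop("cranium and body pose series differ in length")
  if (zero_frame < 1 || zero_frame > nf) stop("invalid zero_frame")
  if (!cranium$valid[zero_frame] || !body$valid[zero_frame])
    stop("zero_frame has no valid pose for both bodies")
  A <- jcs$axes
  o <- jcs$origin
  ang <- matrix(NA_real_, nf, 3)
  tr <- matrix(NA_real_, nf, 3)
  gimbal <- logical(nf)
  for (f in seq_len(nf)) {
    if (!cranium$valid[f] || !body$valid[f]) next
    gb <- frame_motion(body, zero_frame, f)
    gc <- frame_motion(cranium, zero_frame, f)
    R_rel <- t(A) %*% t(gb$Q) %*% gc$Q %*% A
    t_rel <- t(A) %*% t(gb$Q) %*% ((gc$Q - gb$Q) %*% o + gc$q - gb$q)
    e <- decompose_eyr(R_rel)
    ang[f, ] <- c(e$elevation, e$yaw, e$roll)
    gimbal[f] <- e$gimbal
    tr[f, ] <- t_rel
  }
  if (any(gimbal))
    warning("gimbal proximity (|yaw| within 1 deg of 90) in ",
            sum(gimbal), " frame(s)")
  fr <- cranium$frame_rate
  out <- data.frame(frame = seq_len(nf),
                    time_s = (seq_len(nf) - zero_frame) / fr,
                    elevation_deg = ang[, 1], yaw_deg = ang[, 2],
                    roll_deg = ang[, 3],
                    tx_mm = tr[, 1], ty_mm = tr[, 2], tz_mm = tr[, 3])
  structure(out,
            class = c("kinematic_profile", "data.frame"),
            zero_frame = zero_frame, onset_frame = NA_integer_,
            peak_frame = NA_integer_, frame_rate = fr,
            gimbal_frames = which(gimbal))
}

#' @export
print.kinematic_profile <- function(x, ...) {
  on <- attr(x, "onset_frame")
  pk <- attr(x, "peak_frame")
  cat(sprintf("Kinematic profile: %d frames @ %g Hz, zero frame %d\n",
              nrow(x), attr(x, "frame_rate"), attr(x, "zero_frame")))
  if (!is.na(on))
    cat(sprintf("  expansive phase: onset frame %d, peak frame %d (peak elevation %.2f deg)\n",
                on, pk, x$elevation_deg[pk]))
  NextMethod()
  invisible(x)
}

#' Detect the expansive phase from an elevation trace
#'
#' The expansive phase runs from the onset to the peak of neurocranial
#' elevation. Onset is the last frame before the elevation first exceeds
#' `threshold_deg` and stays above it for `persistence` consecutive
#' frames (a persistence window rejects single-frame noise blips); the
#' peak is the frame of maximum elevation after onset.
#'
#' @param elevation_deg numeric elevation trace (degrees), length >= 3,
#'   referenced to the resting pose.
#' @param threshold_deg onset threshold, default 0.5 deg.
#' @param persistence number of consecutive frames that must exceed the
#'   threshold, default 3.
#' @return list with integer `onset_frame` and `peak_frame`.
#' @export
detect_expansive_phase <- function(elevation_deg, threshold_deg = 0.5,
                                   persistence = 3) {
  ele <- as.numeric(elevation_deg)
  n <- length(ele)
  if (n < 3) stop("elevation trace must have at least 3 frames")
  persistence <- max(1L, as.integer(persistence))
  above <- !is.na(ele) & ele > threshold_deg
  first <- NA_integer_
  if (n >= persistence) {
    run <- stats::filter(as.numeric(above), rep(1, persistence),
                         sides = 1)
    hit <- which(!is.na(run) & run == persistence)
    if (length(hit)) first <- hit[1] - persistence + 1L
  }
  if (is.na(first))
    stop("no strike: elevation never exceeds ", threshold_deg,
         " deg for ", persistence, " consecutive frames")
  onset <- max(1L, first - 1L)
  tail <- ele[(onset + 1L):n]
  peak <- onset + which.max(ifelse(is.na(tail), -Inf, tail))
  list(onset_frame = onset, peak_frame = as.integer(peak))
}

#' Annotate a kinematic profile with its expansive phase
#'
#' Runs [detect_expansive_phase()] on the profile's elevation channel and
#' stores onset/peak frames in the profile's attributes.
#'
#' @param profile a `kinematic_profile`.
#' @inheritParams detect_expansive_phase
#' @return the profile with `onset_frame` and `peak_frame` attributes set.
#' @export
annotate_expansive_phase <- function(profile, threshold_deg = 0.5,
                                     persistence = 3) {
  ph <- detect_expansive_phase(profile$elevation_deg, threshold_deg,
                               persistence)
  attr(profile, "onset_frame") <- ph$onset_frame
  attr(profile, "peak_frame") <- ph$peak_frame
  profile
}

#' Summarize a strike over its expansive phase
#'
#' Peak magnitudes attained during the expansive phase: maximum elevation,
#' and maxima of the absolute values of yaw and roll (directionality is
#' ignored for those two channels), plus the phase duration.
#'
#' @param profile a `kinematic_profile` with onset/peak annotated (see
#'   [annotate_expansive_phase()]).
#' @return object of class `strike_summary`: list with `peak_elevation_deg`,
#'   `peak_abs_yaw_deg`, `peak_abs_roll_deg`, `expansive_duration_ms`,
#'   `onset_frame`, `peak_frame`.
#' @export
summarize_strike <- function(profile) {
  on <- attr(profile, "onset_frame")
  pk <- attr(profile, "peak_frame")
  if (is.na(on) || is.na(pk))
    stop("profile has no expansive phase; run annotate_expansive_phase()")
  fr <- attr(profile, "frame_rate")
  win <- on:pk
  structure(list(
    peak_elevation_deg = max(profile$elevation_deg[win], na.rm = TRUE),
    peak_abs_yaw_deg = max(abs(profile$yaw_deg[win]), na.rm = TRUE),
    peak_abs_roll_deg = max(abs(profile$roll_deg[win]), na.rm = TRUE),
    expansive_duration_ms = (pk - on) / fr * 1000,
    onset_frame = on, peak_frame = pk),
    class = "strike_summary")
}

#' @export
print.strike_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Strike summary: peak elevation %.2f deg, |yaw| %.2f deg, ",
    "|roll| %.2f deg, expansive phase %.1f ms (frames %d-%d)\n"),
    x$peak_elevation_deg, x$peak_abs_yaw_deg, x$peak_abs_roll_deg,
    x$expansive_duration_ms, x$onset_frame, x$peak_frame))
  invisible(x)
}

#' Mean of individual means with standard error
#'
#' Per-strike values are first averaged within each individual, then the
#' group mean and s.e.m. are computed over the individual means, so the
#' sample size is the number of individuals, not the number of strikes.
#'
#' @param values numeric per-strike values.
#' @param individual factor/character of the same length assigning each
#'   strike to an individual.
#' @return list with `mean`, `sem` (`NA` when only one individual),
#'   `n_individuals`, and `individual_means` (named vector).
#' @examples
#' mean_of_means(c(2, 4, 6), c("A", "A", "B"))  # mean (3 + 6) / 2 = 4.5
#' @export
mean_of_means <- function(values, individual) {
  stopifnot(length(values) == length(individual))
  if (length(values) == 0) stop("empty group")
  if (anyNA(values)) stop("NA values")
  im <- tapply(values, individual, mean)
  im <- stats::setNames(as.numeric(im), names(im))
  n <- length(im)
  list(mean = mean(im),
       sem = if (n > 1) stats::sd(im) / sqrt(n) else NA_real_,
       n_individuals = n,
       individual_means = im)
}

#' Export a kinematic profile as tidy CSV
#'
#' @param profile a `kinematic_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
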