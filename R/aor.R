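#' Candidate grid for JCS placement
#'
#' Ranges are anteroposterior (positive caudal) and dorsoventral (positive
#' dorsal) offsets from the occiput, in mm, sampled at `spacing_mm`
#' increments. The defaults cover the span of axis-of-rotation positions
#' seen in suction-feeding fishes of the sizes this toolkit targets.
#'
#' @param ap_range_mm length-2 anteroposterior range, mm.
#' @param dv_range_mm length-2 dorsoventral range, mm.
#' @param spacing_mm grid increment, mm (default 1). The grid spacing is
#'   also the worst-case localization error of the grid search.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(ap_range_mm = c(-10, 40), dv_range_mm = c(-20, 20),
                      spacing_mm = 1) {
  stopifnot(length(ap_range_mm) == 2, length(dv_range_mm) == 2,
            spacing_mm > 0, diff(ap_range_mm) > 0, diff(dv_range_mm) > 0)
  structure(list(ap_range_mm = as.numeric(ap_range_mm),
                 dv_range_mm = as.numeric(dv_range_mm),
                 spacing_mm = spacing_mm),
            class = "grid_spec")
}

grid_axis <- function(range, spacing) seq(range[1], range[2], by = spacing)

# JCS translation at one frame for many candidate origins.
# For origins O (3 x m) the relative translation is affine: T = M O + v.
# Returns 3 x m matrix of translations in JCS axes.
jcs_translation_field <- function(A, cranium, body, zero_frame, frame,
                                  origins) {
  gb <- frame_motion(body, zero_frame, frame)
  gc <- frame_motion(cranium, zero_frame, frame)
  M <- t(A) %*% t(gb$Q) %*% (gc$Q - gb$Q)
  v <- as.numeric(t(A) %*% t(gb$Q) %*% (gc$q - gb$q))
  M %*% origins + v
}

# translation objective per candidate under the evaluation-frame policy:
# "peak"  |t| at the peak-elevation frame,
# "max"   max |t| over the expansive phase,
# "rms"   root-mean-square |t| over the expansive phase.
# `component`: 1 = X, 2 = Y, or 1:2 for the joint in-plane magnitude.
translation_objective <- function(A, cranium, body, zero_frame, frames,
                                  peak_frame, origins, component,
                                  policy = c("peak", "max", "rms")) {
  policy <- match.arg(policy)
  eval_frames <- switch(policy, peak = peak_frame, frames)
  acc <- NULL
  for (f in eval_frames) {
    tf <- jcs_translation_field(A, cranium, body, zero_frame, f, origins)
    mag <- sqrt(colSums(tf[component, , drop = FALSE]^2))
    acc <- if (is.null(acc)) rbind(mag) else rbind(acc, mag)
  }
  switch(policy,
         peak = acc[1, ],
         max = apply(acc, 2, max),
         rms = sqrt(colMeans(acc^2)))
}

#' Locate the axis of rotation by a grid of joint coordinate systems
#'
#' Implements translation minimization over candidate JCS placements: a
#' JCS placed away from the true axis of rotation (AOR) measures spurious
#' translation proportional to its distance from the axis, and zero
#' translation exactly at the AOR. Candidate placements are sampled on a
#' grid of anteroposterior (AP) and dorsoventral (DV) offsets from the
#' occiput in the fish frame.
#'
#' `method = "sweep"` follows the two-sweep procedure: sample AP positions
#' and pick the one minimizing |Y-translation|, then sample DV positions at
#' that AP position minimizing |X-translation|. The two sweeps are
#' alternated until the minimizer stops moving (they interact when the AOR
#' lies off the starting DV level; the interaction contracts geometrically,
#' so a few rounds suffice). `method = "joint"` evaluates the full 2D grid
#' against the in-plane translation magnitude as a cross-check.
#'
#' @param cranium,body `pose_series` of neurocranium and body plane.
#' @param fish_frame a `fish_frame` built at `frame` (see
#'   [build_fish_frame()]); its origin must be the occiput.
#' @param grid a [grid_spec()].
#' @param centrum_length_mm vertebral centrum length (V5) used to
#'   normalize the AOR position across individuals, mm.
#' @param zero_frame frame defining the zero pose; default the detected
#'   onset of neurocranial elevation.
#' @param frame_built the frame `fish_frame` was constructed at (default
#'   1); the frame is carried to `zero_frame` through the body-plane
#'   motion before the candidates are laid out.
#' @param policy evaluation-frame policy for the translation objective:
#'   `"peak"` (default; translation at the peak-elevation frame), `"max"`
#'   or `"rms"` (over the expansive phase).
#' @param method `"sweep"` (default) or `"joint"`.
#' @param threshold_deg,persistence onset-detection settings, see
#'   [detect_expansive_phase()].
#' @param flat_tol_mm if every candidate's objective lies within this
#'   band, the translation field carries no information (no rotation
#'   present) and an error is raised.
#' @param max_rounds maximum sweep alternations.
#' @return object of class `aor_result`: list with `position_mm`
#'   (named AP/DV offsets from the occiput, mm), `normalized_position`
#'   (in centrum lengths), `translation_curves` (list of per-sweep
#'   data.frames `offset_mm`, `translation_mm`), `spacing_mm`, `policy`,
#'   `method`, `onset_frame`, `peak_frame`, `boundary_warning`, `rounds`.
#' @export
grid_search_aor <- function(cranium, body, fish_frame,
                            grid = grid_spec(), centrum_length_mm,
                            zero_frame = NULL,
                            policy = c("peak", "max", "rms"),
                            method = c("sweep", "joint"),
                            threshold_deg = 0.5, persistence = 3,
                            flat_tol_mm = 1e-9, max_rounds = 20,
                            frame_built = 1L) {
  policy <- match.arg(policy)
  method <- match.arg(method)
  stopifnot(inherits(fish_frame, "fish_frame"), inherits(grid, "grid_spec"),
            is.numeric(centrum_length_mm), centrum_length_mm > 0)

  # phase from a JCS at the occiput; rotation channels are independent of
  # JCS position, so any origin gives the same elevation trace
  jcs0 <- joint_coordinate_system(fish_frame)
  prof0 <- measure_motion(jcs0, cranium, body, zero_frame = frame_built)
  ph <- detect_expansive_phase(prof0$elevation_deg, threshold_deg,
                               persistence)
  if (is.null(zero_frame)) zero_frame <- ph$onset_frame
  peak <- ph$peak_frame

  # carry the fish frame to the zero frame through the body-plane motion
  G <- frame_motion(body, frame_built, zero_frame)
  occ <- as.numeric(G$Q %*% fish_frame$proximal$origin + G$q)
  A <- G$Q %*% fish_frame$proximal$axes
  frames <- ph$onset_frame:ph$peak_frame
  frames <- frames[frames != zero_frame]
  if (length(frames) == 0) frames <- peak

  ap <- grid_axis(grid$ap_range_mm, grid$spacing_mm)
  dv <- grid_axis(grid$dv_range_mm, grid$spacing_mm)
  origins_at <- function(x, y) {
    # world origins for fish-frame offsets (x, y) from the occiput
    occ + A[, 1, drop = FALSE] %*% rbind(x) + A[, 2, drop = FALSE] %*% rbind(y)
  }
  obj <- function(x, y, component)
    translation_objective(A, cranium, body, zero_frame, frames, peak,
                          origins_at(x, y), component, policy)
  pick <- function(values, offsets, flat_what) {
    if (max(values) - min(values) < flat_tol_mm)
      stop("indeterminate AOR: ", flat_what,
           " is flat across candidates (no rotation present?)")
    cand <- which(values <= min(values) + 1e-12)
    cand[which.min(abs(offsets[cand]))]  # tie-break: closest to occiput
  }

  curves <- list()
  if (method == "sweep") {
    x_cur <- 0
    y_cur <- 0
    rounds <- 0
    repeat {
      rounds <- rounds + 1
      vy <- obj(ap, rep(y_cur, length(ap)), 2L)
      x_new <- ap[pick(vy, ap, "|Y-translation|")]
      curves[[paste0("ap_sweep_", rounds)]] <-
        data.frame(offset_mm = ap, translation_mm = vy)
      vx <- obj(rep(x_new, length(dv)), dv, 1L)
      y_new <- dv[pick(vx, dv, "|X-translation|")]
      curves[[paste0("dv_sweep_", rounds)]] <-
        data.frame(offset_mm = dv, translation_mm = vx)
      if ((x_new == x_cur && y_new == y_cur && rounds > 1) ||
          rounds >= max_rounds) {
        x_cur <- x_new; y_cur <- y_new
        break
      }
      x_cur <- x_new; y_cur <- y_new
    }
  } else {
    gridpts <- expand.grid(x = ap, y = dv)
    v <- obj(gridpts$x, gridpts$y, 1:2)
    if (max(v) - min(v) < flat_tol_mm)
      stop("indeterminate AOR: in-plane translation is flat across candidates")
    cand <- which(v <= min(v) + 1e-12)
    best <- cand[which.min(gridpts$x[cand]^2 + gridpts$y[cand]^2)]
    x_cur <- gridpts$x[best]
    y_cur <- gridpts$y[best]
    rounds <- 1
    curves$joint <- data.frame(offset_ap_mm = gridpts$x,
                               offset_dv_mm = gridpts$y,
                               translation_mm = v)
  }

  boundary <- x_cur %in% grid$ap_range_mm || y_cur %in% grid$dv_range_mm
  if (boundary)
    warning("AOR estimate lies on the grid boundary; enlarge the grid")
  structure(list(
    position_mm = c(ap = x_cur, dv = y_cur),
    normalized_position = c(ap = x_cur, dv = y_cur) / centrum_length_mm,
    centrum_length_mm = centrum_length_mm,
    translation_curves = curves,
    spacing_mm = grid$spacing_mm, policy = policy, method = method,
    onset_frame = ph$onset_frame, peak_frame = peak,
    zero_frame = zero_frame,
    occiput_world = occ, axes = A,
    jcs = structure(list(origin = as.numeric(occ + A[, 1] * x_cur +
                                               A[, 2] * y_cur),
                         axes = A, rotation_order = "ZYX"),
                    class = "jcs"),
    boundary_warning = boundary, rounds = rounds),
    class = "aor_result")
}

#' @export
print.aor_result <- function(x, ...) {
  cat(sprintf(paste0(
    "AOR estimate (%s method, %s policy): %.2f mm caudal, %.2f mm dorsal",
    " of the occiput\n  normalized: (%.3f, %.3f) centrum lengths;",
    " grid spacing %g mm\n"),
    x$method, x$policy, x$position_mm["ap"], x$position_mm["dv"],
    x$normalized_position["ap"], x$normalized_position["dv"],
    x$spacing_mm))
  invisible(x)
}

#' Export an AOR estimate as CSV
#'
#' @param result an `aor_result`.
#' @param path output CSV path for the estimate; sweep curves go to
#'   `curve_path` if given.
#' @param curve_path optional path for the translation-vs-position curves.
#' @return `path`, invisibly.
#' @export
write_aor_csv <- function(result, path, curve_path = NULL) {
  df <- data.frame(ap_mm = result$position_mm["ap"],
                   dv_mm = result$position_mm["dv"],
                   ap_centra = result$normalized_position["ap"],
                   dv_centra = result$normalized_position["dv"],
                   centrum_length_mm = result$centrum_length_mm,
                   spacing_mm = result$spacing_mm,
                   policy = result$policy, method = result$method,
                   onset_frame = result$onset_frame,
                   peak_frame = result$peak_frame,
                   boundary_warning = result$boundary_warning)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(curve_path)) {
    curves <- mapply(function(nm, cv) cbind(sweep = nm, cv),
                     names(result$translation_curves),
                     result$translation_curves, SIMPLIFY = FALSE)
    utils::write.csv(do.call(rbind, lapply(curves, function(d) {
      if (!"offset_mm" %in% names(d)) return(NULL)
      d
    })), curve_path, row.names = FALSE)
  }
  invisible(path)
}

#' 2D Reuleaux estimate of the center of rotation
#'
#' The classical graphical construction: each landmark's rest and peak
#' positions are joined by a chord; the perpendicular bisector of every
#' chord passes through the center of rotation, so the intersection of any
#' two bisectors estimates it. All C(n, 2) landmark pairs are
#' intersected. Pairs whose bisectors are within `parallel_tol_deg` of
#' parallel are excluded: such landmark pairs lie (nearly) on a straight
#' line through the center, and their intersection is unstable.
#'
#' @param landmarks_rest,landmarks_peak `n x 2` matrices (mm) of landmark
#'   positions at rest and at peak elevation, same row order, `n >= 2`.
#' @param min_chord_mm landmarks displaced by less than this are dropped
#'   with a warning (default 0.1 mm); a zero-length chord has no bisector.
#' @param parallel_tol_deg bisector-parallel exclusion angle (default 1).
#' @return object of class `reuleaux_result`: list with `estimates`
#'   (`k x 2` matrix), `pairs` (`k x 2` landmark indices), `excluded`
#'   (data.frame `i`, `j`, `reason`), `mean_estimate` (length 2),
#'   `n_landmarks`, `dropped_landmarks`.
#' @export
reuleaux_aor <- function(landmarks_rest, landmarks_peak,
                         min_chord_mm = 0.1, parallel_tol_deg = 1) {
  p0 <- as.matrix(landmarks_rest)
  p1 <- as.matrix(landmarks_peak)
  stopifnot(ncol(p0) == 2, ncol(p1) == 2, nrow(p0) == nrow(p1))
  if (nrow(p0) < 2) stop("need at least 2 landmarks")
  chord <- p1 - p0
  len <- sqrt(rowSums(chord^2))
  keep <- len >= min_chord_mm
  if (!all(keep))
    warning("dropping landmark(s) with chord shorter than ", min_chord_mm,
            " mm: ", paste(which(!keep), collapse = ", "))
  idx <- which(keep)
  if (length(idx) < 2)
    stop("fewer than 2 landmarks with usable displacement")
  mid <- (p0 + p1) / 2
  pairs <- utils::combn(idx, 2)
  est <- matrix(NA_real_, 0, 2)
  used <- matrix(NA_integer_, 0, 2)
  excl <- data.frame(i = integer(), j = integer(), reason = character())
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    # bisector of chord i: {q : chord_i . (q - mid_i) = 0}; solve both
    Mat <- rbind(chord[i, ], chord[j, ])
    rhs <- c(sum(chord[i, ] * mid[i, ]), sum(chord[j, ] * mid[j, ]))
    # angle between the bisectors equals the angle between the chords
    cosang <- abs(sum(chord[i, ] * chord[j, ])) / (len[i] * len[j])
    ang <- acos(min(1, cosang)) * 180 / pi
    if (ang < parallel_tol_deg) {
      excl <- rbind(excl, data.frame(
        i = i, j = j,
        reason = sprintf("bisectors within %g deg of parallel (%.3g deg)",
                         parallel_tol_deg, ang)))
      next
    }
    q <- solve(Mat, rhs)
    est <- rbind(est, q)
    used <- rbind(used, c(i, j))
  }
  if (nrow(est) == 0)
    stop("no estimate: all landmark pairs excluded as near-parallel")
  rownames(est) <- NULL
  structure(list(estimates = est, pairs = used, excluded = excl,
                 mean_estimate = colMeans(est),
                 n_landmarks = nrow(p0),
                 dropped_landmarks = which(!keep)),
            class = "reuleaux_result")
}

#' @export
print.reuleaux_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Reuleaux AOR: %d estimate(s) from %d landmarks (%d pair(s) excluded)\n",
    "  mean estimate: (%.3f, %.3f) mm\n"),
    nrow(x$estimates), x$n_landmarks, nrow(x$excluded),
    x$mean_estimate[1], x$mean_estimate[2]))
  invisible(x)
}

#' Error of a Reuleaux estimate against a known center
#'
#' Mean and standard error of the Euclidean distances between each
#' pairwise estimate and the true center of rotation.
#'
#' @param result a `reuleaux_result`.
#' @param true_aor length-2 true center (mm).
#' @return list with `mean_mm`, `sem_mm` (`NA` for a single estimate),
#'   `distances_mm`.
#' @export
reuleaux_error <- function(result, true_aor) {
  stopifnot(inherits(result, "reuleaux_result"), length(true_aor) == 2)
  d <- sqrt(colSums((t(result$estimates) - as.numeric(true_aor))^2))
  list(mean_mm = mean(d),
       sem_mm = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
       distances_mm = d)
}

#' Orthographic projection onto the sagittal plane of the fish frame
#'
#' Drops the mediolateral coordinate: points are expressed in the fish
#' frame and only the anteroposterior (X) and dorsoventral (Y) components
#' are kept. This is the projection a lateral-view 2D analysis implicitly
#' performs, and is what makes the 2D method blind to non-planar motion.
#'
#' @param points_3d `n x 3` matrix of world coordinates (mm).
#' @param fish_frame a `fish_frame` (see [build_fish_frame()]).
#' @return `n x 2` matrix of (AP, DV) coordinates relative to the frame
#'   origin (mm).
#' @export
project_to_sagittal <- function(points_3d, fish_frame) {
  stopifnot(inherits(fish_frame, "fish_frame"))
  p <- as.matrix(points_3d)
  stopifnot(ncol(p) == 3)
  rel <- sweep(p, 2, fish_frame$proximal$origin)
  out <- rel %*% fish_frame$proximal$axes[, 1:2]
  colnames(out) <- c("ap_mm", "dv_mm")
  out
}
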