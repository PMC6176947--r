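#' Full strike analysis: poses, AOR, kinematic profile, summary
#'
#' Runs the complete workflow on one trial: fit rigid-body pose series for
#' the neurocranium and the body plane, report tracking precision and
#' body-plane non-rigidity, build the fish frame, locate the axis of
#' rotation by the JCS grid search, then measure the kinematic profile
#' with a JCS placed at the estimated AOR (zeroed at the onset of
#' neurocranial elevation) and summarize the expansive phase.
#'
#' @param trj a [marker_trajectory_set()].
#' @param cranium_ids,body_ids marker labels of the neurocranium and
#'   body-plane rigid bodies.
#' @param occiput_mm occiput position in world coordinates at
#'   `reference_frame`, mm; origin for AOR coordinates.
#' @param centrum_length_mm V5 centrum length, mm.
#' @param long_axis_hint world vector pointing roughly caudal at
#'   `reference_frame`; default `c(1, 0, 0)`.
#' @param dorsal_hint world vector pointing roughly dorsal at
#'   `reference_frame`; default `c(0, 1, 0)`.
#' @param reference_frame frame supplying the rigid-body reference
#'   configurations and the fish frame (default 1). Explicit
#'   [rigid_body_def()] objects can be passed via `cranium_def`/`body_def`
#'   to use CT-derived reference coordinates instead.
#' @param cranium_def,body_def optional pre-built [rigid_body_def()]s
#'   overriding `cranium_ids`/`body_ids` + `reference_frame`.
#' @param grid a [grid_spec()].
#' @param policy,method,threshold_deg,persistence passed to
#'   [grid_search_aor()].
#' @param rigidity_threshold_mm passed to [body_plane_rigidity_report()].
#' @return list of class `strike_analysis` with elements `cranium_poses`,
#'   `body_poses`, `precision_mm`, `rigidity`, `fish_frame`, `aor`,
#'   `profile`, `summary`.
#' @export
analyze_strike <- function(trj, cranium_ids, body_ids, occiput_mm,
                           centrum_length_mm, long_axis_hint = c(1, 0, 0),
                           dorsal_hint = c(0, 1, 0),
                           reference_frame = 1,
                           cranium_def = NULL, body_def = NULL,
                           grid = grid_spec(),
                           policy = "peak", method = "sweep",
                           threshold_deg = 0.5, persistence = 3,
                           rigidity_threshold_mm = 1) {
  stopifnot(inherits(trj, "marker_trajectory_set"))
  if (is.null(cranium_def))
    cranium_def <- rigid_body_def_from_frame(trj, "neurocranium",
                                             cranium_ids, reference_frame)
  if (is.null(body_def))
    body_def <- rigid_body_def_from_frame(trj, "body_plane", body_ids,
                                          reference_frame)
  cr <- fit_pose_series(trj, cranium_def)
  bp <- fit_pose_series(trj, body_def)
  precision <- intermarker_precision(trj, cranium_def$marker_ids)
  rigidity <- body_plane_rigidity_report(trj, body_def,
                                         rigidity_threshold_mm)
  ref_pose_body <- pose_at(bp, reference_frame)
  ref_pose_cr <- pose_at(cr, reference_frame)
  ff <- build_fish_frame(ref_pose_body, ref_pose_cr, long_axis_hint,
                         body_def = body_def, origin = occiput_mm,
                         dorsal_hint = dorsal_hint)
  aor <- grid_search_aor(cr, bp, ff, grid, centrum_length_mm,
                         policy = policy, method = method,
                         threshold_deg = threshold_deg,
                         persistence = persistence,
                         frame_built = reference_frame)
  profile <- measure_motion(aor$jcs, cr, bp, zero_frame = aor$zero_frame)
  profile <- annotate_expansive_phase(profile, threshold_deg, persistence)
  structure(list(cranium_poses = cr, body_poses = bp,
                 precision_mm = precision, rigidity = rigidity,
                 fish_frame = ff, aor = aor, profile = profile,
                 summary = summarize_strike(profile)),
            class = "strike_analysis")
}

# pose of one frame of a series as a `pose` object
pose_at <- function(ps, frame) {
  if (!ps$valid[frame]) stop("no valid pose at frame ", frame)
  structure(list(rotation = ps$rotations[, , frame],
                 translation = ps$translations[frame, ],
                 rms_residual = ps$rms_residual[frame]),
            class = "pose")
}

#' @export
print.strike_analysis <- function(x, ...) {
  cat("Strike analysis\n")
  cat(sprintf("  tracking precision (neurocranium): %.4g mm\n",
              x$precision_mm))
  cat(sprintf("  body-plane distance variation: max %.3g mm\n",
              max(x$rigidity$variation_mm, na.rm = TRUE)))
  print(x$aor)
  print(x$summary)
  invisible(x)
}
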