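#' Define a rigid body from a marker subset
#'
#' A rigid body is a named subset of at least three non-collinear markers
#' together with their reference positions — the coordinates of the markers
#' in the body's own reference frame, taken either from a designated
#' reference frame of the recording (the usual case; see
#' [rigid_body_def_from_frame()]) or from an external (e.g. CT-derived)
#' coordinate file.
#'
#' @param name body label, e.g. `"neurocranium"` or `"body_plane"`.
#' @param marker_ids character vector (length >= 3) of marker labels.
#' @param reference_positions numeric `markers x 3` matrix (mm), rows in
#'   `marker_ids` order.
#' @return object of class `rigid_body_def`.
#' @export
rigid_body_def <- function(name, marker_ids, reference_positions) {
  reference_positions <- as.matrix(reference_positions)
  if (length(marker_ids) < 3) stop("a rigid body needs at least 3 markers")
  stopifnot(nrow(reference_positions) == length(marker_ids),
            ncol(reference_positions) == 3)
  if (anyNA(reference_positions))
    stop("reference positions must be complete")
  assert_not_collinear(reference_positions)
  rownames(reference_positions) <- marker_ids
  structure(list(name = name, marker_ids = marker_ids,
                 reference_positions = reference_positions),
            class = "rigid_body_def")
}

#' @export
print.rigid_body_def <- function(x, ...) {
  cat(sprintf("Rigid body '%s': %d markers (%s)\n", x$name,
              length(x$marker_ids), paste(x$marker_ids, collapse = ", ")))
  invisible(x)
}

#' Rigid body defined by a reference frame of the recording
#'
#' @param trj a [marker_trajectory_set()].
#' @param name body label.
#' @param marker_ids markers belonging to the body.
#' @param frame reference frame index (default 1); all the body's markers
#'   must be present there.
#' @return a [rigid_body_def()].
#' @export
rigid_body_def_from_frame <- function(trj, name, marker_ids, frame = 1) {
  ref <- frame_positions(trj, frame, marker_ids)
  if (anyNA(ref))
    stop("markers missing in reference frame ", frame, ": ",
         paste(marker_ids[apply(is.na(ref), 1, any)], collapse = ", "))
  rigid_body_def(name, marker_ids, ref)
}

# collinear iff the centered configuration has (numerical) rank < 2;
# tested on the second-largest singular value, relative to the largest
assert_not_collinear <- function(pts, tol = 1e-8) {
  ctr <- scale(pts, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= tol * max(sv[1], .Machine$double.eps))
    stop("degenerate geometry: marker configuration is collinear")
  invisible(TRUE)
}

#' Least-squares rigid-body pose from point correspondences
#'
#' Closed-form orthogonal Procrustes (Kabsch) solution: recovers the
#' rotation `R` and translation `t` minimizing the sum of squared
#' distances `sum_i |R p_i + t - q_i|^2` between reference points `p`
#' and observed points `q`. Centroids are subtracted, the cross-covariance
#' is decomposed by SVD, and the sign of the last singular direction is
#' corrected so the result is always a proper rotation (det = +1), never a
#' reflection — important for noisy near-planar marker sets. All markers
#' are weighted equally.
#'
#' @param reference_positions `n x 3` matrix (mm), `n >= 3`, non-collinear.
#' @param observed_positions `n x 3` matrix (mm), same row order.
#' @return object of class `pose`: list with `rotation` (3x3, det +1),
#'   `translation` (length-3, mm) and `rms_residual` (mm; root mean square
#'   3D distance of the aligned reference points from the observations).
#' @examples
#' ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
#' fit_pose(ref, ref)$rms_residual  # identity case: 0
#' @export
fit_pose <- function(reference_positions, observed_positions) {
  p <- as.matrix(reference_positions)
  q <- as.matrix(observed_positions)
  stopifnot(ncol(p) == 3, ncol(q) == 3, nrow(p) == nrow(q))
  if (nrow(p) < 3) stop("fewer than 3 corresponding points")
  if (anyNA(p) || anyNA(q)) stop("fit_pose requires complete points")
  assert_not_collinear(p)
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  H <- crossprod(pc, qc)            # sum_i p_i q_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cq - R %*% cp)
  resid <- sweep(p %*% t(R), 2, tr, "+") - q
  rms <- sqrt(mean(rowSums(resid^2)))
  structure(list(rotation = R, translation = tr, rms_residual = rms),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  ang <- acos(min(1, max(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("Pose: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm, rms residual %.4g mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3],
              x$rms_residual))
  invisible(x)
}

#' Fit one pose per frame for a rigid body
#'
#' Runs [fit_pose()] frame by frame. Markers missing in a frame are
#' dropped for that frame and the pose is fit from the remainder, provided
#' at least three non-collinear markers are present; frames with fewer are
#' flagged invalid (`NA` pose), never interpolated.
#'
#' @param trj a [marker_trajectory_set()].
#' @param body a [rigid_body_def()] whose markers occur in `trj`.
#' @return object of class `pose_series`: list with `rotations`
#'   (`3 x 3 x frames`), `translations` (`frames x 3`), `rms_residual`,
#'   `valid` (logical per frame), `n_markers_used`, `body`, `frame_rate`.
#' @export
fit_pose_series <- function(trj, body) {
  stopifnot(inherits(trj, "marker_trajectory_set"),
            inherits(body, "rigid_body_def"))
  idx <- match(body$marker_ids, trj$marker_ids)
  if (anyNA(idx))
    stop("body markers not in trajectory set: ",
         paste(body$marker_ids[is.na(idx)], collapse = ", "))
  nf <- n_frames(trj)
  rot <- array(NA_real_, dim = c(3, 3, nf))
  trans <- matrix(NA_real_, nf, 3)
  rms <- rep(NA_real_, nf)
  valid <- logical(nf)
  used <- integer(nf)
  for (f in seq_len(nf)) {
    pres <- trj$present[f, idx]
    used[f] <- sum(pres)
    if (used[f] < 3) next
    ref <- body$reference_positions[pres, , drop = FALSE]
    obs <- frame_positions(trj, f, body$marker_ids[pres])
    ok <- tryCatch({
      ps <- fit_pose(ref, obs)
      rot[, , f] <- ps$rotation
      trans[f, ] <- ps$translation
      rms[f] <- ps$rms_residual
      TRUE
    }, error = function(e) FALSE)
    valid[f] <- ok
  }
  if (!any(valid))
    stop("no frame with >=3 visible, non-collinear markers for body '",
         body$name, "'")
  structure(list(rotations = rot, translations = trans, rms_residual = rms,
                 valid = valid, n_markers_used = used, body = body,
                 frame_rate = trj$frame_rate),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  nf <- length(x$valid)
  cat(sprintf("Pose series for '%s': %d frames (%d valid) @ %g Hz, mean rms residual %.4g mm\n",
              x$body$name, nf, sum(x$valid), x$frame_rate,
              mean(x$rms_residual, na.rm = TRUE)))
  invisible(x)
}

n_poses <- function(ps) length(ps$valid)

# per-frame pairwise distances for a marker subset; frames x pairs matrix,
# NA where either marker is absent. Pair labels "a|b".
pair_distances <- function(trj, marker_ids) {
  idx <- match(marker_ids, trj$marker_ids)
  if (anyNA(idx)) stop("unknown marker ids")
  n <- length(idx)
  if (n < 2) stop("need at least 2 markers")
  pairs <- utils::combn(n, 2)
  out <- matrix(NA_real_, n_frames(trj), ncol(pairs))
  lab <- character(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- idx[pairs[1, k]]
    j <- idx[pairs[2, k]]
    d <- trj$positions[, i, , drop = FALSE] - trj$positions[, j, , drop = FALSE]
    out[, k] <- sqrt(rowSums(matrix(d, ncol = 3)^2))
    lab[k] <- paste(marker_ids[pairs[1, k]], marker_ids[pairs[2, k]],
                    sep = "|")
  }
  colnames(out) <- lab
  out
}

#' Tracking precision as mean standard deviation of intermarker distances
#'
#' For every unordered pair of the given markers, the per-frame Euclidean
#' distance is computed over the frames where both markers are present,
#' its standard deviation taken across frames, and the result averaged
#' over pairs. For markers rigidly attached to the same bone this distance
#' is physically constant, so its spread measures tracking noise (mm).
#'
#' @param trj a [marker_trajectory_set()].
#' @param marker_ids subset of markers (>= 2), typically one rigid body's.
#' @return mean standard deviation of pairwise distances, mm.
#' @export
intermarker_precision <- function(trj, marker_ids) {
  d <- pair_distances(trj, marker_ids)
  sds <- apply(d, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) NA_real_ else stats::sd(col)
  })
  if (anyNA(sds)) {
    warning("excluding pair(s) with fewer than 2 co-visible frames: ",
            paste(colnames(d)[is.na(sds)], collapse = ", "))
    sds <- sds[!is.na(sds)]
  }
  if (length(sds) == 0) stop("no marker pair with 2 or more co-visible frames")
  mean(sds)
}

#' Report non-rigidity of a marker set as distance variation per pair
#'
#' Soft-tissue markers (e.g. the body-plane beads sutured to the flank) do
#' not form a true rigid body. This reports, for every unordered pair, the
#' range (max - min) of the intermarker distance across frames, and warns
#' when any pair exceeds a threshold.
#'
#' @param trj a [marker_trajectory_set()].
#' @param body a [rigid_body_def()] (or character vector of marker ids).
#' @param threshold_mm warn when any pair's variation exceeds this
#'   (default 1 mm).
#' @return data.frame with columns `pair`, `min_mm`, `max_mm`,
#'   `variation_mm`, `flagged`.
#' @export
body_plane_rigidity_report <- function(trj, body, threshold_mm = 1) {
  ids <- if (inherits(body, "rigid_body_def")) body$marker_ids else body
  d <- pair_distances(trj, ids)
  rng <- apply(d, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) c(NA_real_, NA_real_) else range(col)
  })
  out <- data.frame(pair = colnames(d), min_mm = rng[1, ], max_mm = rng[2, ],
                    variation_mm = rng[2, ] - rng[1, ],
                    row.names = NULL)
  out$flagged <- !is.na(out$variation_mm) & out$variation_mm > threshold_mm
  if (any(out$flagged))
    warning("marker pair(s) exceed ", threshold_mm, " mm distance variation: ",
            paste(out$pair[out$flagged], collapse = ", "))
  out
}
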