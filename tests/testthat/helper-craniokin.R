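# Shared fixtures and independent oracles, all built in code.

# uniform random proper rotation from a normalized quaternion
random_rotation <- function() {
  v <- stats::rnorm(4)
  v <- v / sqrt(sum(v^2))
  quat_to_rot(v)
}

quat_to_rot <- function(v) {
  w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# Horn's closed-form absolute orientation (quaternion eigenvector method):
# an independent oracle for the SVD-based fit_pose
horn_fit <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  S <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  trS <- sum(diag(S))
  delta <- c(S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1])
  N <- rbind(c(trS, delta),
             cbind(delta, S + t(S) - trS * diag(3)))
  v <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- quat_to_rot(v)
  list(rotation = R, translation = as.numeric(cq - R %*% cp))
}

# six-marker reference configuration used across pose-fit tests
ref6 <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 25, 0),
              c(0, 0, 20), c(20, 15, 5), c(10, 5, 18))

apply_rigid <- function(pts, R, tr) sweep(pts %*% t(R), 2, tr, "+")

# apply one rigid world transform to every marker of a trajectory set
transform_trajectories <- function(trj, R, tr) {
  pos <- trj$positions
  for (f in seq_len(dim(pos)[1])) {
    m <- matrix(pos[f, , ], ncol = 3)
    pos[f, , ] <- apply_rigid(m, R, tr)
  }
  marker_trajectory_set(pos, trj$marker_ids, trj$frame_rate)
}

# pose series fit for both bodies of a simulated trial
fit_trial <- function(trial, trj = trial$trajectories) {
  list(cranium = fit_pose_series(
         trj, rigid_body_def_from_frame(trj, "neurocranium",
                                        trial$marker_groups$neurocranium)),
       body = fit_pose_series(
         trj, rigid_body_def_from_frame(trj, "body_plane",
                                        trial$marker_groups$body_plane)))
}

# fish frame of a trial at its reference frame
trial_fish_frame <- function(trial, ps = fit_trial(trial),
                             hint = c(1, 0, 0), dorsal = c(0, 1, 0)) {
  build_fish_frame(craniokin:::pose_at(ps$body, 1),
                   craniokin:::pose_at(ps$cranium, 1),
                   hint, body_def = ps$body$body,
                   origin = trial$layout$occiput_mm,
                   dorsal_hint = dorsal)
}

# fish frame of a whole scene rigidly moved by (R, tr), hints rotated too
transformed_fish_frame <- function(trial, ps2, R, tr) {
  build_fish_frame(craniokin:::pose_at(ps2$body, 1),
                   craniokin:::pose_at(ps2$cranium, 1),
                   as.numeric(R %*% c(1, 0, 0)),
                   body_def = ps2$body$body,
                   origin = apply_rigid(rbind(trial$layout$occiput_mm),
                                        R, tr)[1, ],
                   dorsal_hint = as.numeric(R %*% c(0, 1, 0)))
}

# grid-search AOR error (mm) for one simulated trial
trial_aor_error <- function(trial, method = "sweep",
                            grid = grid_spec()) {
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  res <- grid_search_aor(ps$cranium, ps$body, ff, grid,
                         trial$layout$centrum_length_mm, method = method)
  sqrt(sum((res$position_mm - trial$spec$true_aor_mm[1:2])^2))
}

expect_all_near <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
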