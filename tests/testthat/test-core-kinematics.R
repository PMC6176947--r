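test_that("fit_pose recovers known rigid transforms exactly", {
  # identity case
  p <- fit_pose(ref6, ref6)
  expect_all_near(p$rotation, diag(3), 1e-12)
  expect_all_near(p$translation, c(0, 0, 0), 1e-12)
  expect_lt(p$rms_residual, 1e-12)

  # stated example: 15 deg about Z then translate (1, 2, 3) mm
  R15 <- craniokin:::rot_z(15)
  obs <- apply_rigid(ref6, R15, c(1, 2, 3))
  p <- fit_pose(ref6, obs)
  expect_all_near(p$rotation, R15, 1e-9)
  expect_all_near(p$translation, c(1, 2, 3), 1e-9)
  expect_lt(p$rms_residual, 1e-9)

  # property: random proper rotations and translations
  set.seed(11)
  for (i in 1:25) {
    R <- random_rotation()
    tr <- stats::rnorm(3, sd = 20)
    p <- fit_pose(ref6, apply_rigid(ref6, R, tr))
    expect_all_near(p$rotation, R, 1e-9)
    expect_all_near(p$translation, tr, 1e-9)
  }
})

test_that("fit_pose is invariant to consistent marker relabeling", {
  set.seed(3)
  R <- random_rotation()
  tr <- c(4, -2, 7)
  obs <- apply_rigid(ref6, R, tr) + matrix(rnorm(18, sd = 0.1), 6, 3)
  p1 <- fit_pose(ref6, obs)
  perm <- sample(6)
  p2 <- fit_pose(ref6[perm, ], obs[perm, ])
  expect_all_near(p1$rotation, p2$rotation, 1e-12)
  expect_all_near(p1$translation, p2$translation, 1e-12)
  expect_equal(p1$rms_residual, p2$rms_residual, tolerance = 1e-12)
})

test_that("fit_pose agrees with the quaternion (Horn) oracle on noisy data", {
  set.seed(7)
  for (i in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 10)
    obs <- apply_rigid(ref6, R, tr) + matrix(rnorm(18, sd = 0.2), 6, 3)
    fit <- fit_pose(ref6, obs)
    oracle <- horn_fit(ref6, obs)
    expect_all_near(fit$rotation, oracle$rotation, 1e-8)
    expect_all_near(fit$translation, oracle$translation, 1e-8)
  }
})

test_that("fit_pose rejects degenerate input and never returns a reflection", {
  expect_error(fit_pose(ref6[1:2, ], ref6[1:2, ]), "fewer than 3")
  line <- cbind(0:3, 0, 0)
  expect_error(fit_pose(line, line), "collinear")

  # reflection guard: noisy near-planar configuration keeps det = +1
  planar <- cbind(ref6[, 1:2], 0)
  set.seed(21)
  for (i in 1:50) {
    obs <- apply_rigid(planar, random_rotation(), rnorm(3)) +
      matrix(rnorm(18, sd = 0.5), 6, 3)
    expect_gt(det(fit_pose(planar, obs)$rotation), 0.999999)
  }
})

test_that("rms residual under iid noise matches a Monte-Carlo oracle", {
  sigma <- 0.1
  set.seed(5)
  # oracle: direct simulation of the residual of the true (not fitted)
  # alignment is sigma per coordinate; fitting absorbs 6 of the 18 dof,
  # so the fitted rms is below sigma. Compare the observed mean rms with
  # an independent replicate set, and bound it by a factor of 2 around
  # sigma * sqrt(1 - 6/(2*6)).
  rms <- replicate(1000, {
    obs <- ref6 + matrix(rnorm(18, sd = sigma), 6, 3)
    fit_pose(ref6, obs)$rms_residual
  })
  target <- sigma * sqrt(1 - 6 / (2 * 6))
  expect_gt(mean(rms), target / 2)
  expect_lt(mean(rms), target * 2)
})

test_that("fit_pose_series handles schedules, gaps and invalid frames", {
  # constant trajectories give the identity pose in every frame
  pos <- array(rep(t(ref6), each = 5), dim = c(5, 6, 3))
  for (k in 1:3) pos[, , k] <- matrix(ref6[, k], 5, 6, byrow = TRUE)
  trj <- marker_trajectory_set(pos, paste0("m", 1:6), 500)
  body <- rigid_body_def("b", paste0("m", 1:6), ref6)
  ps <- fit_pose_series(trj, body)
  expect_true(all(ps$valid))
  for (f in 1:5) expect_all_near(ps$rotations[, , f], diag(3), 1e-12)

  # known rotation schedule is recovered to 1e-6 deg without noise
  trial <- simulate_strike(motion_spec(peak_elevation_deg = 12,
                                       n_frames = 15))
  ps <- fit_trial(trial)$cranium
  for (f in 1:15) {
    ele <- craniokin:::decompose_eyr(ps$rotations[, , f])$elevation
    expect_lt(abs(ele - trial$truth$elevation_deg[f]), 1e-6)
    expect_all_near(ps$rotations[, , f], trial$truth$rotations[, , f], 1e-9)
  }

  # one marker missing in one frame: pose still produced
  pos2 <- trial$trajectories$positions
  pos2[8, 2, ] <- NA
  trj2 <- marker_trajectory_set(pos2, trial$trajectories$marker_ids, 500)
  body2 <- rigid_body_def_from_frame(
    trj2, "nc", trial$marker_groups$neurocranium)
  ps2 <- fit_pose_series(trj2, body2)
  expect_true(ps2$valid[8])
  expect_equal(ps2$n_markers_used[8], 3)

  # fewer than 3 present markers: frame flagged invalid, not interpolated
  pos2[9, 1:2, ] <- NA
  trj3 <- marker_trajectory_set(pos2, trial$trajectories$marker_ids, 500)
  ps3 <- fit_pose_series(trj3, body2)
  expect_false(ps3$valid[9])
  expect_true(all(is.na(ps3$translations[9, ])))

  # no frame with >= 3 visible markers is a fatal input error
  pos4 <- pos2
  pos4[, 1:2, ] <- NA
  trj4 <- marker_trajectory_set(pos4, trial$trajectories$marker_ids, 500)
  expect_error(fit_pose_series(trj4, body2), "no frame")
})

test_that("intermarker precision is zero for rigid motion and tracks noise", {
  trial <- simulate_strike(motion_spec(n_frames = 20))
  expect_lt(intermarker_precision(trial$trajectories,
                                  trial$marker_groups$neurocranium), 1e-12)

  # three markers contribute exactly the three pairwise distances
  ids3 <- trial$marker_groups$neurocranium[1:3]
  d <- craniokin:::pair_distances(trial$trajectories, ids3)
  expect_equal(ncol(d), 3)
  expect_equal(intermarker_precision(trial$trajectories, ids3),
               mean(apply(d, 2, sd)))

  # Monte-Carlo oracle: noisy static markers, 1e4 frames, within 5%
  set.seed(13)
  sigma <- 0.15
  nf <- 1e4
  base <- ref6[1:3, ]
  pos <- array(NA_real_, dim = c(nf, 3, 3))
  for (k in 1:3)
    pos[, , k] <- matrix(base[, k], nf, 3, byrow = TRUE) +
      matrix(rnorm(nf * 3, sd = sigma), nf, 3)
  trj <- marker_trajectory_set(pos, c("a", "b", "c"), 500)
  got <- intermarker_precision(trj, c("a", "b", "c"))
  # independent oracle: sd of the distance between two points whose
  # coordinates carry iid gaussian noise, simulated directly
  oracle <- mean(apply(utils::combn(3, 2), 2, function(pr) {
    d0 <- base[pr[1], ] - base[pr[2], ]
    sd(sqrt(colSums((d0 + matrix(rnorm(3 * nf, sd = sigma * sqrt(2)),
                                 3, nf))^2)))
  }))
  expect_lt(abs(got - oracle) / oracle, 0.05)

  # precision grows monotonically with noise level
  prec <- sapply(c(0.05, 0.1, 0.2), function(s) {
    tr <- simulate_strike(motion_spec(n_frames = 400),
                          noise = noise_spec(marker_noise_sd_mm = s,
                                             seed = 99))
    intermarker_precision(tr$trajectories, tr$marker_groups$neurocranium)
  })
  expect_true(all(diff(prec) > 0))
})

test_that("body-plane rigidity report measures and flags distance variation", {
  trial <- simulate_strike(motion_spec(n_frames = 30))
  rep0 <- body_plane_rigidity_report(trial$trajectories,
                                     trial$marker_groups$body_plane)
  expect_true(all(rep0$variation_mm < 1e-12))
  expect_false(any(rep0$flagged))

  # soft-tissue jitter of amplitude a moves each bead by at most a,
  # so pairwise distances vary by at most 4a (brute-force bound check)
  tr <- simulate_strike(motion_spec(n_frames = 60),
                        noise = noise_spec(body_jitter_amplitude_mm = 0.2,
                                           seed = 4))
  repj <- body_plane_rigidity_report(tr$trajectories,
                                     tr$marker_groups$body_plane)
  expect_true(all(repj$variation_mm <= 0.8))

  # a pair varying 1.5 mm is flagged at the default 1 mm threshold
  pos <- tr$trajectories$positions
  pos[1, 5, 1] <- pos[1, 5, 1] + 1.5   # bp1 is marker index 5
  trj <- marker_trajectory_set(pos, tr$trajectories$marker_ids, 500)
  expect_warning(
    repf <- body_plane_rigidity_report(trj, tr$marker_groups$body_plane),
    "exceed")
  expect_true(any(repf$flagged))
})

test_that("pairs without co-visible frames are excluded with a warning", {
  pos <- array(NA_real_, dim = c(4, 3, 3))
  pos[, 1, ] <- matrix(c(0, 0, 0), 4, 3, byrow = TRUE)
  pos[, 2, ] <- matrix(c(10, 0, 0), 4, 3, byrow = TRUE)
  pos[1, 3, ] <- c(0, 10, 0)   # marker c visible in only one frame
  trj <- marker_trajectory_set(pos, c("a", "b", "c"), 100)
  expect_warning(p <- intermarker_precision(trj, c("a", "b", "c")),
                 "co-visible")
  expect_equal(p, 0)
  # all pairs excluded -> error
  pos2 <- pos[, 1:2, ]
  pos2[2:4, 2, ] <- NA
  trj2 <- marker_trajectory_set(pos2, c("a", "b"), 100)
  expect_warning(expect_error(intermarker_precision(trj2, c("a", "b")),
                              "no marker pair"))
})
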