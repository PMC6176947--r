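test_that("grid search hits an on-node AOR exactly with near-zero translation", {
  trial <- simulate_strike(motion_spec(true_aor_mm = c(10, 0, 0),
                                       peak_elevation_deg = 15,
                                       n_frames = 21))
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  res <- grid_search_aor(ps$cranium, ps$body, ff, grid_spec(),
                         centrum_length_mm = 5)
  expect_equal(unname(res$position_mm), c(10, 0))
  expect_equal(unname(res$normalized_position), c(2, 0))
  # both sweep minima are (numerically) zero translation at the AOR
  for (cv in res$translation_curves)
    expect_lt(min(cv$translation_mm), 1e-9)
  expect_false(res$boundary_warning)
})

test_that("AP sweep curve is V-shaped and matches the closed-form oracle", {
  theta <- 15
  trial <- simulate_strike(motion_spec(true_aor_mm = c(10, 0, 0),
                                       peak_elevation_deg = theta,
                                       n_frames = 21))
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  res <- grid_search_aor(ps$cranium, ps$body, ff, grid_spec(),
                         centrum_length_mm = 5, zero_frame = 1)
  cv <- res$translation_curves$ap_sweep_1
  # per-candidate closed form: |Y-translation| = sin(theta) * |x - x_aor|
  # for a planar rotation evaluated at the peak (full) elevation
  oracle <- abs(sin(theta * pi / 180)) * abs(cv$offset_mm - 10)
  expect_all_near(cv$translation_mm, oracle, 1e-9)
  # V-shape: strictly decreasing before the truth, increasing after
  expect_true(all(diff(cv$translation_mm[cv$offset_mm <= 10]) < 0))
  expect_true(all(diff(cv$translation_mm[cv$offset_mm >= 10]) > 0))
})

test_that("a minimizer on the grid boundary triggers a warning", {
  trial <- simulate_strike(motion_spec(true_aor_mm = c(12, 0, 0),
                                       peak_elevation_deg = 15,
                                       n_frames = 11))
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  expect_warning(
    res <- grid_search_aor(ps$cranium, ps$body, ff,
                           grid_spec(c(-10, 12), c(-5, 5)),
                           centrum_length_mm = 5),
    "boundary")
  expect_true(res$boundary_warning)
})

test_that("motion without neurocranial elevation is reported as no strike", {
  # neurocranium glued to the body plane: nothing ever rotates
  trial <- simulate_strike(motion_spec(peak_elevation_deg = 0,
                                       n_frames = 10))
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  expect_error(grid_search_aor(ps$cranium, ps$body, ff, grid_spec(),
                               centrum_length_mm = 5),
               "no strike")
})

test_that("sequential sweeps and joint 2D search agree off-axis", {
  # AOR well off both grid axes exercises the sweep interaction
  trial <- simulate_strike(motion_spec(true_aor_mm = c(17, 8, 0),
                                       peak_elevation_deg = 25,
                                       n_frames = 21))
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  sw <- grid_search_aor(ps$cranium, ps$body, ff, grid_spec(),
                        centrum_length_mm = 5, method = "sweep")
  jt <- grid_search_aor(ps$cranium, ps$body, ff, grid_spec(),
                        centrum_length_mm = 5, method = "joint")
  expect_equal(sw$position_mm, jt$position_mm)
  expect_equal(unname(sw$position_mm), c(17, 8))
})

test_that("grid search is invariant to rigid world motion of the scene", {
  trial <- simulate_strike(motion_spec(true_aor_mm = c(14, -3, 0),
                                       peak_elevation_deg = 18,
                                       n_frames = 15))
  ps <- fit_trial(trial)
  ff <- trial_fish_frame(trial, ps)
  ref <- grid_search_aor(ps$cranium, ps$body, ff, grid_spec(),
                         centrum_length_mm = 5)
  set.seed(41)
  for (i in 1:3) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 30)
    trj2 <- transform_trajectories(trial$trajectories, R, tr)
    ps2 <- fit_trial(trial, trj2)
    ff2 <- transformed_fish_frame(trial, ps2, R, tr)
    got <- grid_search_aor(ps2$cranium, ps2$body, ff2, grid_spec(),
                           centrum_length_mm = 5)
    expect_all_near(got$position_mm, ref$position_mm, 1e-6)
  }
})

test_that("Reuleaux construction is exact for planar rotation about a center", {
  # chords of a circle: rotate landmarks about a known 2D center
  center <- c(4, -2)
  theta <- 20 * pi / 180
  R2 <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  rest <- rbind(c(-30, 5), c(-20, 18), c(-25, -8),
                c(-12, 10), c(-35, 14), c(-16, -3))
  peak <- t(R2 %*% (t(rest) - center) + center)
  res <- reuleaux_aor(rest, peak)
  expect_equal(nrow(res$estimates), choose(6, 2))
  for (k in seq_len(nrow(res$estimates)))
    expect_all_near(res$estimates[k, ], center, 1e-9)
  err <- reuleaux_error(res, center)
  expect_lt(err$mean_mm, 1e-9)
  expect_lt(err$sem_mm, 1e-9)
})

test_that("landmarks collinear with the center produce a parallel exclusion", {
  center <- c(0, 0)
  theta <- 15 * pi / 180
  R2 <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  # landmarks 1 and 2 on a straight line through the center, opposite sides
  rest <- rbind(c(-20, 10), c(10, -5), c(-15, -12), c(8, 14))
  peak <- t(R2 %*% t(rest))
  res <- reuleaux_aor(rest, peak)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(unlist(res$excluded[1, c("i", "j")], use.names = FALSE),
               c(1, 2))
  expect_equal(nrow(res$estimates), choose(4, 2) - 1)

  # error grows as a landmark approaches collinearity with another:
  # fixed per-landmark tracking perturbations, shrinking angular
  # separation seen from the center
  errs <- sapply(c(30, 10, 4, 2), function(ang_deg) {
    a <- ang_deg * pi / 180
    rest2 <- rbind(c(-20, 10), 15 * c(cos(atan2(10, -20) + a),
                                      sin(atan2(10, -20) + a)))
    peak2 <- t(R2 %*% t(rest2)) + rbind(c(0.05, -0.03), c(-0.04, 0.02))
    reuleaux_error(reuleaux_aor(rest2, peak2, parallel_tol_deg = 0),
                   center)$mean_mm
  })
  expect_true(all(diff(errs) > 0))

  # only two landmarks, collinear with the center: nothing left
  expect_error(reuleaux_aor(rest[1:2, ], peak[1:2, ]), "no estimate")
})

test_that("Reuleaux drops undisplaced landmarks and reports hand-checked errors", {
  # third landmark does not move: dropped with a warning
  th <- 0.2
  R2 <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rest <- rbind(c(-10, 0), c(0, 10), c(3, 4))
  peak <- t(R2 %*% t(rest))
  peak[3, ] <- rest[3, ]
  expect_warning(res <- reuleaux_aor(rest, peak), "dropping")
  expect_equal(res$dropped_landmarks, 3L)
  expect_equal(nrow(res$estimates), 1)

  # distances {1, 3} mm -> mean 2, sem 1
  fake <- structure(list(estimates = rbind(c(1, 0), c(3, 0)),
                         pairs = rbind(c(1, 2), c(1, 3)),
                         excluded = data.frame(), n_landmarks = 3,
                         mean_estimate = c(2, 0)),
                    class = "reuleaux_result")
  err <- reuleaux_error(fake, c(0, 0))
  expect_equal(err$mean_mm, 2)
  expect_equal(err$sem_mm, 1)
})

test_that("sagittal projection keeps in-plane geometry and drops mediolateral", {
  trial <- simulate_strike(motion_spec(n_frames = 5))
  ff <- trial_fish_frame(trial)
  # a point already on the sagittal plane keeps its coordinates
  p <- rbind(c(3, 7, 0))
  expect_equal(unname(project_to_sagittal(p, ff)[1, ]), c(3, 7))
  # mediolateral translation is invisible to the projection
  expect_equal(project_to_sagittal(p, ff),
               project_to_sagittal(p + matrix(c(0, 0, 9), 1), ff))

  # pure yaw: projected chords shrink relative to the 3D displacement
  yaw_trial <- simulate_strike(motion_spec(true_aor_mm = c(10, 0, 0),
                                           peak_elevation_deg = 0,
                                           peak_yaw_deg = 12,
                                           planar = FALSE, n_frames = 5,
                                           interpolation = "linear"))
  d3 <- sqrt(rowSums((yaw_trial$landmarks_peak -
                        yaw_trial$landmarks_rest)^2))
  ff2 <- trial_fish_frame(yaw_trial)
  d2 <- sqrt(rowSums((project_to_sagittal(yaw_trial$landmarks_peak, ff2) -
                        project_to_sagittal(yaw_trial$landmarks_rest, ff2))^2))
  expect_true(all(d2 < d3 + 1e-12))
  expect_true(any(d2 < 0.9 * d3))
})
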