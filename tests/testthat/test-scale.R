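# Scale calibration: direct hold-pair samples, angle iteration, model fit,
# hold tracking/identification.

test_that("pairwise scale is the mean of the two axis ratios", {
  expect_equal(pairwise_scale(300, 350.4, 0.75, 0.876), 400)
  expect_equal(pairwise_scale(100, 100, 1, 1), 100)
  expect_warning(s <- pairwise_scale(50, 200, 0, 0.5),
                 "zero map distance in one axis")
  expect_equal(s, 400)
  expect_error(pairwise_scale(1, 1, 0, 0), "both axes")
})

test_that("angle iteration matches the recurrence step by step", {
  expect_equal(iterate_alpha(rep(0, 10), B = 1234, alpha0 = 0.3),
               rep(0.3, 11))
  # hand-rolled recurrence oracle, gamma = 10, B = 1000, alpha0 = 0
  a <- 0; oracle <- a
  for (i in 1:3) { a <- 10 / 1000 * cos(a) + a; oracle <- c(oracle, a) }
  expect_equal(iterate_alpha(rep(10, 3), 1000, 0), oracle, tolerance = 1e-12)
  expect_equal(oracle[3], 0.0199995, tolerance = 1e-7)
  expect_equal(oracle[4], 0.0299975, tolerance = 1e-7)
})

test_that("angle iteration reproduces the generator's exact trajectory", {
  run <- noiseless_run()
  a <- iterate_alpha(run$truth$gamma, run$truth$params$B,
                     run$truth$params$alpha0)
  expect_lt(max(abs(a - run$truth$camera$alpha)), 1e-9)
})

test_that("a constant scale with no camera motion fits exactly", {
  s_meas <- data.frame(frame = c(0L, 5L, 9L), s = 400)
  fit <- fit_scale_model(s_meas, rep(0, 9))
  expect_equal(fit$A * cos(fit$alpha0), 400, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-9)
})

test_that("noiseless supporting points recover A and alpha0", {
  run <- noiseless_run()
  n <- run$truth$params$n_frames
  sup <- round(seq(1, n, length.out = 10))
  s_meas <- data.frame(frame = sup - 1L, s = run$truth$camera$s[sup])
  fit <- fit_scale_model(s_meas, run$truth$gamma)
  expect_lt(abs(fit$A - 400) / 400, 0.01)
  expect_lt(abs(fit$alpha0 - (-0.2)), 0.02)
})

test_that("5% scale noise leaves the amplitude recoverable (20 seeds)", {
  run <- noiseless_run()
  n <- run$truth$params$n_frames
  sup <- round(seq(1, n, length.out = 10))
  s_true <- run$truth$camera$s[sup]
  set.seed(20)
  errs <- replicate(20, {
    s_n <- s_true * (1 + rnorm(10, 0, 0.05))
    f <- fit_scale_model(data.frame(frame = sup - 1L, s = s_n),
                         run$truth$gamma)
    abs(f$A - 400) / 400
  })
  expect_lt(median(errs), 0.05)
})

test_that("the fit is invariant to a constant frame re-indexing", {
  run <- noiseless_run()
  n <- run$truth$params$n_frames
  sup <- round(seq(1, n, length.out = 8))
  s_meas <- data.frame(frame = sup - 1L, s = run$truth$camera$s[sup])
  base <- fit_scale_model(s_meas, run$truth$gamma)
  # prepend k still frames: alpha stays at alpha0 across them
  k <- 10L
  shifted <- fit_scale_model(
    data.frame(frame = s_meas$frame + k, s = s_meas$s),
    c(rep(0, k), run$truth$gamma))
  expect_equal(shifted$A, base$A, tolerance = 1e-4)
  expect_equal(shifted$alpha0, base$alpha0, tolerance = 1e-4)
})

test_that("fitted scale peaks where the camera is closest to parallel", {
  run <- noiseless_run()   # alpha sweeps through 0 during the run
  sr <- noiseless_analysis()
  peak <- which.max(sr$scale$s_fit)
  flat <- which.min(abs(sr$scale$alpha))
  expect_lt(abs(peak - flat), 3)
  # and decreases toward both ends of the sweep
  expect_lt(sr$scale$s_fit[1], sr$scale$s_fit[peak])
  expect_lt(tail(sr$scale$s_fit, 1), sr$scale$s_fit[peak])
})

test_that("hold tracks get the generator's map ids at sigma = 0", {
  run <- noiseless_run()
  gamma <- estimate_shift(filter_matches(run$matches[, 1:5]),
                          n_frames = run$truth$params$n_frames)
  tracks <- track_and_identify_holds(run$detections, gamma,
                                     default_route_map())
  tr <- tracks$tracks
  det <- tracks$detections           # retains the generator's true_id
  true_id <- tapply(det$true_id, det$track, function(z) z[1])
  expect_true(all(!is.na(tr$map_id)))
  expect_equal(tr$map_id, as.integer(true_id[as.character(tr$track)]))
})

test_that("a single repeated detection yields one unassigned track", {
  det <- data.frame(frame = 0:9, class = "hold", x = 500, y = 300,
                    w = 60, h = 60, confidence = 0.9)
  gamma <- structure(list(gamma_px = rep(0, 9),
                          cumulative_px = rep(0, 10),
                          n_inliers = rep(10L, 9),
                          imputed = rep(FALSE, 9)),
                     class = "camera_trajectory")
  tracks <- track_and_identify_holds(det, gamma, default_route_map())
  expect_equal(nrow(tracks$tracks), 1L)
  expect_true(is.na(tracks$tracks$map_id))
  expect_error(measure_scale(tracks, default_route_map()),
               "insufficient holds")
})

test_that("tracking is invariant to a constant per-frame camera shift", {
  run <- noiseless_run()
  det0 <- run$detections[, 1:7]
  zero_gamma <- structure(
    list(gamma_px = rep(0, length(run$truth$gamma)),
         cumulative_px = rep(0, length(run$truth$gamma) + 1L),
         n_inliers = rep(1L, length(run$truth$gamma)),
         imputed = rep(FALSE, length(run$truth$gamma))),
    class = "camera_trajectory")
  # undo the camera motion in the detections, then track with gamma = 0
  cum <- cumsum(c(0, run$truth$gamma))
  det_static <- det0
  det_static$y <- det0$y - cum[det0$frame + 1L]
  t_static <- track_and_identify_holds(det_static, zero_gamma,
                                       default_route_map())
  gamma <- estimate_shift(filter_matches(run$matches[, 1:5]),
                          n_frames = run$truth$params$n_frames)
  t_moving <- track_and_identify_holds(det0, gamma, default_route_map())
  expect_equal(nrow(t_static$tracks), nrow(t_moving$tracks))
  expect_equal(sort(t_static$tracks$map_id), sort(t_moving$tracks$map_id))
})
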