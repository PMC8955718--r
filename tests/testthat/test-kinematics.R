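# Interpolation, joint angles, center of gravity, velocity, filtering.

test_that("interior gaps interpolate linearly, ends clamp to nearest", {
  series <- list(
    x = matrix(c(0, 99, 2), 3, 19), y = matrix(c(0, 99, 2), 3, 19),
    conf = matrix(c(0.9, 0, 0.9), 3, 19), frame = 0:2)
  colnames(series$x) <- colnames(series$y) <- colnames(series$conf) <-
    retained_keypoints()
  out <- interpolate_missing(series)
  expect_equal(unname(out$x[2, 1]), 1)
  expect_equal(unname(out$y[2, 1]), 1)
  expect_true(all(out$interpolated[2, ]))
  expect_false(any(out$interpolated[c(1, 3), ]))

  # no gaps: identity
  full <- series
  full$conf[] <- 0.9
  expect_equal(interpolate_missing(full)$x, full$x)
})

test_that("keypoints with under two valid samples stay missing, logged", {
  series <- list(
    x = matrix(1, 3, 19), y = matrix(1, 3, 19),
    conf = matrix(0.9, 3, 19), frame = 0:2)
  colnames(series$x) <- colnames(series$y) <- colnames(series$conf) <-
    retained_keypoints()
  series$conf[, "nose"] <- c(0.5, 0, 0)
  expect_warning(out <- interpolate_missing(series), "nose")
  expect_true(all(is.na(out$x[2:3, "nose"])))
})

test_that("dropout fills land within 3 sigma of truth on torso keypoints", {
  # torso points move smoothly (spline), so linear fills are noise-limited;
  # fast-transfer limb keypoints violate the linearity premise and are not
  # the target of this bound
  run <- default_run()
  sel <- select_athlete(run$pose, run$config$image_w)
  series <- pose_series(sel$frames)
  filled <- interpolate_missing(series)
  cam <- run$truth$camera
  sigma <- run$truth$params$sigma_px
  for (kp in c("mid_hip", "neck", "r_hip", "l_shoulder")) {
    gaps <- which(filled$interpolated[, kp])
    if (!length(gaps)) next
    # reproject the world truth of this keypoint
    w <- speedkin:::build_world(run$config, default_route_map(),
                                cam$frame / run$config$fps,
                                run$truth$params$duration_s)
    y_true <- 360 - cam$s[gaps] * (w$kp_y[gaps, kp] - cam$c_y[gaps])
    expect_true(all(abs(filled$y[gaps, kp] - y_true) <= 3 * sigma + 1e-6))
  }
})

test_that("joint angles follow plane geometry and stay in [0, 180]", {
  expect_equal(joint_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(joint_angle(c(-1, 0), c(0, 0), c(1, 0)), 180)
  expect_lt(abs(joint_angle(c(2, 2), c(0, 0), c(1, 1))), 1e-4)
  expect_true(is.na(joint_angle(c(0, 0), c(0, 0), c(1, 1))))
})

test_that("joint angles are similarity-invariant", {
  set.seed(8)
  for (rep in 1:25) {
    a <- runif(2, -5, 5); j <- runif(2, -5, 5); b <- runif(2, -5, 5)
    theta <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 10)
    t <- runif(2, -20, 20)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    tr <- function(p) as.numeric(s * R %*% p + t)
    expect_equal(joint_angle(tr(a), tr(j), tr(b)), joint_angle(a, j, b),
                 tolerance = 1e-9)
  }
})

test_that("the center of gravity is a proper mass-weighted combination", {
  tab <- default_anthropometric_table()
  # degenerate pose: every keypoint at (3, 7) must give COG (3, 7)
  sf <- skeleton_frame(0L, rep(3, 19), rep(7, 19), rep(1, 19))
  expect_equal(unname(cog(sf, tab)), c(3, 7))

  # mirrored pose: x-component of the COG vanishes by symmetry
  set.seed(9)
  x <- runif(19, -4, 4); y <- runif(19, 0, 10)
  sfp <- skeleton_frame(0L, x, y, rep(1, 19))
  sfm <- skeleton_frame(0L, -x, y, rep(1, 19))
  expect_equal(unname(cog(sfp, tab)[1] + cog(sfm, tab)[1]), 0,
               tolerance = 1e-12)

  # brute-force oracle: explicit per-segment summation
  oracle <- c(0, 0)
  for (b in seq_len(nrow(tab))) {
    p <- c(x[match(tab$proximal_kp[b], retained_keypoints())],
           y[match(tab$proximal_kp[b], retained_keypoints())])
    d <- c(x[match(tab$distal_kp[b], retained_keypoints())],
           y[match(tab$distal_kp[b], retained_keypoints())])
    oracle <- oracle + tab$mass_frac[b] * (p + tab$com_ratio[b] * (d - p))
  }
  expect_equal(unname(cog(sfp, tab)), oracle, tolerance = 1e-9)
})

test_that("the COG lies inside the convex hull of the keypoints", {
  set.seed(10)
  tab <- default_anthropometric_table()
  for (rep in 1:20) {
    x <- runif(19, 0, 100); y <- runif(19, 0, 100)
    sf <- skeleton_frame(0L, x, y, rep(1, 19))
    C <- cog(sf, tab)
    expect_gte(C[["x"]], min(x)); expect_lte(C[["x"]], max(x))
    expect_gte(C[["y"]], min(y)); expect_lte(C[["y"]], max(y))
  }
})

test_that("velocity applies the camera-compensation arithmetic", {
  # dy_up = 10 px, gamma = 2 px, fps = 24, s = 400 px/m -> 0.72 m/s
  v <- velocity(c(0, 0), c(0, 10), gamma = 2, scale = 400, fps = 24,
                pixel_y_axis = "up")
  expect_equal(v$v_y, 0.72)
  expect_equal(v$v_x, 0)
  expect_error(velocity(c(0, 0), c(0, 1), 0, scale = -5, fps = 24),
               "non-positive scale")
})

test_that("velocity is invariant to a common rescaling of pixels and s", {
  set.seed(11)
  x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
  g <- rnorm(29)
  v1 <- velocity(x, y, g, scale = 350, fps = 24)
  v2 <- velocity(2.5 * x, 2.5 * y, 2.5 * g, scale = 2.5 * 350, fps = 24)
  expect_equal(v2$v_y, v1$v_y, tolerance = 1e-12)
  expect_equal(v2$v_x, v1$v_x, tolerance = 1e-12)
})

test_that("a world-static climber has zero velocity under arbitrary pan", {
  run <- cached("static_run", function()
    generate_run(synth_config(profile = "static", camera = "translate",
                              alpha0 = 0, sigma_px = 0, dropout = 0,
                              outlier_frac = 0), seed = 3))
  sr <- analyze_run(run)
  expect_lt(max(abs(sr$vel$speed)), 1e-6)
})

test_that("the zero-phase low-pass passes constants and kills 10 Hz", {
  expect_equal(as.numeric(lowpass(rep(2.5, 100), 3, 24)), rep(2.5, 100),
               tolerance = 1e-5)
  t <- (0:479) / 24
  x <- sin(2 * pi * t) + sin(2 * pi * 10 * t)
  y <- as.numeric(lowpass(x, 3, 24))
  amp <- function(z, f) {
    n <- length(z)
    2 * Mod(fft(z))[round(f * n / 24) + 1] / n
  }
  expect_gt(amp(y, 1), 0.9)                       # 1 Hz kept
  expect_lt(amp(y, 10) / amp(x, 10), 10^(-20 / 20))  # >= 20 dB down
})

test_that("short series come back unfiltered but flagged", {
  expect_warning(out <- lowpass(1:5, 3, 24), "warm-up")
  expect_equal(as.numeric(out), 1:5)
  expect_false(attr(out, "filtered"))
})

test_that("auto cutoff brackets a pure 1 Hz tone between 1 and 2 Hz", {
  t <- (0:239) / 24
  cut <- auto_cutoff(sin(2 * pi * t), fps = 24)
  expect_gte(cut, 1)
  expect_lte(cut, 2)
})
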