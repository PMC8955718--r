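# Synthetic-climb generator: determinism, projection consistency, match
# structure, rendering.

test_that("identical seeds give byte-identical artifact files", {
  cfg <- synth_config(duration_s = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_run(cfg, seed = 4, out_dir = d1)
  generate_run(cfg, seed = 4, out_dir = d2)
  files <- c("matches.csv", "detections.csv", "truth.json")
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  p1 <- sort(list.files(file.path(d1, "pose"), full.names = TRUE))
  p2 <- sort(list.files(file.path(d2, "pose"), full.names = TRUE))
  expect_equal(length(p1), length(p2))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
})

test_that("noiseless hold pairs reproduce the true per-frame scale", {
  run <- noiseless_run()
  map <- default_route_map()
  det <- run$detections
  for (f in c(0L, 50L, 100L)) {
    d <- det[det$frame == f, ]
    expect_gte(nrow(d), 2L)
    for (pair in list(c(1L, 2L), c(1L, nrow(d)))) {
      m1 <- map[match(d$true_id[pair[1]], map$id), ]
      m2 <- map[match(d$true_id[pair[2]], map$id), ]
      s <- pairwise_scale(d$x[pair[1]] - d$x[pair[2]],
                          d$y[pair[1]] - d$y[pair[2]],
                          m1$x_m - m2$x_m, m1$y_m - m2$y_m)
      expect_equal(s, run$truth$camera$s[f + 1L], tolerance = 1e-6)
    }
  }
})

test_that("ground-truth scale obeys s = A cos(alpha) exactly", {
  run <- default_run()
  cam <- run$truth$camera
  expect_equal(cam$s, run$truth$params$A * cos(cam$alpha), tolerance = 1e-12)
})

test_that("inlier match displacement equals the camera shift exactly", {
  run <- default_run()          # sigma = 2: jitter is endpoint-correlated
  m <- run$matches
  inl <- m[m$inlier, ]
  for (f in c(1L, 40L, 120L)) {
    g <- inl[inl$frame == f, ]
    expect_equal(g$y_curr - g$y_prev,
                 rep(run$truth$gamma[f], nrow(g)), tolerance = 1e-9)
    expect_equal(g$x_curr, g$x_prev, tolerance = 1e-9)
  }
})

test_that("dwell intervals are non-overlapping per limb", {
  for (run in list(default_run(), noiseless_run())) {
    d <- run$truth$dwell_intervals
    for (l in unique(d$limb)) {
      e <- d[d$limb == l, ]
      e <- e[order(e$t_start), ]
      expect_true(all(e$t_end > e$t_start))
      if (nrow(e) > 1)
        expect_true(all(e$t_start[-1] >= e$t_end[-nrow(e)] - 1e-9))
    }
  }
})

test_that("an explicit dwell schedule past the run end is rejected", {
  sched <- data.frame(limb = "rh", hold_id = 1L, t_start = 0, t_end = 99)
  expect_error(generate_run(synth_config(duration_s = 2), seed = 1,
                            schedule = sched),
               "dwell schedule exceeds run duration")
})

test_that("rendered frames contain one red region per visible hold", {
  run <- cached("render_run", function()
    generate_run(synth_config(duration_s = 1, sigma_px = 0, dropout = 0,
                              outlier_frac = 0), seed = 6))
  for (frame in c(0L, 12L)) {
    img <- render_frame(run, frame)
    n_vis <- sum(run$detections$frame == frame)
    regs <- hsv_segment_holds(img)
    expect_equal(nrow(regs), n_vis)
    # centroids within 1 px (scaled) of the projected hold centers
    d <- run$detections[run$detections$frame == frame, ]
    f <- 4  # renderer scale_down default
    for (k in seq_len(nrow(d))) {
      dist <- sqrt((regs$cx - d$x[k] / f)^2 + (regs$cy - d$y[k] / f)^2)
      expect_lte(min(dist), 1)
    }
  }
})

test_that("a frame with no holds in view renders a uniform wall", {
  run <- cached("render_run", function()
    generate_run(synth_config(duration_s = 1, sigma_px = 0, dropout = 0,
                              outlier_frac = 0), seed = 6))
  far_map <- default_route_map()
  far_map$y_m <- far_map$y_m / far_map$y_m * 14.9   # all at the top, out of view
  img <- render_frame(run, 0L, route_map = far_map)
  expect_equal(sd(img), 0)
  expect_equal(nrow(hsv_segment_holds(img)), 0L)
})

test_that("the spotlight gradient changes V but never H", {
  run <- cached("render_run", function()
    generate_run(synth_config(duration_s = 1, sigma_px = 0, dropout = 0,
                              outlier_frac = 0), seed = 6))
  plain <- render_frame(run, 0L)
  lit <- render_frame(run, 0L, spotlight = TRUE)
  to_hsv <- function(img)
    rgb2hsv(rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                  as.vector(img[, , 3])), maxColorValue = 1)
  h1 <- to_hsv(plain); h2 <- to_hsv(lit)
  expect_equal(h2[1, ], h1[1, ], tolerance = 1e-12)   # hue untouched
  expect_gt(mean(abs(h2[3, ] - h1[3, ])), 0.01)       # value shifted
})
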