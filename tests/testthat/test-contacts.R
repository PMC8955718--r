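# Contact detection, hold association, inter-hold timing, HSV segmentation.

test_that("constant speed above threshold yields no contacts", {
  out <- detect_contacts(rep(1, 200), fps = 24, eps = 0.2)
  expect_equal(nrow(out), 0L)
})

test_that("a rectified sine yields one contact per zero", {
  t <- (0:48) / 24                       # 2 s inclusive
  speed <- abs(sin(2 * pi * t / 2))      # zeros at t = 0, 1, 2 s
  out <- detect_contacts(speed, fps = 24, eps = 0.1)
  expect_equal(nrow(out), 3L)
  centers <- (out$t_touch_s + out$t_release_s) / 2
  expect_true(all(abs(centers - c(0, 1, 2)) <= 1.5 / 24))
})

test_that("contact durations are sane and bounded by the run length", {
  sr <- default_analysis()
  run <- default_run()
  dur <- run$truth$params$duration_s
  expect_true(all(sr$contacts$duration_s >= 0))
  for (l in unique(sr$contacts$limb)) {
    d <- sr$contacts[sr$contacts$limb == l, ]
    expect_lte(sum(d$duration_s), dur)
    # per-limb intervals must not overlap
    d <- d[order(d$t_touch_s), ]
    if (nrow(d) > 1)
      expect_true(all(d$t_touch_s[-1] >= d$t_release_s[-nrow(d)]))
  }
})

test_that("lowering eps never increases the interval count", {
  # holds over the detector's operating range; an eps below the speed
  # noise floor (~0.1 m/s at 2 px keypoint noise) fragments dips instead
  sr <- default_analysis()
  for (sp in sr$limb_speed) {
    counts <- vapply(c(0.30, 0.25, 0.20, 0.15, 0.10),
                     function(e) nrow(detect_contacts(sp, 24, e)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("hold association picks the hold under the limb, within radius", {
  run <- noiseless_run()
  sr <- noiseless_analysis()
  tracks <- sr$tracks
  iv <- data.frame(start = 60L, end = 70L, t_touch_s = 2.5,
                   t_release_s = 2.9, duration_s = 0.4, sub_eps_s = 0.4)
  # the midpoint frame of the interval is where association happens
  pos7 <- hold_positions_at(tracks, 65L)
  target <- pos7[1, ]
  limb_x <- rep(target$x, 200); limb_y <- rep(target$y, 200)
  got <- assign_contact_holds(iv, limb_x, limb_y, tracks, limb = "rh")
  expect_equal(got$hold_id, target$map_id)

  far <- assign_contact_holds(iv, limb_x + 500, limb_y, tracks,
                              radius_px = 60, limb = "rh")
  expect_true(is.na(far$hold_id))
})

test_that("synthetic contacts match the dwell schedule in count, IoU, ids", {
  run <- default_run()                    # sigma = 2 px study conditions
  sr <- default_analysis()
  for (nm in c("rh", "lh", "rf", "lf")) {
    tv <- limb_truth(run, nm)
    dv <- sr$contacts[sr$contacts$limb == nm, ]
    expect_equal(nrow(dv), nrow(tv))
    for (k in seq_len(nrow(tv))) {
      expect_gte(iou_interval(dv$t_touch_s[k], dv$t_release_s[k],
                              tv$t_start[k], tv$t_end[k]), 0.7)
      expect_equal(dv$hold_id[k], tv$hold_id[k])
    }
  }
})

test_that("time between holds uses first touches", {
  contacts <- data.frame(limb = c("rh", "lh", "rh"),
                         hold_id = c(3L, 5L, 3L),
                         t_touch_s = c(1.0, 2.5, 4.0))
  expect_equal(time_between_holds(contacts, 3L, 5L), 1.5)
  expect_equal(time_between_holds(contacts, 3L, 3L), 0)
  expect_error(time_between_holds(contacts, 3L, 9L), "never touched")
})

test_that("inter-hold times recovered from a synthetic run match truth", {
  run <- default_run()
  sr <- default_analysis()
  d <- run$truth$dwell_intervals
  ft <- function(h) min(d$t_start[d$hold_id == h])
  for (pair in list(c(1L, 5L), c(3L, 7L))) {
    truth_dt <- ft(pair[2]) - ft(pair[1])
    got_dt <- time_between_holds(sr$contacts, pair[1], pair[2])
    expect_lte(abs(got_dt - truth_dt), 2 / 24)
  }
})

test_that("the HSV segmenter ignores sub-threshold specks", {
  img <- array(0.5, dim = c(90, 120, 3))
  # one real hold-sized disc and one 2 px speck
  disc <- function(img, cx, cy, r) {
    for (ch in 1:3) {
      m <- outer(seq_len(90), seq_len(120),
                 function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
      img[, , ch][m] <- c(0.85, 0.08, 0.08)[ch]
    }
    img
  }
  img <- disc(img, 40, 40, 8)
  img <- disc(img, 100, 20, 1.2)
  regs <- hsv_segment_holds(img, min_area = 20, morph_radius = 1)
  expect_equal(nrow(regs), 1L)
  expect_lt(abs(regs$cx - 40) + abs(regs$cy - 40), 3)
  # an all-gray frame has nothing to segment
  expect_equal(nrow(hsv_segment_holds(array(0.5, dim = c(60, 60, 3)))), 0L)
})

test_that("segmentation is robust to the spotlight gradient", {
  run <- cached("render_run", function()
    generate_run(synth_config(duration_s = 1, sigma_px = 0, dropout = 0,
                              outlier_frac = 0), seed = 6))
  plain <- hsv_segment_holds(render_frame(run, 5L))
  lit <- hsv_segment_holds(render_frame(run, 5L, spotlight = TRUE))
  expect_equal(nrow(lit), nrow(plain))
  expect_equal(lit$cx, plain$cx, tolerance = 1)
  expect_equal(lit$cy, plain$cy, tolerance = 1)
})
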