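# Synthetic-climb generator: world-space climber + panning tripod camera
# -> pose JSON, feature-match pairs, hold detections, and ground truth for
# every pipeline stage.
#
# The generator emulates exactly the statistical structure the pipeline
# assumes: a climber ascending the 15 m wall with zero-velocity dwell
# intervals of the limbs on route-map holds; a camera that keeps the athlete
# vertically centered; a per-frame affine projection with scale
# s_i = A cos(alpha_i); keypoints perturbed by Gaussian noise and dropped
# out i.i.d.; and match pairs of static wall points displaced by exactly the
# camera shift, plus a controllable fraction of horizontal-displacement
# outliers.

#' Configuration of a synthetic climb
#'
#' @param fps frame rate (1/s).
#' @param duration_s run length; `NA` in the constant profile derives it
#'   from the wall height and speed.
#' @param profile `"cadence"` (fixed limb cadence, torso spline through the
#'   hand events -- the default training-like run), `"constant"` (torso
#'   ascends at `speed_ms` exactly) or `"static"` (climber frozen, camera
#'   pans -- the compensation-identity fixture).
#' @param camera `"rotate"` (tripod rotation: `s_i = A cos(alpha_i)` varies)
#'   or `"translate"` (constant scale; image motion is a pure translation).
#' @param A scale amplitude `c*f/d` (px/m).
#' @param B angle gain `c*f` (px).
#' @param alpha0 start angle (rad).
#' @param speed_ms torso speed for the constant profile (m/s).
#' @param sigma_px Gaussian keypoint/detection noise (px).
#' @param dropout i.i.d. keypoint dropout probability.
#' @param outlier_frac fraction of match pairs replaced by horizontal
#'   outliers.
#' @param n_matches match pairs per frame transition.
#' @param lane `"left"`, `"right"` or `"both"` (two athletes).
#' @param image_w,image_h image size (px).
#' @param hold_size_m rendered/detected hold diameter (m).
#' @param dwell_s,cadence_s dwell length and inter-touch spacing of the
#'   cadence profile (s).
#' @param reach_m,release_m hand reach above the torso at touch and at
#'   release (m).
#' @param foot_offset_m foot depth below the torso at touch (m).
#' @param pan_amp_m,pan_hz camera pan path of the static profile.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(fps = 24, duration_s = 6,
                         profile = c("cadence", "constant", "static"),
                         camera = c("rotate", "translate"),
                         A = 400, B = 5000, alpha0 = -0.2,
                         speed_ms = 1.5, sigma_px = 2, dropout = 0.05,
                         outlier_frac = 0.2, n_matches = 80,
                         lane = "left", image_w = 1280, image_h = 720,
                         hold_size_m = 0.20, dwell_s = 0.55,
                         cadence_s = 0.45, reach_m = 0.7, release_m = 0.25,
                         foot_offset_m = 0.8, pan_amp_m = 0.5,
                         pan_hz = 0.4) {
  profile <- match.arg(profile)
  camera <- match.arg(camera)
  stopifnot(fps > 0, A > 0, B > 0, sigma_px >= 0,
            dropout >= 0, dropout < 1, outlier_frac >= 0, outlier_frac < 1)
  if (profile == "constant" && is.na(duration_s)) duration_s <- NA
  structure(as.list(environment()), class = "synth_config")
}

lane_offset <- function(lane) if (identical(lane, "right")) 3.6 else 0

#' Generate a synthetic climbing run
#'
#' @param config [synth_config()].
#' @param seed integer; fixes all randomness.
#' @param out_dir if given, writes `pose/` (per-frame JSON),
#'   `matches.csv`, `detections.csv` and `truth.json` there.
#' @param route_map route map (defaults to the bundled one).
#' @param schedule optional explicit dwell schedule: data.frame `limb`,
#'   `hold_id`, `t_start`, `t_end` (overrides the profile-derived one;
#'   must fit inside the run duration).
#' @return List of class `synth_run`: `truth`, `pose` (list of frames, each
#'   a list of 25 x 3 person matrices), `matches`, `detections`, `config`.
#' @export
generate_run <- function(config = synth_config(), seed = 1L, out_dir = NULL,
                         route_map = default_route_map(),
                         schedule = NULL) {
  set.seed(as.integer(seed))
  cfg <- config
  map <- route_map

  # ---- timing -------------------------------------------------------------
  duration <- cfg$duration_s
  if (cfg$profile == "constant" && is.na(duration)) {
    top <- max(map$y_m[map$kind == "hand"])
    duration <- (top - cfg$reach_m - 0.3) / cfg$speed_ms + 0.6
  }
  n <- round(duration * cfg$fps)
  t <- (seq_len(n) - 1L) / cfg$fps

  athletes <- switch(cfg$lane, both = c("left", "right"), cfg$lane)
  prim <- athletes[1L]

  # ---- schedule + world motion for each athlete ---------------------------
  worlds <- lapply(seq_along(athletes), function(ai) {
    off <- if (ai == 1L) 0 else 0.15     # second athlete slightly delayed
    build_world(cfg, map, t, duration, time_offset = off,
                schedule = if (ai == 1L) schedule else NULL)
  })

  # ---- camera -------------------------------------------------------------
  w1 <- worlds[[1L]]
  cam <- build_camera(cfg, t, w1$torso_y)
  x0 <- cfg$image_w / 2; y0 <- cfg$image_h / 2
  c_x <- mean(vapply(athletes, lane_offset, numeric(1))) + 1.5

  proj_x <- function(x_m, lane, i)
    x0 + cam$s[i] * (x_m + lane_offset(lane) - c_x)
  proj_y <- function(y_m, i) y0 - cam$s[i] * (y_m - cam$c_y[i])

  # ---- pose records -------------------------------------------------------
  pose <- vector("list", n)
  for (i in seq_len(n)) pose[[i]] <- list()
  for (ai in seq_along(athletes)) {
    wx <- worlds[[ai]]$kp_x; wy <- worlds[[ai]]$kp_y
    lane <- athletes[ai]
    keep <- match(retained_keypoints(), body25_names())
    for (i in seq_len(n)) {
      rec <- matrix(0, 25L, 3L,
                    dimnames = list(body25_names(), c("x", "y", "conf")))
      px <- proj_x(wx[i, ], lane, i) + rnorm(19L, 0, cfg$sigma_px)
      py <- proj_y(wy[i, ], i) + rnorm(19L, 0, cfg$sigma_px)
      conf <- runif(19L, 0.4, 0.95)
      drop <- runif(19L) < cfg$dropout
      px[drop] <- 0; py[drop] <- 0; conf[drop] <- 0
      rec[keep, 1L] <- px; rec[keep, 2L] <- py; rec[keep, 3L] <- conf
      pose[[i]][[length(pose[[i]]) + 1L]] <- rec
    }
  }

  # ---- hold detections ----------------------------------------------------
  det <- list()
  for (lane in athletes) {
    for (i in seq_len(n)) {
      hx <- proj_x(map$x_m, lane, i)
      hy <- proj_y(map$y_m, i)
      vis <- hx >= 0 & hx <= cfg$image_w & hy >= 0 & hy <= cfg$image_h
      if (!any(vis)) next
      m <- sum(vis)
      det[[length(det) + 1L]] <- data.frame(
        frame = i - 1L, class = "hold",
        x = hx[vis] + rnorm(m, 0, cfg$sigma_px),
        y = hy[vis] + rnorm(m, 0, cfg$sigma_px),
        w = cam$s[i] * cfg$hold_size_m, h = cam$s[i] * cfg$hold_size_m,
        confidence = runif(m, 0.75, 0.99),
        true_id = map$id[vis])
    }
  }
  detections <- do.call(rbind, det)

  # ---- match pairs --------------------------------------------------------
  mt <- list()
  for (i in 2:n) {
    m <- cfg$n_matches
    y_m <- runif(m, cam$c_y[i - 1L] - 0.8, cam$c_y[i - 1L] + 0.8)
    x_m <- runif(m, 0.1, 2.9)
    xp <- proj_x(x_m, prim, i - 1L) + rnorm(m, 0, cfg$sigma_px)
    yp <- proj_y(y_m, i - 1L) + rnorm(m, 0, cfg$sigma_px)
    # inliers: displacement is exactly the camera shift (down positive)
    xc <- xp
    yc <- yp + cam$gamma[i - 1L]
    n_out <- round(cfg$outlier_frac * m)
    if (n_out > 0) {
      o <- seq_len(n_out)
      xc[o] <- xp[o] + sample(c(-1, 1), n_out, TRUE) * runif(n_out, 10, 80)
      yc[o] <- yp[o] + runif(n_out, -2, 2)
    }
    mt[[i - 1L]] <- data.frame(frame = i - 1L, x_prev = xp, y_prev = yp,
                               x_curr = xc, y_curr = yc,
                               inlier = c(rep(FALSE, n_out),
                                          rep(TRUE, m - n_out)))
  }
  matches <- do.call(rbind, mt)

  # ---- ground truth -------------------------------------------------------
  cogw <- w1$cog
  truth <- list(
    params = list(A = cfg$A, B = cfg$B, alpha0 = cfg$alpha0, fps = cfg$fps,
                  sigma_px = cfg$sigma_px, dropout = cfg$dropout,
                  outlier_frac = cfg$outlier_frac, camera = cfg$camera,
                  profile = cfg$profile, lane = cfg$lane,
                  image_w = cfg$image_w, image_h = cfg$image_h,
                  duration_s = duration, n_frames = n),
    camera = data.frame(frame = seq_len(n) - 1L, alpha = cam$alpha,
                        s = cam$s, c_y = cam$c_y),
    gamma = cam$gamma,
    cog_world = data.frame(frame = seq_len(n) - 1L, t = t,
                           x = cogw$x, y = cogw$y),
    dwell_intervals = w1$dwell,
    limb_world = w1$limbs,
    sides = athletes)
  run <- structure(list(truth = truth, pose = pose, matches = matches,
                        detections = detections, config = cfg),
                   class = "synth_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pose_sequence(pose, file.path(out_dir, "pose"))
    write_matches(matches[, 1:5], file.path(out_dir, "matches.csv"))
    write_detections(detections[, 1:7], file.path(out_dir, "detections.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  run
}

# -- internals --------------------------------------------------------------

smoothstep <- function(u) { u <- pmin(pmax(u, 0), 1); u * u * (3 - 2 * u) }

# per-limb event table -> world position series with exact dwell plateaus
limb_path <- function(events, pos, t, duration) {
  n <- length(t)
  x <- numeric(n); y <- numeric(n)
  ne <- nrow(events)
  if (!ne) return(list(x = rep(1.5, n), y = rep(0.5, n)))
  for (i in seq_len(n)) {
    ti <- t[i]
    k <- findInterval(ti, events$t_touch)
    if (k == 0L) {                       # approach to the first hold
      p1 <- c(pos$x[1L], pos$y[1L])
      p0 <- p1 - c(0, 0.4)
      u <- if (events$t_touch[1L] > 0) ti / events$t_touch[1L] else 1
      p <- p0 + (p1 - p0) * sin(min(u, 1) * pi / 2)
    } else if (ti <= events$t_release[k] || k == ne) {
      p <- c(pos$x[k], pos$y[k])         # dwell (last hold is kept forever)
    } else {
      u <- (ti - events$t_release[k]) /
        (events$t_touch[k + 1L] - events$t_release[k])
      p <- c(pos$x[k], pos$y[k]) +
        (c(pos$x[k + 1L], pos$y[k + 1L]) - c(pos$x[k], pos$y[k])) *
        smoothstep(u)
    }
    x[i] <- p[1L]; y[i] <- p[2L]
  }
  list(x = x, y = y)
}

build_world <- function(cfg, map, t, duration, time_offset = 0,
                        schedule = NULL) {
  hand <- map[map$kind == "hand", ]; hand <- hand[order(hand$id), ]
  foot <- map[map$kind == "foot", ]; foot <- foot[order(foot$y_m), ]
  foot_targets <- rbind(foot,
                        hand[hand$y_m > max(foot$y_m) + 0.1, ])

  mk_events <- function(ids, t_touch, t_release) {
    keep <- t_touch <= duration - 0.15 & t_touch < t_release
    e <- data.frame(hold_id = ids, t_touch = t_touch,
                    t_release = pmin(t_release, duration))[keep, ]
    # drop events overlapping their predecessor (skipped hold)
    if (nrow(e) > 1L) {
      ok <- c(TRUE, diff(e$t_touch) > 0 & e$t_touch[-1L] >
                e$t_release[-nrow(e)] - 1e-9)
      e <- e[ok, ]
    }
    e
  }

  limbs <- list()
  if (cfg$profile == "static") {
    ids <- list(rh = hand$id[1L], lh = hand$id[2L],
                rf = foot$id[1L], lf = foot$id[2L])
    events <- lapply(ids, function(id)
      data.frame(hold_id = id, t_touch = 0, t_release = duration))
    torso_y <- rep(min(hand$y_m[1:2]) - cfg$reach_m + 0.35, length(t))
    torso_x <- rep(1.5, length(t))
  } else if (cfg$profile == "constant") {
    y0 <- 0.3; v <- cfg$speed_ms
    torso_y <- pmin(pmax(y0 + v * (t - time_offset), y0), max(map$y_m))
    torso_x <- rep(1.5, length(t))
    hand_ev <- function(h) {
      tt <- pmax(0, (h$y_m - cfg$reach_m - y0) / v) + time_offset
      tr <- pmax(tt + 0.25, (h$y_m - cfg$release_m - y0) / v + time_offset)
      mk_events(h$id, tt, tr)
    }
    foot_ev <- function(f) {
      tt <- pmax(0, (f$y_m + cfg$foot_offset_m - y0) / v) + time_offset
      tr <- pmax(tt + 0.2,
                 (f$y_m + cfg$foot_offset_m + 0.45 - y0) / v + time_offset)
      mk_events(f$id, tt, tr)
    }
    odd <- function(d) d[seq(1, nrow(d), 2), ]
    even <- function(d) d[seq(2, nrow(d), 2), ]
    events <- list(rh = hand_ev(odd(hand)), lh = hand_ev(even(hand)),
                   rf = foot_ev(odd(foot_targets)),
                   lf = foot_ev(even(foot_targets)))
  } else {                              # cadence
    kh <- seq_len(nrow(hand))
    tt_h <- (kh - 1L) * cfg$cadence_s + time_offset
    tr_h <- tt_h + cfg$dwell_s
    kf <- seq_len(nrow(foot_targets))
    tt_f <- 0.2 + (kf - 1L) * cfg$cadence_s + time_offset
    tr_f <- tt_f + cfg$dwell_s
    odd <- function(v) v[seq(1, length(v), 2)]
    even <- function(v) v[seq(2, length(v), 2)]
    events <- list(
      rh = mk_events(odd(hand$id), odd(tt_h), odd(tr_h)),
      lh = mk_events(even(hand$id), even(tt_h), even(tr_h)),
      rf = mk_events(odd(foot_targets$id), odd(tt_f), odd(tr_f)),
      lf = mk_events(even(foot_targets$id), even(tt_f), even(tr_f)))
    # torso spline through the (combined) hand-touch events
    kept <- tt_h <= duration - 0.15
    tk <- tt_h[kept]
    yk <- hand$y_m[kept] - cfg$reach_m
    if (length(tk) < 2L) stop("dwell schedule exceeds run duration")
    slope <- (yk[length(yk)] - yk[length(yk) - 1L]) /
      (tk[length(tk)] - tk[length(tk) - 1L])
    if (tail(tk, 1) < max(t)) {
      tk <- c(tk, max(t)); yk <- c(yk, tail(yk, 1) + slope *
                                     (max(t) - tail(tk[-length(tk)], 1)))
    }
    if (tk[1L] > 0) { tk <- c(0, tk); yk <- c(yk[1L], yk) }
    torso_y <- splinefun(tk, yk, method = "hyman")(t)
    xk <- 0.3 * hand$x_m[kept] + 0.7 * 1.5
    torso_x <- splinefun(tt_h[kept], xk, method = "natural")(t)
  }

  # race-start posture: every limb is already placed on its first target
  # when the clock starts, so the first dwell opens at t = 0
  if (cfg$profile != "static")
    events <- lapply(events, function(e) {
      if (nrow(e)) e$t_touch[1L] <- 0
      e
    })

  if (!is.null(schedule)) {
    if (any(schedule$t_end > duration + 1e-9))
      stop("dwell schedule exceeds run duration")
    events <- lapply(split(schedule, schedule$limb), function(g)
      data.frame(hold_id = g$hold_id, t_touch = g$t_start,
                 t_release = g$t_end))
  }
  for (e in events)
    if (nrow(e) && any(e$t_touch > duration))
      stop("dwell schedule exceeds run duration")

  pos_of <- function(e) data.frame(x = map$x_m[match(e$hold_id, map$id)],
                                   y = map$y_m[match(e$hold_id, map$id)])
  paths <- lapply(events, function(e) limb_path(e, pos_of(e), t, duration))

  # dwell truth: last dwell of each limb extends to the run end
  dwell <- do.call(rbind, lapply(names(events), function(nm) {
    e <- events[[nm]]
    if (!nrow(e)) return(NULL)
    t_end <- e$t_release
    t_end[nrow(e)] <- max(t)            # held until the recording ends
    data.frame(limb = nm, hold_id = e$hold_id, t_start = e$t_touch,
               t_end = t_end)
  }))

  # skeleton synthesis (world coordinates, y up, meters)
  n <- length(t)
  nm19 <- retained_keypoints()
  kx <- matrix(0, n, 19L, dimnames = list(NULL, nm19))
  ky <- matrix(0, n, 19L, dimnames = list(NULL, nm19))
  set <- function(kp, x, y) { kx[, kp] <<- x; ky[, kp] <<- y }
  set("mid_hip", torso_x, torso_y)
  set("r_hip", torso_x + 0.12, torso_y)
  set("l_hip", torso_x - 0.12, torso_y)
  set("neck", torso_x, torso_y + 0.55)
  set("nose", torso_x, torso_y + 0.73)
  set("r_shoulder", torso_x + 0.19, torso_y + 0.55)
  set("l_shoulder", torso_x - 0.19, torso_y + 0.55)
  set("r_wrist", paths$rh$x, paths$rh$y)
  set("l_wrist", paths$lh$x, paths$lh$y)
  set("r_elbow", (kx[, "r_shoulder"] + kx[, "r_wrist"]) / 2 + 0.07,
      (ky[, "r_shoulder"] + ky[, "r_wrist"]) / 2)
  set("l_elbow", (kx[, "l_shoulder"] + kx[, "l_wrist"]) / 2 - 0.07,
      (ky[, "l_shoulder"] + ky[, "l_wrist"]) / 2)
  set("r_big_toe", paths$rf$x, paths$rf$y)
  set("l_big_toe", paths$lf$x, paths$lf$y)
  set("r_ankle", paths$rf$x + 0.04, paths$rf$y + 0.10)
  set("l_ankle", paths$lf$x - 0.04, paths$lf$y + 0.10)
  set("r_heel", kx[, "r_ankle"] + 0.06, ky[, "r_ankle"] - 0.04)
  set("l_heel", kx[, "l_ankle"] - 0.06, ky[, "l_ankle"] - 0.04)
  set("r_knee", (kx[, "r_hip"] + kx[, "r_ankle"]) / 2 + 0.10,
      (ky[, "r_hip"] + ky[, "r_ankle"]) / 2)
  set("l_knee", (kx[, "l_hip"] + kx[, "l_ankle"]) / 2 - 0.10,
      (ky[, "l_hip"] + ky[, "l_ankle"]) / 2)

  cogw <- cog_series(list(x = kx, y = ky, frame = seq_len(n) - 1L))
  list(torso_x = torso_x, torso_y = torso_y, kp_x = kx, kp_y = ky,
       cog = data.frame(x = cogw$x_px, y = cogw$y_px),
       dwell = dwell,
       limbs = lapply(paths, function(p) data.frame(t = t, x = p$x, y = p$y)),
       events = events)
}

build_camera <- function(cfg, t, torso_y) {
  n <- length(t)
  c_y <- if (cfg$profile == "static")
    torso_y[1L] + cfg$pan_amp_m * sin(2 * pi * cfg$pan_hz * t)
  else torso_y
  if (cfg$camera == "translate") {
    alpha <- rep(cfg$alpha0, n)
    s <- rep(cfg$A * cos(cfg$alpha0), n)
    gamma <- s[1L] * diff(c_y)
  } else {
    d <- cfg$B / cfg$A
    h_cam <- c_y[1L] - d * tan(cfg$alpha0)
    alpha <- atan((c_y - h_cam) / d)
    s <- cfg$A * cos(alpha)
    gamma <- cfg$B * diff(alpha) / cos(alpha[-n])
  }
  list(alpha = alpha, s = s, gamma = gamma, c_y = c_y)
}

#' @export
print.synth_run <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "Synthetic run: %d frames @ %g fps, profile '%s', camera '%s'\n",
    p$n_frames, p$fps, p$profile, p$camera))
  cat(sprintf("  A = %g px/m, B = %g px, alpha0 = %g rad, sigma = %g px\n",
              p$A, p$B, p$alpha0, p$sigma_px))
  cat(sprintf("  %d dwell intervals, %d detections, %d match pairs\n",
              nrow(x$truth$dwell_intervals), nrow(x$detections),
              nrow(x$matches)))
  invisible(x)
}
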