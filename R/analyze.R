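# Pipeline orchestration: from raw artifacts to a summarised run.

#' Analyse a speed-climbing run
#'
#' Runs the full pipeline: read/reduce pose keypoints, pick the athlete on
#' the requested side, estimate camera motion from match pairs, track and
#' identify holds, calibrate the scale model, interpolate keypoints, compute
#' the center of gravity, velocities and joint angles, detect hold contacts
#' from filtered limb-speed curves, and assemble the parameter set.
#'
#' @param pose pose input: directory/file path, list of raw frame records
#'   ([read_pose_sequence()]) or a `synth_run`. When a `synth_run` is given
#'   its matches/detections are used and the remaining arguments may be
#'   omitted.
#' @param detections detections CSV path or data.frame.
#' @param matches matches CSV path or data.frame.
#' @param route_map route map (path or data.frame).
#' @param config [run_config()].
#' @param table anthropometric table.
#' @param sections section table.
#' @param lane `"left"`, `"right"` or `NULL` (side with the most valid
#'   frames).
#' @param image_w image width in pixels (lane split midline).
#' @return Object of class `speed_run`.
#' @export
analyze_run <- function(pose, detections = NULL, matches = NULL,
                        route_map = default_route_map(),
                        config = run_config(),
                        table = default_anthropometric_table(),
                        sections = default_sections(), lane = NULL,
                        image_w = 1280) {
  if (inherits(pose, "synth_run")) {
    run <- pose
    if (is.null(detections)) detections <- run$detections[, 1:7]
    if (is.null(matches)) matches <- run$matches[, 1:5]
    image_w <- run$config$image_w
    config$fps <- run$config$fps
    pose <- run$pose
  }
  records <- if (is.character(pose)) read_pose_sequence(pose) else pose
  if (is.character(detections)) detections <- read_detections(detections)
  if (is.character(matches)) matches <- read_matches(matches)
  if (is.character(route_map)) route_map <- read_route_map(route_map)
  n <- length(records)

  # athlete selection: one skeleton per image half; frames with a single
  # detected person keep it regardless of the half it straddles
  sel <- select_athlete(records, image_w, lane, config$min_confidence)
  frames <- assign_side(sel$frames, image_w)
  lane <- sel$lane

  # camera motion
  inl <- filter_matches(matches, config$vertical_match_tol_px, config$mad_k)
  gamma <- estimate_shift(inl, n_frames = n)

  # holds and scale
  tracks <- track_and_identify_holds(detections, gamma, route_map)
  s_meas <- measure_scale(tracks, route_map)
  scale <- fit_scale_model(s_meas, gamma)

  # kinematics
  series <- interpolate_missing(pose_series(frames), config$min_confidence)
  cogpx <- cog_series(series, table)
  vel <- velocity(cogpx$x_px, cogpx$y_px, gamma, scale, config$fps,
                  config$pixel_y_axis)
  cutoff <- config$lowpass_cutoff_hz
  if (identical(cutoff, "auto")) cutoff <- auto_cutoff(vel$v_y, config$fps)
  # filter the velocity *components*, then take the magnitude: filtering the
  # magnitude itself would keep the mean of the rectified noise as a bias
  vel$speed_filt <- filtered_speed(vel, cutoff, config$fps,
                                   config$lowpass_order)
  vel$t_s <- (vel$frame + 0.5) / config$fps   # finite-difference midpoint
  angles <- joint_angles(series, config$pixel_y_axis)

  # contacts from limb-speed curves
  limb_kp <- c(rh = "r_wrist", lh = "l_wrist",
               rf = "r_big_toe", lf = "l_big_toe")
  contacts <- list()
  limb_speed <- list()
  for (nm in names(limb_kp)) {
    kp <- limb_kp[[nm]]
    lv <- velocity(series$x[, kp], series$y[, kp], gamma, scale,
                   config$fps, config$pixel_y_axis)
    sp <- filtered_speed(lv, cutoff, config$fps, config$lowpass_order)
    limb_speed[[nm]] <- sp
    iv <- detect_contacts(sp, config$fps, config$contact_speed_eps)
    contacts[[nm]] <- assign_contact_holds(
      iv, series$x[, kp], series$y[, kp], tracks,
      radius_px = config$contact_radius_px, limb = nm, fps = config$fps)
  }
  contacts <- do.call(rbind, contacts)
  rownames(contacts) <- NULL

  final_hold <- max(route_map$id[route_map$kind == "hand"])
  parameters <- compute_parameters(
    data.frame(t_s = vel$t_s, speed = vel$speed_filt),
    contacts, angles, sections, config$fps, final_hold)

  # metric COG track: integrated camera-compensated displacements
  cog <- data.frame(frame = cogpx$frame, t_s = cogpx$frame / config$fps,
                    x_px = cogpx$x_px, y_px = cogpx$y_px,
                    x_m = cumsum(c(0, vel$v_x)) / config$fps,
                    y_m = cumsum(c(0, vel$v_y)) / config$fps,
                    speed_ms = c(vel$speed_filt, NA_real_))

  structure(list(frames = frames, gamma = gamma, tracks = tracks,
                 scale = scale, series = series, cog = cog, vel = vel,
                 angles = angles, limb_speed = limb_speed,
                 contacts = contacts, parameters = parameters,
                 config = config, sections = sections, lane = lane),
            class = "speed_run")
}

filtered_speed <- function(vel, cutoff, fps, order = 2) {
  vx <- as.numeric(lowpass(vel$v_x, cutoff, fps, order))
  vy <- as.numeric(lowpass(vel$v_y, cutoff, fps, order))
  sqrt(vx^2 + vy^2)
}

#' @export
print.speed_run <- function(x, ...) {
  cat(sprintf("Speed-climbing run (%s lane): %d frames @ %g fps\n",
              x$lane, nrow(x$cog), x$config$fps))
  cat(sprintf("  scale A = %.1f px/m, camera pan total %.0f px\n",
              x$scale$A, tail(x$gamma$cumulative_px, 1)))
  cat(sprintf("  %d contact intervals on %d identified holds\n",
              nrow(x$contacts), sum(!is.na(x$tracks$tracks$map_id))))
  et <- x$parameters$endtime_s
  cat(sprintf("  endtime: %s\n", if (is.na(et)) "unavailable"
              else sprintf("%.3f s", et)))
  invisible(x)
}

#' @export
summary.speed_run <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$parameters)
  invisible(object)
}

#' @export
plot.speed_run <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1)); on.exit(par(op))
  plot(x$vel$t_s, x$vel$speed_filt, type = "l", xlab = "time (s)",
       ylab = "COG speed (m/s)", main = "Center-of-gravity speed", ...)
  sp <- x$limb_speed$rf
  plot(x$vel$t_s, sp, type = "l", xlab = "time (s)",
       ylab = "right-foot speed (m/s)", main = "Right foot with contacts")
  cf <- x$contacts[x$contacts$limb == "rf", ]
  if (nrow(cf))
    rect(cf$t_touch_s, 0, cf$t_release_s, max(sp, na.rm = TRUE),
         col = grDevices::adjustcolor("green", 0.3), border = NA)
  invisible(x)
}

#' Per-limb filtered speed series of an analysed run
#'
#' @param run `speed_run`.
#' @return data.frame `frame`, `t_s`, one column per limb (m/s).
#' @export
limb_speeds <- function(run) {
  data.frame(frame = run$vel$frame, t_s = run$vel$t_s, run$limb_speed)
}
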