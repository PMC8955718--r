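# Run-level parameter set and run synchronization.

#' Compute the run parameter set
#'
#' Sections are delimited by the first-touch times of their boundary holds;
#' within a window the path is the summed metric center-of-gravity
#' displacement, and the speed statistics are taken over the window's
#' frames. The run clock starts at the first frame where the
#' center-of-gravity speed exceeds `start_speed_ms` for `start_frames`
#' consecutive frames, and stops at the first touch of `final_hold`.
#'
#' @param vel data.frame with per-transition columns `t_s` and `speed`
#'   (m/s, low-pass filtered center-of-gravity speed).
#' @param contacts contact data.frame (`limb`, `hold_id`, `t_touch_s`,
#'   `duration_s`).
#' @param angles data.frame from [joint_angles()] (column `sh` used).
#' @param sections section table ([default_sections()]).
#' @param fps frame rate.
#' @param final_hold hold id whose first touch defines the finish.
#' @param start_speed_ms,start_frames start-trigger threshold and dwell.
#' @return Named list of class `run_parameters`; section entries are `NA`
#'   when a boundary hold was never touched.
#' @export
compute_parameters <- function(vel, contacts, angles, sections = default_sections(),
                               fps = 24, final_hold = 20L,
                               start_speed_ms = 0.3, start_frames = 3L) {
  first_touch <- function(h) {
    t <- contacts$t_touch_s[!is.na(contacts$hold_id) & contacts$hold_id == h]
    if (!length(t)) NA_real_ else min(t)
  }
  win_stats <- function(t0, t1) {
    if (is.na(t0) || is.na(t1) || t1 <= t0)
      return(list(path = NA_real_, mean = NA_real_, std = NA_real_,
                  end = NA_real_, time = NA_real_))
    i <- vel$t_s >= t0 & vel$t_s <= t1
    if (!any(i))
      return(list(path = NA_real_, mean = NA_real_, std = NA_real_,
                  end = NA_real_, time = NA_real_))
    sp <- vel$speed[i]
    list(path = sum(sp) / fps, mean = mean(sp), std = sd(sp),
         end = mean(tail(sp, 3L)), time = t1 - t0)
  }

  # start trigger: sustained speed above threshold
  above <- vel$speed > start_speed_ms
  runs <- rle(above)
  t_start <- NA_real_
  if (any(runs$values & runs$lengths >= start_frames)) {
    k <- which(runs$values & runs$lengths >= start_frames)[1L]
    idx <- if (k == 1L) 1L else sum(runs$lengths[seq_len(k - 1L)]) + 1L
    t_start <- vel$t_s[idx]
  }
  t_finish <- first_touch(final_hold)
  endtime <- if (is.na(t_start) || is.na(t_finish)) NA_real_
  else t_finish - t_start

  out <- list(endtime_s = endtime, t_start_s = t_start)
  whole <- win_stats(min(vel$t_s), max(vel$t_s) + 1e-9)
  out$path_m <- whole$path
  out$speed_mean_ms <- whole$mean
  out$speed_std_ms <- whole$std

  for (r in seq_len(nrow(sections))) {
    nm <- sections$name[r]
    st <- win_stats(first_touch(sections$start_hold[r]),
                    first_touch(sections$end_hold[r]))
    out[[paste0(nm, "_path_m")]] <- st$path
    out[[paste0(nm, "_speed_mean_ms")]] <- st$mean
    out[[paste0(nm, "_speed_std_ms")]] <- st$std
    out[[paste0(nm, "_speed_end_ms")]] <- st$end
    out[[paste0(nm, "_time_s")]] <- st$time
  }

  cdur <- function(limbs) {
    d <- contacts$duration_s[contacts$limb %in% limbs]
    c(mean = if (length(d)) mean(d) else NA_real_,
      std = if (length(d) > 1L) sd(d) else NA_real_)
  }
  h <- cdur(c("rh", "lh")); f <- cdur(c("rf", "lf"))
  out$contact_hands_mean_s <- h[["mean"]]
  out$contact_hands_std_s <- h[["std"]]
  out$contact_feet_mean_s <- f[["mean"]]
  out$contact_feet_std_s <- f[["std"]]

  sh <- angles$sh[is.finite(angles$sh)]
  out$sh_mean_deg <- if (length(sh)) mean(sh) else NA_real_
  out$sh_maxmin_deg <- if (length(sh)) max(sh) - min(sh) else NA_real_
  out$sh_std_deg <- if (length(sh) > 1L) sd(sh) else NA_real_
  structure(out, class = "run_parameters")
}

#' @export
print.run_parameters <- function(x, ...) {
  cat("Run parameters\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm,
                if (is.na(x[[nm]])) "NA" else sprintf("%.4f", x[[nm]])))
  invisible(x)
}

#' Synchronize two runs at a hold
#'
#' Shifts both time axes so the first touch of `at_hold` happens at t = 0 in
#' each run, and builds a piecewise-linear warp mapping run A's hold-touch
#' times onto run B's over all shared touched holds.
#'
#' @param contacts_a,contacts_b contact data.frames of the two runs.
#' @param at_hold hold id used as the common origin.
#' @return List: `offset_a`, `offset_b` (the subtracted origins),
#'   `shift_s = offset_b - offset_a`, `shared` (data.frame `hold_id`,
#'   `t_a`, `t_b`, both origin-shifted) and `warp` (function mapping shifted
#'   A-times to shifted B-times; identity extension outside the shared
#'   range).
#' @export
synchronize_runs <- function(contacts_a, contacts_b, at_hold) {
  ft <- function(contacts, h) {
    t <- contacts$t_touch_s[!is.na(contacts$hold_id) & contacts$hold_id == h]
    if (!length(t)) NA_real_ else min(t)
  }
  oa <- ft(contacts_a, at_hold); ob <- ft(contacts_b, at_hold)
  if (is.na(oa) || is.na(ob))
    stop("hold ", at_hold, " was not touched in both runs")
  shared <- intersect(contacts_a$hold_id[!is.na(contacts_a$hold_id)],
                      contacts_b$hold_id[!is.na(contacts_b$hold_id)])
  if (!length(shared)) stop("no shared touched holds")
  ta <- vapply(shared, function(h) ft(contacts_a, h), numeric(1)) - oa
  tb <- vapply(shared, function(h) ft(contacts_b, h), numeric(1)) - ob
  o <- order(ta)
  ta <- ta[o]; tb <- tb[o]
  warp <- if (length(ta) >= 2L) {
    function(t) {
      out <- approx(ta, tb, t)$y
      k <- length(ta)
      out[t < ta[1L]] <- tb[1L] + (t[t < ta[1L]] - ta[1L])
      out[t > ta[k]] <- tb[k] + (t[t > ta[k]] - ta[k])
      out
    }
  } else function(t) t
  list(offset_a = oa, offset_b = ob, shift_s = ob - oa,
       shared = data.frame(hold_id = shared[o], t_a = ta, t_b = tb),
       warp = warp)
}
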