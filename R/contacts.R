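# Contact intervals from limb-speed curve sketching, and hold association.
#
# While a hand or foot rests on a hold its world speed is zero; the filtered
# limb-speed curve therefore dips to (near) zero during contact. Each local
# minimum below a threshold is expanded to the surrounding pair of
# inflection points: the preceding negative-slope inflection marks the
# touch, the following positive-slope inflection the release.

#' Detect contact intervals on a filtered limb-speed curve
#'
#' Each contiguous run of frames with speed `< eps` (a dip holding one or
#' more local minima) seeds a candidate contact. Inflection frames are sign
#' changes of the discrete second difference; the candidate expands outward
#' to `[last negative-slope inflection at or before the dip, first
#' positive-slope inflection at or after it]` -- touching is the knee into
#' the dip, releasing the knee out of it. Candidates that overlap, whose
#' separating gap stays below `eps`, or whose gap is shorter than
#' `min_release_s` (a limb cannot release and re-touch faster; such gaps
#' are filter ripple) are merged. The raw (unfiltered) curve plays no role
#' here -- filtering is what excludes spurious turning points.
#'
#' @param speed filtered limb-speed series (m/s), one value per frame
#'   transition.
#' @param fps frame rate.
#' @param eps speed threshold (m/s).
#' @param min_release_s shortest physically plausible release (s).
#' @return data.frame `start`, `end` (0-based frame indices into the speed
#'   series, inclusive), `t_touch_s`, `t_release_s`, `duration_s`,
#'   `sub_eps_s` (auxiliary: span of the sub-threshold dip).
#' @export
detect_contacts <- function(speed, fps, eps = 0.15, min_release_s = 0.15) {
  n <- length(speed)
  empty <- data.frame(start = integer(0), end = integer(0),
                      t_touch_s = numeric(0), t_release_s = numeric(0),
                      duration_s = numeric(0), sub_eps_s = numeric(0))
  if (n < 3L) return(empty)
  d1 <- diff(speed)
  d2 <- diff(d1)                      # second difference at frames 2..n-1
  curv_sign <- sign(d2)
  # curvature changes sign between frames f and f + 1 (d2[j] lives at frame
  # j + 1); the slope across that boundary is d1[f]. Descending inflections
  # anchor at f (touch side), ascending ones at f + 1 (release side).
  f_chg <- which(curv_sign[-1L] * curv_sign[-length(curv_sign)] < 0) + 1L
  chg_slope <- d1[f_chg]
  neg_infl <- f_chg[chg_slope < 0]
  pos_infl <- f_chg[chg_slope > 0] + 1L
  gap_frames <- max(1L, round(min_release_s * fps))
  below <- speed < eps
  if (!any(below)) return(empty)
  # interior above-eps stretches shorter than the minimum release cannot be
  # real releases: close them before delimiting the dips
  rl0 <- rle(below)
  if (length(rl0$lengths) > 2L) {
    interior <- seq_along(rl0$values)[-c(1L, length(rl0$values))]
    flip <- interior[!rl0$values[interior] & rl0$lengths[interior] < gap_frames]
    rl0$values[flip] <- TRUE
    below <- inverse.rle(rl0)
  }
  rl <- rle(below)
  run_end <- cumsum(rl$lengths)
  run_start <- run_end - rl$lengths + 1L
  cores <- cbind(run_start[rl$values], run_end[rl$values])
  hi <- 2 * eps   # beyond this level the limb is clearly moving again
  iv <- t(apply(cores, 1L, function(core) {
    a <- core[1L]; b <- core[2L]
    lo_bound <- which(speed[seq_len(max(a - 1L, 1L))] >= hi)
    lo_bound <- if (length(lo_bound)) max(lo_bound) else 0L
    hi_bound <- which(speed >= hi)
    hi_bound <- hi_bound[hi_bound > b]
    hi_bound <- if (length(hi_bound)) min(hi_bound) else n + 1L
    cand_a <- neg_infl[neg_infl > lo_bound & neg_infl <= a]
    cand_b <- pos_infl[pos_infl >= b & pos_infl < hi_bound]
    start <- if (length(cand_a)) max(cand_a) else a
    end <- if (length(cand_b)) min(cand_b) else b
    # the first sub-eps sample is already in contact: the touch precedes it
    # (and symmetrically for the release), so never collapse onto the core
    c(max(1L, min(start, a - 1L)), min(n, max(end, b + 1L)))
  }))
  o <- order(iv[, 1L], iv[, 2L])
  iv <- iv[o, , drop = FALSE]
  merged <- list(iv[1L, ])
  for (k in seq_len(nrow(iv))[-1L]) {
    last <- merged[[length(merged)]]
    gap <- iv[k, 1L] - last[2L] - 1L
    mergeable <- gap <= 0L || gap < gap_frames ||
      all(speed[(last[2L] + 1L):(iv[k, 1L] - 1L)] < eps)
    if (mergeable)
      merged[[length(merged)]] <- c(last[1L], max(last[2L], iv[k, 2L]))
    else merged[[length(merged) + 1L]] <- iv[k, ]
  }
  m <- do.call(rbind, merged)
  sub_eps <- vapply(seq_len(nrow(m)), function(r) {
    sum(speed[m[r, 1L]:m[r, 2L]] < eps) / fps
  }, numeric(1))
  # a finite-difference speed sample lives at the frame midpoint; contacts
  # running into the recording edges are censored there
  t_touch <- (m[, 1L] - 0.5) / fps
  t_release <- (m[, 2L] - 0.5) / fps
  t_touch[m[, 1L] == 1L] <- 0
  t_release[m[, 2L] == n] <- n / fps
  data.frame(start = m[, 1L] - 1L, end = m[, 2L] - 1L,
             t_touch_s = t_touch, t_release_s = t_release,
             duration_s = t_release - t_touch,
             sub_eps_s = sub_eps)
}

#' Associate contact intervals with tracked holds
#'
#' The hold is the nearest identified hold-track center (in raw image
#' coordinates at the interval midpoint frame) within `radius_px` of the
#' limb keypoint; farther contacts stay unassigned.
#'
#' @param intervals data.frame from [detect_contacts()].
#' @param limb_x,limb_y per-frame limb keypoint positions (image pixels).
#' @param tracks `hold_tracks` object.
#' @param radius_px assignment radius; `NA` = 1.2 x median detected box
#'   width.
#' @param limb label stored on the result.
#' @param fps frame rate.
#' @return data.frame of contact intervals with `limb` and `hold_id`
#'   columns (`NA` = unassigned).
#' @export
assign_contact_holds <- function(intervals, limb_x, limb_y, tracks,
                                 radius_px = NA, limb = "limb", fps = 24) {
  if (is.na(radius_px))
    radius_px <- 1.2 * median(tracks$detections$w)
  hold_id <- rep(NA_integer_, nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    mid <- floor((intervals$start[r] + intervals$end[r]) / 2) + 1L
    mid <- min(max(mid, 1L), length(limb_x))
    pos <- hold_positions_at(tracks, mid - 1L)
    pos <- pos[!is.na(pos$map_id), , drop = FALSE]
    if (!nrow(pos)) next
    dist <- sqrt((pos$x - limb_x[mid])^2 + (pos$y - limb_y[mid])^2)
    j <- which.min(dist)
    if (dist[j] <= radius_px) hold_id[r] <- pos$map_id[j]
  }
  cbind(data.frame(limb = limb, hold_id = hold_id), intervals)
}

#' Time between the first touches of two holds
#'
#' @param contacts contact data.frame with `hold_id` and `t_touch_s`.
#' @param holdA,holdB hold ids.
#' @return `t_touch(B) - t_touch(A)` in seconds, using the first touch per
#'   hold over all limbs.
#' @export
time_between_holds <- function(contacts, holdA, holdB) {
  first_touch <- function(h) {
    t <- contacts$t_touch_s[!is.na(contacts$hold_id) & contacts$hold_id == h]
    if (!length(t)) stop("hold ", h, " was never touched")
    min(t)
  }
  first_touch(holdB) - first_touch(holdA)
}
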