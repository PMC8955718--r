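# Interpolation, joint angles, center of gravity, camera-compensated
# metric velocity.

#' Fill missing or low-confidence keypoint samples
#'
#' Operates on a stacked track ([pose_series()]): interior gaps are linearly
#' interpolated per keypoint and coordinate, ends take the nearest valid
#' value. "Bad" samples are those with confidence below `min_confidence`.
#' Keypoints with fewer than two valid samples are left missing and logged.
#'
#' @param series list from [pose_series()].
#' @param min_confidence validity threshold.
#' @return The series with `x`, `y` filled and a logical matrix
#'   `interpolated` marking filled samples.
#' @export
interpolate_missing <- function(series, min_confidence = 0.1) {
  n <- nrow(series$x)
  filled <- matrix(FALSE, n, ncol(series$x),
                   dimnames = dimnames(series$x))
  for (k in seq_len(ncol(series$x))) {
    ok <- series$conf[, k] > min_confidence
    if (sum(ok) < 2L) {
      if (!all(ok)) {
        warning("keypoint '", colnames(series$x)[k],
                "' has <2 valid samples; left missing")
        series$x[!ok, k] <- NA_real_
        series$y[!ok, k] <- NA_real_
        filled[, k] <- FALSE
      }
      next
    }
    if (all(ok)) next
    t <- seq_len(n)
    series$x[, k] <- approx(t[ok], series$x[ok, k], t, rule = 2)$y
    series$y[, k] <- approx(t[ok], series$y[ok, k], t, rule = 2)$y
    filled[!ok, k] <- TRUE
  }
  series$interpolated <- filled
  series
}

#' 2D joint angle at vertex `j`
#'
#' Angle between the vectors `a - j` and `b - j`, in degrees within
#' `[0, 180]`. Degenerate configurations (`a == j` or `b == j`) return `NA`
#' so they can be interpolated downstream.
#'
#' @param a,j,b numeric length-2 points (any planar unit).
#' @return Angle in degrees, or `NA` when degenerate.
#' @export
joint_angle <- function(a, j, b) {
  u <- a - j; v <- b - j
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Joint-angle series for a stacked track
#'
#' Computes elbow and knee angles on both sides plus the shoulder--hip
#' ("SH") inclination: the angle of the mid-shoulder to mid-hip axis against
#' the upward wall vertical. The SH definition is an interpretation of the
#' parameter set, not a quantity the pipeline's sources pin down; it is
#' flagged as such in the documentation.
#'
#' @param series interpolated [pose_series()].
#' @param pixel_y_axis `"down"` when the series is in native image pixels.
#' @return data.frame: `frame`, one column per joint angle (degrees).
#' @export
joint_angles <- function(series, pixel_y_axis = "down") {
  n <- nrow(series$x)
  p <- function(kp, i) c(series$x[i, kp], series$y[i, kp])
  defs <- list(
    r_elbow = c("r_shoulder", "r_elbow", "r_wrist"),
    l_elbow = c("l_shoulder", "l_elbow", "l_wrist"),
    r_knee = c("r_hip", "r_knee", "r_ankle"),
    l_knee = c("l_hip", "l_knee", "l_ankle"))
  out <- data.frame(frame = series$frame)
  for (nm in names(defs)) {
    d <- defs[[nm]]
    out[[nm]] <- vapply(seq_len(n), function(i)
      joint_angle(p(d[1], i), p(d[2], i), p(d[3], i)), numeric(1))
  }
  up <- if (pixel_y_axis == "down") c(0, -1) else c(0, 1)
  out$sh <- vapply(seq_len(n), function(i) {
    ms <- (p("r_shoulder", i) + p("l_shoulder", i)) / 2
    mh <- (p("r_hip", i) + p("l_hip", i)) / 2
    joint_angle(ms, mh, mh + up)
  }, numeric(1))
  out
}

#' Center of gravity of one skeleton (segment-mass summation)
#'
#' `C = sum_b m_b (j_pb + r_b x_b)` over the 12 body segments, where `j_pb`
#' is the proximal joint, `x_b = distal - proximal` the segment vector,
#' `m_b` the mass fraction and `r_b` the center-of-mass ratio. Because the
#' fractions sum to 1, C is a convex combination of segment centers of mass.
#'
#' @param sf [skeleton_frame()] (all segment endpoints available, i.e.
#'   post-interpolation).
#' @param table anthropometric table.
#' @return Numeric `c(x, y)` in the input units.
#' @export
cog <- function(sf, table = default_anthropometric_table()) {
  px <- sf$x[table$proximal_kp]; py <- sf$y[table$proximal_kp]
  dx <- sf$x[table$distal_kp];   dy <- sf$y[table$distal_kp]
  if (anyNA(c(px, py, dx, dy)))
    stop("missing segment endpoint; interpolate the track first")
  c(x = sum(table$mass_frac * (px + table$com_ratio * (dx - px))),
    y = sum(table$mass_frac * (py + table$com_ratio * (dy - py))))
}

#' Center-of-gravity series for a stacked track
#'
#' @param series interpolated [pose_series()].
#' @param table anthropometric table.
#' @return data.frame `frame`, `x_px`, `y_px` (input pixel convention).
#' @export
cog_series <- function(series, table = default_anthropometric_table()) {
  pxi <- match(table$proximal_kp, colnames(series$x))
  dxi <- match(table$distal_kp, colnames(series$x))
  if (anyNA(series$x[, c(pxi, dxi)]) || anyNA(series$y[, c(pxi, dxi)]))
    stop("missing segment endpoint; interpolate the track first")
  w <- table$mass_frac; r <- table$com_ratio
  xs <- series$x[, pxi, drop = FALSE] +
    sweep(series$x[, dxi, drop = FALSE] - series$x[, pxi, drop = FALSE],
          2, r, `*`)
  ys <- series$y[, pxi, drop = FALSE] +
    sweep(series$y[, dxi, drop = FALSE] - series$y[, pxi, drop = FALSE],
          2, r, `*`)
  data.frame(frame = series$frame,
             x_px = as.numeric(xs %*% w), y_px = as.numeric(ys %*% w))
}

#' Camera-compensated metric velocity of a pixel track
#'
#' `v_y,i = (dy_up,i + gamma_i) * fps / s_i`, `v_x,i = dx_i * fps / s_i`:
#' the camera shift (vertical by construction) is added back to the apparent
#' vertical motion before scaling to meters. Input positions in native image
#' convention (y down) are flipped to the upward convention first, so
#' positive `v_y` is always up the wall.
#'
#' @param x_px,y_px per-frame pixel positions (length n).
#' @param gamma `camera_trajectory` (length n-1 shifts).
#' @param scale `scale_model`, or numeric per-frame scale (px/m, length n or
#'   1).
#' @param fps frame rate.
#' @param pixel_y_axis `"down"` (default) or `"up"`.
#' @return data.frame `frame` (0-based, n-1 rows), `v_x`, `v_y`, `speed`
#'   (m/s).
#' @export
velocity <- function(x_px, y_px, gamma, scale, fps, pixel_y_axis = "down") {
  n <- length(x_px)
  stopifnot(length(y_px) == n, n >= 2L)
  g <- if (inherits(gamma, "camera_trajectory")) gamma$gamma_px else gamma
  stopifnot(length(g) == n - 1L)
  s <- if (inherits(scale, "scale_model")) scale$s_fit else scale
  if (length(s) == 1L) s <- rep(s, n)
  stopifnot(length(s) == n)
  if (any(s <= 0)) stop("non-positive scale factor")
  y_up <- if (pixel_y_axis == "down") -y_px else y_px
  si <- s[-n]
  data.frame(frame = seq_len(n - 1L) - 1L,
             v_x = diff(x_px) * fps / si,
             v_y = (diff(y_up) + g) * fps / si,
             speed = sqrt((diff(x_px) * fps / si)^2 +
                            ((diff(y_up) + g) * fps / si)^2))
}
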