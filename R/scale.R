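# Pixel-to-metric scale calibration.
#
# A hold pair with known map distances gives a direct scale sample
#   s = 1/2 (|dx_px / dx_m| + |dy_px / dy_m|)   [px/m].
# Across the run the scale follows the tripod geometry
#   s_i = A cos(alpha_i),      A = c f / d,
# with the camera angle driven by the measured shift gamma through
#   alpha_{i+1} = gamma_i / B cos(alpha_i) + alpha_i,   B = c f.
# Only the aggregates A (px/m) and B (px) are identifiable; c, f, d are
# never reported individually.

#' Direct scale sample from one hold pair (worked per-axis mean)
#'
#' @param dpx_x,dpx_y pixel distance between the two holds (same frame).
#' @param dm_x,dm_y map distance between the two holds (meters).
#' @return Scale `s` in px/m. If one map axis distance is zero the single
#'   nonzero axis is used (logged via a warning).
#' @export
pairwise_scale <- function(dpx_x, dpx_y, dm_x, dm_y) {
  if (dm_x == 0 && dm_y == 0) stop("zero map distance in both axes")
  if (dm_x == 0 || dm_y == 0) {
    warning("zero map distance in one axis; using the other axis only")
    return(if (dm_x == 0) abs(dpx_y / dm_y) else abs(dpx_x / dm_x))
  }
  (abs(dpx_x / dm_x) + abs(dpx_y / dm_y)) / 2
}

#' Iterate the camera angle from the shift series
#'
#' `alpha[1] = alpha0`; `alpha[i+1] = gamma[i]/B * cos(alpha[i]) + alpha[i]`.
#'
#' @param gamma `camera_trajectory` or numeric vector of per-frame shifts.
#' @param B angle gain (px), nonzero.
#' @param alpha0 start angle (rad).
#' @return Numeric vector of per-frame angles, length `length(gamma) + 1`.
#' @export
iterate_alpha <- function(gamma, B, alpha0) {
  if (inherits(gamma, "camera_trajectory")) gamma <- gamma$gamma_px
  stopifnot(B != 0)
  n <- length(gamma) + 1L
  alpha <- numeric(n)
  alpha[1L] <- alpha0
  for (i in seq_len(n - 1L))
    alpha[i + 1L] <- gamma[i] / B * cos(alpha[i]) + alpha[i]
  alpha
}

#' Fit the cos-alpha scale model to measured scale samples
#'
#' Minimises `sum (A cos(alpha_i(B, alpha0)) - s_meas_i)^2` over
#' `(A, B, alpha0)` by Levenberg--Marquardt least squares with a multi-start
#' over `alpha0` (the loss is non-convex in the start angle). A is seeded at
#' the largest measured sample, B at a gain that keeps the angle sweep
#' moderate.
#'
#' @param s_meas data.frame with columns `frame` (0-based) and `s` (px/m);
#'   at least 3 supporting points.
#' @param gamma `camera_trajectory` (or numeric shift vector).
#' @param alpha0_starts start angles for the multi-start.
#' @return Object of class `scale_model` with elements `A`, `B`, `alpha0`,
#'   `alpha`, `s_fit`, `s_meas`, `rss`, `converged`.
#' @export
fit_scale_model <- function(s_meas, gamma,
                            alpha0_starts = c(-0.4, -0.2, 0, 0.2, 0.4)) {
  if (inherits(gamma, "camera_trajectory")) gamma <- gamma$gamma_px
  stopifnot(is.data.frame(s_meas), all(c("frame", "s") %in% names(s_meas)))
  s_meas <- s_meas[is.finite(s_meas$s), , drop = FALSE]
  if (nrow(s_meas) < 3L)
    stop("at least 3 supporting points are needed to fit the scale model")
  n <- length(gamma) + 1L
  if (any(s_meas$frame < 0L | s_meas$frame >= n))
    stop("supporting point outside the frame range")
  idx <- s_meas$frame + 1L

  resid_fun <- function(p) {
    a <- iterate_alpha(gamma, p[2L], p[3L])
    p[1L] * cos(a[idx]) - s_meas$s
  }
  A0 <- max(s_meas$s)
  B0 <- max(sum(abs(gamma)) / 0.4, 10 * max(abs(gamma)), 1)
  best <- NULL
  for (a0 in alpha0_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(A = A0, B = B0, alpha0 = a0),
                         fn = resid_fun,
                         lower = c(1e-6, 1e-3, -pi / 2 + 1e-3),
                         upper = c(Inf, Inf, pi / 2 - 1e-3),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = coef(fit), rss = rss,
                   converged = fit$info %in% 1:4)
  }
  if (is.null(best))
    stop("scale-model fit did not converge from any start angle")
  p <- best$par
  alpha <- iterate_alpha(gamma, p[["B"]], p[["alpha0"]])
  structure(list(A = p[["A"]], B = p[["B"]], alpha0 = p[["alpha0"]],
                 alpha = alpha, s_fit = p[["A"]] * cos(alpha),
                 s_meas = s_meas, rss = best$rss,
                 converged = best$converged),
            class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  cat("Scale model  s_i = A cos(alpha_i)\n")
  cat(sprintf("  A = %.2f px/m, B = %.1f px, alpha0 = %.4f rad\n",
              x$A, x$B, x$alpha0))
  cat(sprintf("  %d supporting points, RSS %.4g, %sconverged\n",
              nrow(x$s_meas), x$rss, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
coef.scale_model <- function(object, ...)
  c(A = object$A, B = object$B, alpha0 = object$alpha0)

#' Predict the fitted scale at given frames
#'
#' @param object a `scale_model`.
#' @param frame 0-based frame indices (default: all frames).
#' @param ... unused.
#' @export
predict.scale_model <- function(object, frame = NULL, ...) {
  if (is.null(frame)) return(object$s_fit)
  object$s_fit[frame + 1L]
}

#' @export
plot.scale_model <- function(x, ...) {
  f <- seq_along(x$s_fit) - 1L
  plot(f, x$s_fit, type = "l", col = "blue", xlab = "frame",
       ylab = "scale (px/m)", main = "Fitted scale factor", ...)
  if (nrow(x$s_meas)) points(x$s_meas$frame, x$s_meas$s, pch = 16)
  legend("topright", c("fit", "measured"), lty = c(1, NA), pch = c(NA, 16),
         col = c("blue", "black"), bty = "n")
  invisible(x)
}

#' Collect per-frame supporting scale samples from identified holds
#'
#' For every frame in which at least two map-identified hold tracks are
#' visible, the widest vertically separated pair gives one direct sample via
#' [pairwise_scale()] (the widest pair minimises the relative pixel error).
#'
#' @param tracks `hold_tracks` object from [track_and_identify_holds()]
#'   (carries the per-detection track assignment).
#' @param route_map route map data.frame.
#' @return data.frame with columns `frame`, `s`.
#' @export
measure_scale <- function(tracks, route_map) {
  tr <- tracks$tracks
  if (sum(!is.na(tr$map_id)) < 2L) stop("insufficient holds for calibration")
  det <- tracks$detections
  det$map_id <- tr$map_id[match(det$track, tr$track)]
  det <- det[!is.na(det$map_id), , drop = FALSE]
  out_frame <- numeric(0); out_s <- numeric(0)
  for (f in sort(unique(det$frame))) {
    d <- det[det$frame == f, ]
    if (nrow(d) < 2L) next
    i <- which.min(d$y); j <- which.max(d$y)   # widest vertical separation
    if (i == j) next
    mi <- route_map[match(d$map_id[i], route_map$id), ]
    mj <- route_map[match(d$map_id[j], route_map$id), ]
    s <- tryCatch(suppressWarnings(
      pairwise_scale(d$x[i] - d$x[j], d$y[i] - d$y[j],
                     mi$x_m - mj$x_m, mi$y_m - mj$y_m)),
      error = function(e) NA_real_)
    if (is.finite(s)) { out_frame <- c(out_frame, f); out_s <- c(out_s, s) }
  }
  if (!length(out_s)) stop("insufficient holds for calibration")
  data.frame(frame = as.integer(out_frame), s = out_s)
}
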