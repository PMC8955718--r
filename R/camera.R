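# Per-frame vertical camera motion from feature-match pairs.
#
# The camera sits on a tripod and only rotates vertically, so between two
# consecutive frames every static wall feature shares (to first order) one
# vertical image displacement. gamma_i > 0 means the camera panned up, in
# which case static features move *down* in the image.

#' Filter match pairs down to static-wall inliers
#'
#' Two-stage filter: first keep pairs with essentially vertical displacement
#' (`|dx| <= tol_px`), then keep pairs whose vertical displacement lies in a
#' robust band `median +/- k * MAD` per frame, so pairs with almost the same
#' distance remain. The MAD gets a 0.5 px floor so an exactly-rigid
#' displacement field does not degenerate the band to a point.
#'
#' @param pairs data.frame as from [read_matches()].
#' @param tol_px horizontal tolerance (pixels).
#' @param k MAD multiplier.
#' @return The inlier subset (possibly empty).
#' @export
filter_matches <- function(pairs, tol_px = 3, k = 3) {
  stopifnot(tol_px >= 0, k >= 0)
  if (!nrow(pairs)) return(pairs)
  dx <- pairs$x_curr - pairs$x_prev
  pairs <- pairs[abs(dx) <= tol_px, , drop = FALSE]
  if (!nrow(pairs)) return(pairs)
  dy <- pairs$y_curr - pairs$y_prev
  keep <- logical(nrow(pairs))
  for (f in unique(pairs$frame)) {
    i <- pairs$frame == f
    med <- median(dy[i])
    band <- max(k * mad(dy[i]), 0.5)
    keep[i] <- abs(dy[i] - med) <= band
  }
  pairs[keep, , drop = FALSE]
}

#' Estimate the per-frame camera shift
#'
#' For each frame transition the shift is the mean vertical displacement of
#' the inlier pairs: `gamma_i = mean(y_curr - y_prev)` in image-down
#' coordinates, i.e. `-mean(dy)` in the upward convention. Transitions with
#' no inliers carry the previous value forward and are flagged.
#'
#' @param inliers data.frame of filtered match pairs ([filter_matches()]).
#' @param n_frames number of frames in the run; the trajectory has
#'   `n_frames - 1` shifts. Defaults to `max(frame) + 1`.
#' @return Object of class `camera_trajectory`: `gamma_px` (length
#'   `n_frames - 1`), `cumulative_px` (length `n_frames`, starts at 0),
#'   `n_inliers`, `imputed`.
#' @export
estimate_shift <- function(inliers, n_frames = NULL) {
  if (!nrow(inliers)) stop("no static features: cannot estimate camera motion")
  if (is.null(n_frames)) n_frames <- max(inliers$frame) + 1L
  stopifnot(n_frames >= 2L)
  gamma <- rep(NA_real_, n_frames - 1L)
  n_in <- integer(n_frames - 1L)
  dy <- inliers$y_curr - inliers$y_prev
  agg <- tapply(dy, inliers$frame, mean)
  cnt <- tapply(dy, inliers$frame, length)
  idx <- as.integer(names(agg))          # 0-based index of the later frame
  gamma[idx] <- as.numeric(agg)
  n_in[idx] <- as.integer(cnt)
  imputed <- is.na(gamma)
  if (all(imputed)) stop("no static features: cannot estimate camera motion")
  # causal carry-forward; leading gaps take the first observed value
  first <- which(!imputed)[1L]
  if (first > 1L) gamma[seq_len(first - 1L)] <- gamma[first]
  for (i in seq_along(gamma))
    if (is.na(gamma[i])) gamma[i] <- gamma[i - 1L]
  structure(list(gamma_px = gamma,
                 cumulative_px = c(0, cumsum(gamma)),
                 n_inliers = n_in, imputed = imputed),
            class = "camera_trajectory")
}

#' @export
print.camera_trajectory <- function(x, ...) {
  cat("Camera trajectory:", length(x$gamma_px), "frame transitions\n")
  cat(sprintf("  total pan %.1f px, mean |gamma| %.2f px, %d imputed\n",
              x$cumulative_px[length(x$cumulative_px)],
              mean(abs(x$gamma_px)), sum(x$imputed)))
  invisible(x)
}

# gamma aligned to frames: shift between frame i and i+1 (1-based index i)
gamma_at <- function(gamma, i) gamma$gamma_px[i]
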