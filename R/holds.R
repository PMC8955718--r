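# Hold tracking across frames and identification against the route map.

#' Track detected holds across frames and assign route-map ids
#'
#' Detection boxes are linked frame-to-frame by camera-compensated nearest
#' neighbour (the predicted position of a track in the next frame is its
#' last position shifted by the camera displacement). Completed tracks are
#' ordered bottom-to-top and matched against every contiguous window of the
#' route map (holds sorted by height): for each window the single scale
#' minimising the squared gap-vector residuals is fitted, and the window with
#' the smallest residual assigns the map ids. This exploits that inter-hold
#' distance *ratios* are scale-free signatures of the standardized route.
#'
#' @param detections data.frame from [read_detections()].
#' @param gamma `camera_trajectory` covering the detection frames.
#' @param route_map route map data.frame ([default_route_map()]).
#' @param gate_px linking gate; `NA` = 0.75 x median box size (safely below
#'   the closest inter-hold distance at any plausible scale).
#' @return Object of class `hold_tracks`: `tracks` (one row per physical
#'   hold: `track`, `map_id`, `x_px`, `y_comp_px`, `first_seen`,
#'   `last_seen`, `n_det`), `detections` (input plus `track` column) and
#'   `cumulative_px`.
#' @export
track_and_identify_holds <- function(detections, gamma, route_map,
                                     gate_px = NA) {
  if (!nrow(detections)) stop("insufficient holds for calibration")
  cum <- gamma$cumulative_px
  d <- detections[order(detections$frame, detections$y), ]
  if (any(d$frame + 1L > length(cum)))
    stop("detections extend past the camera trajectory")
  if (is.na(gate_px)) gate_px <- 0.75 * median(c(d$w, d$h))
  # compensated coordinates: static holds collapse to one point (up to the
  # residual of the pure-translation camera model)
  d$y_comp <- d$y - cum[d$frame + 1L]
  track_of <- integer(nrow(d))
  last_pos <- matrix(numeric(0), ncol = 2)   # per-track last compensated pos
  for (i in seq_len(nrow(d))) {
    if (nrow(last_pos)) {
      dist <- sqrt((last_pos[, 1] - d$x[i])^2 + (last_pos[, 2] - d$y_comp[i])^2)
      j <- which.min(dist)
    } else dist <- Inf
    if (length(dist) && min(dist) <= gate_px) {
      track_of[i] <- j
      last_pos[j, ] <- c(d$x[i], d$y_comp[i])
    } else {
      last_pos <- rbind(last_pos, c(d$x[i], d$y_comp[i]))
      track_of[i] <- nrow(last_pos)
    }
  }
  d$track <- track_of
  tr <- do.call(rbind, lapply(split(d, d$track), function(g)
    data.frame(track = g$track[1L], x_px = mean(g$x),
               y_comp_px = mean(g$y_comp),
               first_seen = min(g$frame), last_seen = max(g$frame),
               n_det = nrow(g))))
  # bottom-to-top in world coordinates = decreasing compensated image y
  tr <- tr[order(-tr$y_comp_px), ]
  tr$map_id <- assign_map_ids(tr, route_map)
  rownames(tr) <- NULL
  structure(list(tracks = tr, detections = d, cumulative_px = cum),
            class = "hold_tracks")
}

# Align the ordered track sequence with a contiguous window of the map by
# least-squares over gap vectors (one free scale per window).
assign_map_ids <- function(tr, route_map) {
  n <- nrow(tr)
  if (n < 2L) return(rep(NA_integer_, n))
  map <- route_map[order(route_map$y_m), ]
  if (nrow(map) < n) stop("route map has fewer holds than tracked")
  # track gap vectors in world orientation (y up)
  gx <- diff(tr$x_px)
  gy <- diff(-tr$y_comp_px)
  best <- NULL
  for (start in seq_len(nrow(map) - n + 1L)) {
    w <- map[start:(start + n - 1L), ]
    mx <- diff(w$x_m); my <- diff(w$y_m)
    s_hat <- sum(gx * mx + gy * my) / sum(mx^2 + my^2)
    if (!is.finite(s_hat) || s_hat <= 0) next
    rss <- sum((gx - s_hat * mx)^2 + (gy - s_hat * my)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, ids = w$id)
  }
  if (is.null(best)) rep(NA_integer_, n) else as.integer(best$ids)
}

#' @export
print.hold_tracks <- function(x, ...) {
  cat("Hold tracks:", nrow(x$tracks), "tracks,",
      sum(!is.na(x$tracks$map_id)), "identified\n")
  invisible(x)
}

#' Hold-track center at a given frame, in raw image coordinates
#'
#' @param tracks `hold_tracks` object.
#' @param frame 0-based frame index.
#' @return data.frame `track`, `map_id`, `x`, `y` (image pixels at `frame`).
#' @export
hold_positions_at <- function(tracks, frame) {
  tr <- tracks$tracks
  data.frame(track = tr$track, map_id = tr$map_id, x = tr$x_px,
             y = tr$y_comp_px + tracks$cumulative_px[frame + 1L])
}
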