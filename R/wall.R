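# Wall geometry, route map, wall sections.

#' Speed-wall geometry constants
#'
#' The competition wall is 15 m high per lane of 3 m width with a 5 degree
#' overhang, built from 30 panels. The panel count is stored for reference
#' only; no geometry is derived from it.
#'
#' @param height_m,lane_width_m,overhang_deg,panel_count overrides for
#'   non-standard walls.
#' @return List of class `wall_geometry`.
#' @export
wall_geometry <- function(height_m = 15, lane_width_m = 3,
                          overhang_deg = 5, panel_count = 30L) {
  stopifnot(height_m > 0, lane_width_m > 0,
            overhang_deg >= 0, overhang_deg < 90)
  structure(list(height_m = height_m, lane_width_m = lane_width_m,
                 overhang_deg = overhang_deg,
                 panel_count = as.integer(panel_count)),
            class = "wall_geometry")
}

#' Bundled route map (synthetic, IFSC-style)
#'
#' An approximate layout of the standardized speed route: 20 hand holds
#' (ids 1--20, y strictly increasing) and 11 foot holds (ids 21--31) over a
#' 15 m x 3 m lane. The coordinates are a synthetic stand-in constructed for
#' this package -- the downstream calibration only consumes inter-hold
#' distances, which a user-supplied map file overrides exactly.
#'
#' @param lane `"left"` or `"right"` (label only; coordinates are per-lane).
#' @return data.frame of class `route_map` with columns `id`, `kind`,
#'   `x_m`, `y_m`.
#' @export
default_route_map <- function(lane = "left") {
  read_route_map(system.file("extdata", "route_map_synthetic.csv",
                             package = "speedkin", mustWork = TRUE),
                 lane = lane)
}

#' Read a route map CSV (`id,kind,x_m,y_m`)
#'
#' @param path CSV file.
#' @param lane lane label attached as attribute.
#' @param wall [wall_geometry()] used for coordinate bounds.
#' @return data.frame of class `route_map`.
#' @export
read_route_map <- function(path, lane = "left", wall = wall_geometry()) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "kind", "x_m", "y_m")
  if (!all(need %in% names(m)))
    stop("route map needs columns: ", paste(need, collapse = ", "))
  m <- m[, need]
  m$id <- as.integer(m$id)
  if (anyDuplicated(m$id)) stop("route map hold ids must be unique")
  if (!all(m$kind %in% c("hand", "foot")))
    stop("hold kind must be 'hand' or 'foot'")
  if (any(m$x_m < 0 | m$x_m > wall$lane_width_m) ||
      any(m$y_m < 0 | m$y_m > wall$height_m))
    stop("hold coordinates outside the wall")
  hand <- m[m$kind == "hand", ]
  hand <- hand[order(hand$id), ]
  if (nrow(hand) > 1 && any(diff(hand$y_m) <= 0))
    stop("hand-hold heights must strictly increase with id")
  structure(m, class = c("route_map", "data.frame"), lane = lane)
}

#' Default wall sections
#'
#' Sections are delimited by hold ids: Start (holds 1--5), Middle I (6--8),
#' Middle II (6--12) and End (12--20). Middle II deliberately overlaps
#' Middle I; the End span is an extrapolation of the same scheme and can be
#' overridden.
#'
#' @return data.frame with columns `name`, `start_hold`, `end_hold`.
#' @export
default_sections <- function() {
  s <- data.frame(
    name = c("Start", "MiddleI", "MiddleII", "End"),
    start_hold = c(1L, 6L, 6L, 12L),
    end_hold = c(5L, 8L, 12L, 20L),
    stringsAsFactors = FALSE)
  stopifnot(all(s$start_hold < s$end_hold))
  s
}

#' Analysis configuration
#'
#' @param fps frame rate (1/s).
#' @param pixel_y_axis `"down"` (native image convention) or `"up"`.
#' @param vertical_match_tol_px horizontal tolerance when filtering match
#'   pairs for pure vertical motion.
#' @param mad_k MAD multiplier of the robust vertical-displacement band.
#' @param lowpass_cutoff_hz cutoff of the zero-phase filter, or `"auto"` for
#'   the spectral-energy rule.
#' @param lowpass_order effective order of the zero-phase filter.
#' @param contact_speed_eps limb-speed threshold (m/s) seeding contact
#'   minima.
#' @param contact_radius_px hold-assignment radius; `NA` = 1.2 x median
#'   detected hold width.
#' @param min_confidence keypoints below this confidence count as missing.
#' @param seed integer seed for any stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(fps = 24, pixel_y_axis = c("down", "up"),
                       vertical_match_tol_px = 3, mad_k = 3,
                       lowpass_cutoff_hz = 5, lowpass_order = 2,
                       contact_speed_eps = 0.15,
                       contact_radius_px = NA, min_confidence = 0.1,
                       seed = 1L) {
  stopifnot(fps > 0, vertical_match_tol_px >= 0, mad_k >= 0,
            contact_speed_eps >= 0)
  structure(list(fps = fps, pixel_y_axis = match.arg(pixel_y_axis),
                 vertical_match_tol_px = vertical_match_tol_px,
                 mad_k = mad_k, lowpass_cutoff_hz = lowpass_cutoff_hz,
                 lowpass_order = lowpass_order,
                 contact_speed_eps = contact_speed_eps,
                 contact_radius_px = contact_radius_px,
                 min_confidence = min_confidence, seed = as.integer(seed)),
            class = "run_config")
}
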