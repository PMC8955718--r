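# Segment-mass model: 12 body segments with mass fractions and center-of-mass
# ratios (male reference values), bounded by pose keypoints.

#' Bundled anthropometric table
#'
#' Twelve segments (head, trunk and bilateral upper arm, forearm, upper leg,
#' lower leg, foot). Each row carries the segment's mass fraction `mass_frac`
#' of total body mass and the ratio `com_ratio` of the distance from the
#' proximal joint to the segment's center of mass over the segment length.
#' Bilateral segments each carry the per-side fraction, so the twelve
#' fractions sum to exactly 1. The keypoint mapping is the standard 2D
#' convention: head nose-neck, trunk neck-midhip, arm segments
#' shoulder-elbow-wrist, leg segments hip-knee-ankle, foot ankle-big toe; the
#' proximal joint of a segment is the first keypoint of its pair.
#'
#' @return data.frame with columns `segment`, `proximal_kp`, `distal_kp`,
#'   `mass_frac`, `com_ratio`.
#' @export
default_anthropometric_table <- function() {
  read_anthropometric_table(
    system.file("extdata", "anthropometric_male.csv", package = "speedkin",
                mustWork = TRUE))
}

#' Read an anthropometric table from CSV
#'
#' Accepts either the full five-column layout of the bundled table or the
#' three-column exchange layout `segment,mass_frac,com_ratio`, in which case
#' keypoint bounds are filled in from the segment name.
#'
#' @param path CSV file path.
#' @return data.frame as in [default_anthropometric_table()].
#' @export
read_anthropometric_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "mass_frac", "com_ratio")
  if (!all(need %in% names(tab)))
    stop("anthropometric table needs columns: ", paste(need, collapse = ", "))
  if (!all(c("proximal_kp", "distal_kp") %in% names(tab))) {
    ref <- read.csv(system.file("extdata", "anthropometric_male.csv",
                                package = "speedkin", mustWork = TRUE),
                    stringsAsFactors = FALSE)
    idx <- match(tab$segment, ref$segment)
    if (anyNA(idx))
      stop("unknown segment name(s): ",
           paste(tab$segment[is.na(idx)], collapse = ", "))
    tab$proximal_kp <- ref$proximal_kp[idx]
    tab$distal_kp <- ref$distal_kp[idx]
  }
  tab[, c("segment", "proximal_kp", "distal_kp", "mass_frac", "com_ratio")]
}

#' Validate an anthropometric table
#'
#' Checks the structural invariants the center-of-gravity summation relies
#' on: exactly 12 segments, every expected segment present, mass fractions
#' summing to 1 within `1e-6`, every fraction and ratio strictly inside
#' (0, 1), and keypoint bounds drawn from the retained keypoint set.
#'
#' @param table data.frame as returned by [default_anthropometric_table()].
#' @return List with logical `ok` and character vector `violations`
#'   (empty when valid).
#' @export
validate_table <- function(table) {
  v <- character(0)
  expected <- default_segment_names()
  if (nrow(table) != 12L)
    v <- c(v, "12 segments required")
  missing <- setdiff(expected, table$segment)
  if (length(missing))
    v <- c(v, paste0("missing segment: ", paste(missing, collapse = ", ")))
  s <- sum(table$mass_frac)
  if (abs(s - 1) > 1e-6)
    v <- c(v, sprintf("mass sum != 1 (got %.6f)", s))
  bad_m <- table$mass_frac <= 0 | table$mass_frac >= 1
  if (any(bad_m))
    v <- c(v, paste0("mass_frac outside (0,1): ",
                     paste(table$segment[bad_m], collapse = ", ")))
  bad_r <- table$com_ratio <= 0 | table$com_ratio >= 1
  if (any(bad_r))
    v <- c(v, paste0("com_ratio outside (0,1): ",
                     paste(table$segment[bad_r], collapse = ", ")))
  kp <- retained_keypoints()
  bad_kp <- !(table$proximal_kp %in% kp) | !(table$distal_kp %in% kp)
  if (any(bad_kp))
    v <- c(v, paste0("unknown keypoint bound in: ",
                     paste(table$segment[bad_kp], collapse = ", ")))
  list(ok = length(v) == 0L, violations = v)
}

default_segment_names <- function() {
  c("head", "trunk",
    "upper_arm_r", "upper_arm_l", "forearm_r", "forearm_l",
    "upper_leg_r", "upper_leg_l", "lower_leg_r", "lower_leg_l",
    "foot_r", "foot_l")
}
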