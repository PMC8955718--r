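# BODY_25 keypoint layout and the 19-keypoint reduction.

#' BODY_25 keypoint names, in the order the pose JSON stores them
#'
#' @return Character vector of length 25.
#' @export
body25_names <- function() {
  c("nose", "neck",
    "r_shoulder", "r_elbow", "r_wrist",
    "l_shoulder", "l_elbow", "l_wrist",
    "mid_hip",
    "r_hip", "r_knee", "r_ankle",
    "l_hip", "l_knee", "l_ankle",
    "r_eye", "l_eye", "r_ear", "l_ear",
    "l_big_toe", "l_small_toe", "l_heel",
    "r_big_toe", "r_small_toe", "r_heel")
}

#' The 19 keypoints retained for kinematic analysis
#'
#' Ears, eyes and small toes carry no information for climbing kinematics and
#' are dropped; the remaining 19 keypoints keep their BODY_25 names and order.
#'
#' @return Character vector of length 19.
#' @export
retained_keypoints <- function() {
  drop <- c("r_eye", "l_eye", "r_ear", "l_ear", "l_small_toe", "r_small_toe")
  setdiff(body25_names(), drop)
}

#' Construct a skeleton frame
#'
#' One athlete on one frame: 19 named keypoints with pixel coordinates
#' (image convention, y down) and confidences. A missing keypoint is encoded
#' as confidence 0.
#'
#' @param frame 0-based frame index.
#' @param x,y numeric vectors of length 19 (pixels).
#' @param conf confidences in `[0, 1]`, length 19.
#' @param side `"left"`, `"right"` or `"unassigned"`.
#' @return An object of class `skeleton_frame`.
#' @export
skeleton_frame <- function(frame, x, y, conf, side = "unassigned") {
  nm <- retained_keypoints()
  stopifnot(length(x) == 19L, length(y) == 19L, length(conf) == 19L)
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop("keypoint confidences must lie in [0, 1]")
  side <- match.arg(side, c("left", "right", "unassigned"))
  structure(
    list(frame = as.integer(frame), side = side,
         x = setNames(as.numeric(x), nm),
         y = setNames(as.numeric(y), nm),
         conf = setNames(as.numeric(conf), nm)),
    class = "skeleton_frame")
}

#' Reduce a raw 25-keypoint record to the 19-keypoint skeleton
#'
#' @param record matrix-like with 25 rows and columns x, y, confidence, in
#'   BODY_25 order (as returned by [read_pose_sequence()]), or a numeric
#'   vector of 75 values.
#' @param frame 0-based frame index stored on the result.
#' @return A [skeleton_frame()].
#' @export
reduce_keypoints <- function(record, frame = 0L) {
  if (is.numeric(record) && is.null(dim(record))) {
    stopifnot(length(record) == 75L)
    record <- matrix(record, ncol = 3L, byrow = TRUE)
  }
  record <- as.matrix(record)
  if (nrow(record) != 25L || ncol(record) < 3L)
    stop("a BODY_25 record needs 25 rows of (x, y, confidence)")
  keep <- match(retained_keypoints(), body25_names())
  conf <- pmin(pmax(record[keep, 3L], 0), 1)
  skeleton_frame(frame, record[keep, 1L], record[keep, 2L], conf)
}

valid_kp <- function(sf, min_confidence = 0) sf$conf > min_confidence

#' Assign each skeleton to a wall side
#'
#' A skeleton belongs to the left side iff the mean x of its valid keypoints
#' falls in the left image half. With `majority = TRUE` all frames of a track
#' receive the per-track majority side, which stabilises the assignment
#' against frames where the athlete crosses the lane midline.
#'
#' @param frames list of [skeleton_frame()] belonging to one athlete track.
#' @param image_width_px image width in pixels.
#' @param majority apply a per-track majority vote (default `TRUE`).
#' @return The list with `side` set on each frame; frames without any valid
#'   keypoint stay `"unassigned"`.
#' @export
assign_side <- function(frames, image_width_px, majority = TRUE) {
  per <- vapply(frames, function(sf) {
    v <- valid_kp(sf)
    if (!any(v)) return(NA_character_)
    if (mean(sf$x[v]) < image_width_px / 2) "left" else "right"
  }, character(1))
  if (majority && any(!is.na(per))) {
    tab <- table(per)
    win <- names(tab)[which.max(tab)]
    per[!is.na(per)] <- win
  }
  for (i in seq_along(frames))
    frames[[i]]$side <- if (is.na(per[i])) "unassigned" else per[i]
  frames
}

#' Stack a skeleton track into per-keypoint series matrices
#'
#' @param frames list of [skeleton_frame()].
#' @return List with matrices `x`, `y`, `conf` (frames in rows, 19 keypoints
#'   in columns) and the integer `frame` vector.
#' @export
pose_series <- function(frames) {
  nm <- retained_keypoints()
  list(x = do.call(rbind, lapply(frames, `[[`, "x")),
       y = do.call(rbind, lapply(frames, `[[`, "y")),
       conf = do.call(rbind, lapply(frames, `[[`, "conf")),
       frame = vapply(frames, `[[`, integer(1), "frame")) |>
    (\(p) { colnames(p$x) <- colnames(p$y) <- colnames(p$conf) <- nm; p })()
}
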