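# Readers/writers for the per-frame pose JSON dialect
# (people[].pose_keypoints_2d, 75 numbers per person).

#' Read a pose sequence
#'
#' Reads a directory of per-frame JSON files (sorted by file name) or a
#' single JSON file holding a list of frames. Malformed frames are logged
#' via `warning()` and emitted as empty records rather than aborting the
#' read: readers are total.
#'
#' @param path directory of `*.json` files or one JSON file.
#' @return List with one element per frame; each element is a list of
#'   person records, a 25 x 3 matrix (x, y, confidence) each. Frames with no
#'   detected people are empty lists.
#' @export
read_pose_sequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (!length(files)) stop("no pose JSON files in ", path)
    lapply(files, read_pose_file)
  } else if (file.exists(path)) {
    doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("unreadable pose JSON: ", path, " (",
                           conditionMessage(e), ")"))
    lapply(doc, parse_pose_frame, src = path)
  } else stop("no such pose input: ", path)
}

read_pose_file <- function(file) {
  doc <- tryCatch(jsonlite::fromJSON(file, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(doc)) {
    warning("malformed pose JSON skipped: ", file)
    return(list())
  }
  parse_pose_frame(doc, src = file)
}

parse_pose_frame <- function(doc, src = "<frame>") {
  people <- doc$people
  if (is.null(people)) return(list())
  out <- list()
  for (p in people) {
    kp <- unlist(p$pose_keypoints_2d)
    if (length(kp) != 75L || !is.numeric(kp)) {
      warning("person record without 75 keypoint numbers skipped in ", src)
      next
    }
    out[[length(out) + 1L]] <- matrix(kp, ncol = 3L, byrow = TRUE,
                                      dimnames = list(body25_names(),
                                                      c("x", "y", "conf")))
  }
  out
}

#' Write a pose sequence as per-frame JSON files
#'
#' Inverse of [read_pose_sequence()]; used by the synthetic generator and by
#' round-trip tests.
#'
#' @param frames list as returned by [read_pose_sequence()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_pose_sequence <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    people <- lapply(frames[[i]], function(m)
      list(person_id = list(-1L),
           pose_keypoints_2d = as.numeric(t(m))))
    doc <- list(version = 1.3, people = people)
    paths[i] <- file.path(dir, sprintf("frame_%06d_keypoints.json", i - 1L))
    jsonlite::write_json(doc, paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Split multi-person frames into one track per wall side
#'
#' For every frame, skeletons are grouped by image half (mean x of valid
#' keypoints) and only the highest-confidence skeleton per half is kept, so
#' at most one athlete per side survives. Frames where a side has no
#' skeleton get an all-missing placeholder so each track spans all frames.
#'
#' @param records output of [read_pose_sequence()].
#' @param image_width_px image width (pixels).
#' @param min_confidence threshold below which keypoints count as missing.
#' @return List with skeleton-frame lists `left` and `right`.
#' @export
split_people <- function(records, image_width_px, min_confidence = 0.1) {
  empty <- function(i) skeleton_frame(i - 1L, rep(0, 19), rep(0, 19), rep(0, 19))
  left <- right <- vector("list", length(records))
  for (i in seq_along(records)) {
    sfs <- lapply(records[[i]], reduce_keypoints, frame = i - 1L)
    best <- list(left = NULL, right = NULL)
    score <- c(left = -Inf, right = -Inf)
    for (sf in sfs) {
      v <- valid_kp(sf, min_confidence)
      if (!any(v)) next
      half <- if (mean(sf$x[v]) < image_width_px / 2) "left" else "right"
      s <- mean(sf$conf[v])
      if (s > score[[half]]) { score[[half]] <- s; best[[half]] <- sf }
    }
    left[[i]] <- if (is.null(best$left)) empty(i) else best$left
    right[[i]] <- if (is.null(best$right)) empty(i) else best$right
  }
  list(left = left, right = right)
}

#' Select one athlete track from raw pose records
#'
#' Frames holding two or more skeletons are split by image half and the
#' requested lane's best skeleton is kept; frames with a single skeleton
#' keep it unconditionally (a tracking camera often centers the lone
#' athlete on the midline). With `lane = NULL` the side holding the most
#' valid frames wins.
#'
#' @inheritParams split_people
#' @param lane `"left"`, `"right"` or `NULL`.
#' @return List: `frames` (skeleton-frame list) and the resolved `lane`.
#' @export
select_athlete <- function(records, image_width_px, lane = NULL,
                           min_confidence = 0.1) {
  halves <- split_people(records, image_width_px, min_confidence)
  has <- function(sf) any(valid_kp(sf, min_confidence))
  if (is.null(lane)) {
    n_valid <- vapply(halves, function(fr)
      sum(vapply(fr, has, logical(1))), numeric(1))
    lane <- names(which.max(n_valid))
  }
  other <- setdiff(c("left", "right"), lane)
  frames <- halves[[lane]]
  for (i in seq_along(frames)) {
    n_people <- length(records[[i]])
    if (!has(frames[[i]]) && n_people == 1L && has(halves[[other]][[i]]))
      frames[[i]] <- halves[[other]][[i]]
  }
  list(frames = frames, lane = lane)
}
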