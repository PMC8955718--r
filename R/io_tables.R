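# CSV dialects for detections, match pairs, and result exports.
# All readers degrade malformed rows to logged skips.

#' Read hold detections (`frame,class,x,y,w,h,confidence`)
#'
#' `x`, `y` are box centers in pixels (image convention), `w`, `h` box sizes.
#'
#' @param path CSV file.
#' @return data.frame of detection boxes, frame 0-indexed.
#' @export
read_detections <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "class", "x", "y", "w", "h", "confidence")
  if (!all(need %in% names(d)))
    stop("detections CSV needs columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  bad <- !is.finite(d$x) | !is.finite(d$y) | d$w <= 0 | d$h <= 0 |
    d$confidence < 0 | d$confidence > 1 | d$frame < 0
  if (any(bad)) {
    warning(sum(bad), " malformed detection row(s) skipped")
    d <- d[!bad, ]
  }
  d$frame <- as.integer(d$frame)
  d
}

#' @rdname read_detections
#' @param detections data.frame in the same layout.
#' @export
write_detections <- function(detections, path) {
  write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read feature-match pairs (`frame,x_prev,y_prev,x_curr,y_curr`)
#'
#' `frame` is the 0-based index of the *later* frame of the pair, so it is
#' at least 1.
#'
#' @param path CSV file.
#' @return data.frame of match pairs.
#' @export
read_matches <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_prev", "y_prev", "x_curr", "y_curr")
  if (!all(need %in% names(m)))
    stop("matches CSV needs columns: ", paste(need, collapse = ", "))
  m <- m[, need]
  bad <- m$frame < 1 | !stats::complete.cases(m)
  if (any(bad)) {
    warning(sum(bad), " malformed match row(s) skipped")
    m <- m[!bad, ]
  }
  m$frame <- as.integer(m$frame)
  m
}

#' @rdname read_matches
#' @param matches data.frame in the same layout.
#' @export
write_matches <- function(matches, path) {
  write.csv(matches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the full result set of an analysed run
#'
#' Writes deterministic CSV files: `cog.csv` (per-frame center of gravity and
#' velocity), `angles.csv` (per-frame joint angles), `contacts.csv` (one row
#' per contact interval), `scale.csv` (per-frame camera angle and scale),
#' `gamma.csv` (per-frame camera shift) and `parameters.csv` (one row per
#' run-level parameter). Re-reading reproduces the numbers to full double
#' precision (15 significant digits are written).
#'
#' @param run a `speed_run` object from [analyze_run()], or a list holding
#'   any subset of the fields `cog`, `angles`, `contacts`, `scale`, `gamma`,
#'   `parameters`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.access(out_dir, 2) == 0
  if (!ok) stop("unwritable output path: ", out_dir)
  wr <- function(df, file) {
    p <- file.path(out_dir, file)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 15))
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }
  paths <- character(0)
  if (!is.null(run$cog)) paths <- c(paths, wr(run$cog, "cog.csv"))
  if (!is.null(run$angles)) paths <- c(paths, wr(run$angles, "angles.csv"))
  if (!is.null(run$contacts))
    paths <- c(paths, wr(run$contacts, "contacts.csv"))
  if (!is.null(run$scale_table))
    paths <- c(paths, wr(run$scale_table, "scale.csv"))
  else if (!is.null(run$scale))
    paths <- c(paths, wr(scale_table(run$scale), "scale.csv"))
  if (!is.null(run$gamma)) {
    g <- run$gamma
    gdf <- data.frame(frame = seq_along(g$gamma_px),
                      gamma_px = g$gamma_px,
                      cumulative_px = g$cumulative_px[-1L],
                      n_inliers = g$n_inliers, imputed = g$imputed)
    paths <- c(paths, wr(gdf, "gamma.csv"))
  }
  if (!is.null(run$parameters)) {
    p <- run$parameters
    pdf <- data.frame(parameter = names(p), value = unlist(p, use.names = FALSE))
    paths <- c(paths, wr(pdf, "parameters.csv"))
  }
  invisible(paths)
}

scale_table <- function(model) {
  data.frame(frame = seq_along(model$alpha) - 1L,
             alpha_rad = model$alpha, s_fit = model$s_fit,
             s_meas = {
               s <- rep(NA_real_, length(model$alpha))
               if (!is.null(model$s_meas) && nrow(model$s_meas))
                 s[model$s_meas$frame + 1L] <- model$s_meas$s
               s
             })
}
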