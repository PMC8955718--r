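# Classical hold segmentation: HSV thresholding + morphology + region
# labelling. The holds are uniformly coloured (red on most walls), but the
# spotlight and chalk vary brightness across the frame, so the
# saturation/value thresholds are taken from image quantiles rather than
# fixed (a "dynamic range").

#' Segment climbing holds in an RGB frame by HSV thresholding
#'
#' The RGB image is converted to HSV; a hue-wraparound-safe band combined
#' with quantile-derived saturation/value minima yields a binary mask, which
#' is cleaned by a morphological open-then-close with a disc brush and
#' labelled into connected regions.
#'
#' @param img numeric array `h x w x 3`, values in `[0, 1]`.
#' @param hue_range hue band in `[0, 1]`; `lo > hi` wraps around red
#'   (default `c(0.95, 0.08)`).
#' @param sat_quantile,val_quantile quantiles of the within-band saturation
#'   and value used as dynamic minima.
#' @param min_area discard regions smaller than this (px^2).
#' @param morph_radius disc radius (px) of the open/close brush.
#' @return data.frame of hold regions: `label`, `cx`, `cy` (centroid px),
#'   `area`, `mean_value`, and bbox columns `x0`, `y0`, `x1`, `y1`.
#' @export
hsv_segment_holds <- function(img, hue_range = c(0.95, 0.08),
                              sat_quantile = 0.5, val_quantile = 0.25,
                              min_area = 20, morph_radius = 2) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  rgbm <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
                as.vector(img[, , 3L]))
  hsv <- rgb2hsv(rgbm, maxColorValue = 1)
  hue <- hsv[1L, ]; sat <- hsv[2L, ]; val <- hsv[3L, ]
  in_hue <- if (hue_range[1L] <= hue_range[2L])
    hue >= hue_range[1L] & hue <= hue_range[2L]
  else hue >= hue_range[1L] | hue <= hue_range[2L]
  # dynamic minima: anchored on the pixels already matching the hue band,
  # which makes the mask invariant to global/gradient brightness changes
  cand <- in_hue & sat > 0.2
  if (!any(cand)) return(empty_regions())
  smin <- quantile(sat[cand], sat_quantile) * 0.5
  vmin <- quantile(val[cand], val_quantile) * 0.5
  mask <- matrix(in_hue & sat >= smin & val >= vmin, h, w)
  brush <- EBImage::makeBrush(2L * as.integer(morph_radius) + 1L,
                              shape = "disc")
  m <- EBImage::closing(EBImage::opening(EBImage::Image(mask * 1), brush),
                        brush)
  lab <- EBImage::bwlabel(m)
  labv <- as.integer(EBImage::imageData(lab))
  if (!any(labv > 0L)) return(empty_regions())
  # EBImage images are column-major with x as the first dimension after
  # transposition; our mask was h x w already, so row = y, col = x
  idx <- which(labv > 0L)
  row <- (idx - 1L) %% h + 1L
  col <- (idx - 1L) %/% h + 1L
  valm <- matrix(val, h, w)
  regs <- lapply(split(seq_along(idx), labv[idx]), function(i) {
    data.frame(cx = mean(col[i]), cy = mean(row[i]), area = length(i),
               mean_value = mean(valm[cbind(row[i], col[i])]),
               x0 = min(col[i]), y0 = min(row[i]),
               x1 = max(col[i]), y1 = max(row[i]))
  })
  out <- do.call(rbind, regs)
  out <- cbind(label = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out[out$area >= min_area, , drop = FALSE]
}

empty_regions <- function() {
  data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
             area = numeric(0), mean_value = numeric(0),
             x0 = numeric(0), y0 = numeric(0),
             x1 = numeric(0), y1 = numeric(0))
}
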