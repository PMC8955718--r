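# Minimal wall renderer: a fixture for the HSV segmenter, not a
# photorealistic scene. Gray wall, saturated red hold discs, optional white
# chalk speckle and a vertical spotlight gradient (a pure V-channel effect:
# the gradient multiplies RGB, leaving hue and saturation untouched).

#' Render one synthetic frame as an RGB array
#'
#' @param run `synth_run` from [generate_run()] (or its `truth` element plus
#'   config fields -- only camera and map geometry are used).
#' @param frame 0-based frame index.
#' @param route_map route map; defaults to the bundled one.
#' @param spotlight add the vertical brightness gradient.
#' @param chalk number of white speckle dots (0 disables).
#' @param scale_down integer factor shrinking the rendered image (the
#'   default 4 keeps fixtures small: 320 x 180).
#' @return Numeric array `h x w x 3` in `[0, 1]`.
#' @export
render_frame <- function(run, frame, route_map = default_route_map(),
                         spotlight = FALSE, chalk = 0, scale_down = 4L) {
  cfg <- run$config
  cam <- run$truth$camera
  i <- frame + 1L
  stopifnot(i >= 1L, i <= nrow(cam))
  f <- as.integer(scale_down)
  w <- cfg$image_w %/% f; h <- cfg$image_h %/% f
  s <- cam$s[i] / f
  x0 <- w / 2; y0 <- h / 2
  c_x <- lane_offset(if (cfg$lane == "both") "left" else cfg$lane) + 1.5
  img <- array(0.55, dim = c(h, w, 3L))          # gray wall

  hx <- x0 + s * (route_map$x_m - c_x)
  hy <- y0 - s * (route_map$y_m - cam$c_y[i])
  r <- s * cfg$hold_size_m / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_along(hx)) {
    # visibility rule matches the detection generator: center in frame
    if (hx[k] < 0 || hx[k] > w || hy[k] < 0 || hy[k] > h) next
    disc <- (xx - hx[k])^2 + (yy - hy[k])^2 <= r^2
    img[, , 1L][disc] <- 0.85
    img[, , 2L][disc] <- 0.08
    img[, , 3L][disc] <- 0.08
  }
  if (chalk > 0) {
    cx <- sample.int(w, chalk, replace = TRUE)
    cy <- sample.int(h, chalk, replace = TRUE)
    for (ch in 1:3) img[, , ch][cbind(cy, cx)] <- 0.95
  }
  if (spotlight) {
    grad <- matrix(seq(0.7, 1.0, length.out = h), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * grad
  }
  pmin(pmax(img, 0), 1)
}
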