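#' Map the SNPC polar angle to hue
#'
#' hue = ((theta + offset) mod 2pi) / 2pi, a bijection from the circle onto
#' [0, 1). Saturation and value are held constant in the rendered maps
#' (encoding r as saturation/value proved visually confusing and is only
#' available behind a flag in [theta_colours()]).
#'
#' @param theta Angles in radians.
#' @param offset Hue rotation in radians (default 0); see
#'   [auto_hue_offset()].
#' @return Numeric hue vector in `[0, 1)`.
#' @export
theta_to_hue <- function(theta, offset = 0) {
  ((theta + offset) %% (2 * pi)) / (2 * pi)
}

#' Calibrate the hue offset on a reference pattern
#'
#' Chooses the offset so that the circular mode of theta over the densest
#' localisations (the large-cluster signature) maps to blue/violet (hue 0.7),
#' which in turn places the noise angular mode in the yellow/green range,
#' giving the intended visual contrast between aggregation and segregation.
#'
#' @param theta Angles in radians.
#' @param log10Den Matching log-density values used to select the densest
#'   quartile.
#' @return Offset in radians.
#' @export
auto_hue_offset <- function(theta, log10Den) {
  ok <- is.finite(theta) & is.finite(log10Den)
  dense <- ok & log10Den >= quantile(log10Den[ok], 0.75)
  # circular mean of the dense-quartile angles
  mode_theta <- atan2(mean(sin(theta[dense])), mean(cos(theta[dense])))
  (0.7 * 2 * pi - mode_theta) %% (2 * pi)
}

#' Per-localisation colours from theta
#'
#' @param theta Angles in radians.
#' @param offset Hue offset (radians).
#' @param r Optional radial coordinate; if `encode_r = TRUE` it modulates
#'   saturation.
#' @param encode_r Encode r as saturation (off by default).
#' @return Character vector of hex colours.
#' @export
theta_colours <- function(theta, offset = 0, r = NULL, encode_r = FALSE) {
  hue <- theta_to_hue(theta, offset)
  s <- if (encode_r && !is.null(r)) pmin(1, r / quantile(r, 0.95)) else 1
  grDevices::hsv(h = hue, s = s, v = 1)
}

#' Render localisations as a raster image
#'
#' Deterministic scatter rasteriser: coordinates are mapped to pixels with a
#' single affine transform that preserves aspect ratio and orientation (y up),
#' and each point is drawn as a square of `point_size` pixels. Rendering the
#' same inputs twice yields byte-identical files.
#'
#' @param table A `kna_locs` table.
#' @param colours One colour per localisation (any R colour specification).
#' @param path Output PNG path.
#' @param width Output width in pixels (height follows the aspect ratio).
#' @param point_size Point side length in pixels (default 1).
#' @param background Background colour (default black).
#' @return Invisibly, the path; the pixel positions used are attached as
#'   attribute `"pixels"` for testing.
#' @export
render_points <- function(table, colours, path, width = 512, point_size = 1,
                          background = "black") {
  if (length(colours) != nrow(table))
    stop("need one colour per localisation (", nrow(table), " points, ",
         length(colours), " colours)")
  if (any(is.na(colours))) {
    bad <- which(is.na(colours))[1]
    stop("missing colour for localisation ", bad,
         " (empty colour key entry?)")
  }
  xr <- range(table$x); yr <- range(table$y)
  span_x <- max(xr[2] - xr[1], .Machine$double.eps)
  span_y <- max(yr[2] - yr[1], .Machine$double.eps)
  scale <- (width - 1) / span_x
  height <- max(1L, as.integer(ceiling(span_y * scale)) + 1L)
  px <- as.integer(round((table$x - xr[1]) * scale)) + 1L
  py <- height - as.integer(round((table$y - yr[1]) * scale))  # y up
  bg <- grDevices::col2rgb(background) / 255
  img <- array(rep(bg, each = height * width), dim = c(height, width, 3))
  rgb <- grDevices::col2rgb(colours) / 255
  half <- max(0L, as.integer(point_size) %/% 2L)
  for (i in seq_len(nrow(table))) {
    rows <- max(1L, py[i] - half):min(height, py[i] + half)
    cols <- max(1L, px[i] - half):min(width, px[i] + half)
    img[rows, cols, 1] <- rgb[1, i]
    img[rows, cols, 2] <- rgb[2, i]
    img[rows, cols, 3] <- rgb[3, i]
  }
  png::writePNG(img, path)
  attr(path, "pixels") <- data.frame(px = px, py = py)
  invisible(path)
}
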