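#' Rendering configuration
#'
#' @param colormap `"diverging_red_blue"` or `"hsv"`.
#' @param magnitude_for_saturation modulate the diverging tone by flow
#'   magnitude (HSV rendering always encodes magnitude as saturation).
#' @param magnitude_ceiling magnitude (pixels/frame) mapped to full
#'   saturation; larger magnitudes are clipped.
#' @param background_color color for excluded/invalid pixels.
#' @param palette three anchor colors (inward extreme, neutral midpoint,
#'   outward extreme) for the diverging ramp.
#' @return List of class `"render_config"`.
#' @export
render_config <- function(colormap = c("diverging_red_blue", "hsv"),
                          magnitude_for_saturation = FALSE,
                          magnitude_ceiling = 2,
                          background_color = "black",
                          palette = c("#FF0000", "#FFFFFF", "#0000FF")) {
  colormap <- match.arg(colormap)
  if (magnitude_ceiling <= 0)
    stop("magnitude_ceiling must be > 0", call. = FALSE)
  structure(list(colormap = colormap,
                 magnitude_for_saturation = magnitude_for_saturation,
                 magnitude_ceiling = magnitude_ceiling,
                 background_color = background_color,
                 palette = palette),
            class = "render_config")
}

#' Position of a wrapped angle difference on the diverging ramp
#'
#' The diverging encoding is the monotone injective map
#' `position = delta / pi` from `delta` in `[0, pi]` to `[0, 1]`:
#' 0 (aligned with the to-center vector, inward) at the red end, `pi`
#' (anti-aligned, outward) at the blue end, `pi/2` at the neutral
#' midpoint.
#'
#' @param delta wrapped angle difference(s) in `[0, pi]`.
#' @return Position(s) in `[0, 1]`.
#' @export
diverging_position <- function(delta) delta / pi

# linear RGB ramp through the three palette anchors; t in [0,1] -> rgb in [0,1]
diverging_ramp <- function(t, palette) {
  ramp <- grDevices::colorRamp(palette, space = "rgb")
  ramp(t) / 255
}

#' Render a direction map with the diverging colormap
#'
#' Each included pixel is colored by its wrapped angle difference `delta`:
#' full red at `delta = 0` (inward), the neutral midpoint at `pi/2`, full
#' blue at `pi` (outward).  With `magnitude_for_saturation` the color is
#' blended toward the background in proportion to
#' `1 - min(magnitude / magnitude_ceiling, 1)`.  Excluded pixels get the
#' background color.
#'
#' @param map a `"direction_map"`.
#' @param config a [render_config()].
#' @return `m x n x 3` RGB array in `[0, 1]`.
#' @export
render_diverging <- function(map, config = render_config()) {
  stopifnot(inherits(map, "direction_map"))
  m <- nrow(map$label); n <- ncol(map$label)
  inc <- map$label != "Excluded"
  bg <- grDevices::col2rgb(config$background_color)[, 1] / 255
  img <- array(rep(bg, each = m * n), c(m, n, 3))
  if (any(inc)) {
    t <- diverging_position(map$delta[inc])
    rgbv <- diverging_ramp(t, config$palette)
    if (config$magnitude_for_saturation) {
      s <- pmin(map$magnitude[inc] / config$magnitude_ceiling, 1)
      rgbv <- rgbv * s + matrix(bg, nrow(rgbv), 3, byrow = TRUE) * (1 - s)
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inc] <- rgbv[, ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Render a flow field in HSV color space
#'
#' Conventional optical-flow encoding: hue is the flow orientation (the
#' angle `atan2(vy, vx)` mapped linearly onto the hue circle), saturation
#' is `min(magnitude / magnitude_ceiling, 1)`, value is 1 on valid pixels.
#' Invalid pixels get the background color.
#'
#' @param flow a `"flow_field"`.
#' @param config a [render_config()].
#' @return `m x n x 3` RGB array in `[0, 1]`.
#' @export
render_hsv <- function(flow, config = render_config(colormap = "hsv")) {
  stopifnot(inherits(flow, "flow_field"))
  m <- nrow(flow$vx); n <- ncol(flow$vx)
  bg <- grDevices::col2rgb(config$background_color)[, 1] / 255
  img <- array(rep(bg, each = m * n), c(m, n, 3))
  v <- flow$valid
  if (any(v)) {
    ang <- atan2(flow$vy[v], flow$vx[v])          # (-pi, pi]
    hue <- (ang / (2 * pi)) %% 1                  # [0, 1)
    mag <- sqrt(flow$vx[v]^2 + flow$vy[v]^2)
    sat <- pmin(mag / config$magnitude_ceiling, 1)
    cols <- hsv_to_rgb_continuous(hue, sat, 1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[v] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  img
}

# continuous HSV -> RGB (value fixed by caller); double precision so the
# hue/saturation encoding is exactly invertible, unlike 8-bit color strings
hsv_to_rgb_continuous <- function(h, s, v = 1) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0 | i == 5, v, ifelse(i == 1, q, ifelse(i == 4, t, p)))
  g <- ifelse(i == 1 | i == 2, v, ifelse(i == 0, t, ifelse(i == 3, q, p)))
  b <- ifelse(i == 3 | i == 4, v, ifelse(i == 2, t, ifelse(i == 5, q, p)))
  cbind(r, g, b, deparse.level = 0)
}

#' Decode an HSV flow rendering
#'
#' Inverse of [render_hsv()] on valid pixels: recovers the flow
#' orientation angle and the clipped, ceiling-normalized magnitude from an
#' RGB array.  Used for round-trip verification of the encoding.
#'
#' @param img RGB array from [render_hsv()].
#' @param valid logical matrix of pixels to decode.
#' @param config the [render_config()] used to render.
#' @return List with `angle` (radians in `(-pi, pi]`) and `magnitude`
#'   (pixels/frame, clipped at `magnitude_ceiling`), vectors over
#'   `which(valid)`.
#' @export
decode_hsv <- function(img, valid, config = render_config(colormap = "hsv")) {
  r <- img[, , 1][valid]; g <- img[, , 2][valid]; b <- img[, , 3][valid]
  hsvv <- grDevices::rgb2hsv(rbind(r, g, b) * 255, maxColorValue = 255)
  ang <- hsvv[1, ] * 2 * pi
  ang[ang > pi] <- ang[ang > pi] - 2 * pi
  list(angle = ang, magnitude = hsvv[2, ] * config$magnitude_ceiling)
}

#' Write an RGB array as PNG
#'
#' @param img `m x n x 3` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_render <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Time-series summary panels
#'
#' Two stacked panels over frame pairs: detected-vector counts and mean
#' flow magnitude (top), and inward/outward proportions (bottom).  Frames
#' with no included vector appear as gaps, not zeros.
#'
#' @param summaries `data.frame` from [summarize_series()].
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
render_summary_panels <- function(summaries, path, width = 900, height = 700) {
  if (nrow(summaries) == 0) stop("empty summary series", call. = FALSE)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 4))  # dies with the device
  with(summaries, {
    graphics::plot(frame, n_vectors, type = "o", pch = 16, col = "black",
                   xlab = "frame pair", ylab = "detected vectors",
                   main = "Flow vectors detected over time")
    graphics::par(new = TRUE)
    graphics::plot(frame, mean_magnitude, type = "o", pch = 1, col = "gray40",
                   axes = FALSE, xlab = "", ylab = "", lty = 2)
    graphics::axis(4, col.axis = "gray40")
    graphics::mtext("mean |V| (px/frame)", side = 4, line = 2.5,
                    col = "gray40")
    graphics::plot(frame, prop_inward, type = "o", pch = 16, col = "red3",
                   ylim = c(0, 1), xlab = "frame pair", ylab = "proportion",
                   main = "Inward / outward proportion over time")
    graphics::lines(frame, prop_outward, type = "o", pch = 16, col = "blue3")
    graphics::legend("topright", c("inward", "outward"),
                     col = c("red3", "blue3"), pch = 16, lty = 1, bty = "n")
  })
  invisible(path)
}
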