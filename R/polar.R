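#' Polar resampling of an image about the cell center
#'
#' Re-represents an image on an `(R, theta)` grid about a center, so that
#' the distance from the cell center becomes one image axis: the sample at
#' grid point `(R, theta)` is the image interpolated at
#' `(x, y) = (C_col + R cos(theta), C_row + R sin(theta))` in the y-down
#' convention (theta measured from the +x/column axis toward +y/row).
#'
#' The radial axis holds `n_r` sample points spanning `[0, r_max]`
#' (the first row is exactly `R = 0`, i.e. the interpolated center value);
#' the angular axis holds `n_theta` points spanning `[0, 2*pi)`.  Samples
#' falling outside the image are set to `NA` and counted.
#'
#' @param image 2-D numeric matrix.
#' @param center `(row, col)` center, or a `"center_estimate"`.
#' @param n_r,n_theta grid sizes; defaults: `ceiling(r_max) + 1` radii and
#'   360 angles.
#' @param r_max maximum radius in pixels; default: distance from the
#'   center to the nearest image edge.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return An object of class `"polar_image"`: matrix `values`
#'   (`n_r x n_theta`), the grid description (`r`, `theta`, `r_max`,
#'   `n_r`, `n_theta`), `center`, `interpolation` and `n_outside`.
#' @export
to_polar <- function(image, center, n_r = NULL, n_theta = 360L,
                     r_max = NULL,
                     interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(center, "center_estimate")) center <- center$center
  m <- nrow(image); n <- ncol(image)
  if (center[1] < 1 || center[1] > m || center[2] < 1 || center[2] > n)
    stop("center lies outside the image", call. = FALSE)
  if (is.null(r_max))
    r_max <- min(center[1] - 1, m - center[1], center[2] - 1, n - center[2])
  if (r_max <= 0) stop("r_max must be > 0", call. = FALSE)
  if (is.null(n_r)) n_r <- as.integer(ceiling(r_max)) + 1L
  if (n_r < 2L || n_theta < 4L)
    stop("polar grid too small (need n_r >= 2, n_theta >= 4)", call. = FALSE)

  r <- seq(0, r_max, length.out = n_r)
  # theta on [0, 2*pi): sinpi/cospi keep quadrant angles exact
  tfrac <- 2 * (seq_len(n_theta) - 1L) / n_theta
  ct <- cospi(tfrac); st <- sinpi(tfrac)
  rows <- outer(r, st) + center[1]   # y = C_row + R sin(theta)
  cols <- outer(r, ct) + center[2]   # x = C_col + R cos(theta)
  sampler <- if (interpolation == "bilinear") sample_bilinear else sample_nearest
  vals <- matrix(sampler(image, as.vector(rows), as.vector(cols)), n_r, n_theta)
  structure(list(values = vals, r = r, theta = pi * tfrac,
                 r_max = r_max, n_r = n_r, n_theta = as.integer(n_theta),
                 center = center, interpolation = interpolation,
                 n_outside = sum(is.na(vals))),
            class = "polar_image")
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf("<polar_image> %d radii x %d angles, r_max %.2f px, %s interpolation\n",
              x$n_r, x$n_theta, x$r_max, x$interpolation))
  if (x$n_outside > 0)
    cat(sprintf("  %d sample(s) outside the image (NA)\n", x$n_outside))
  invisible(x)
}

#' Polar resampling of a direction map
#'
#' Transforms the categorical label plane with nearest-neighbour sampling
#' (labels are never interpolated) and the `delta` and `magnitude` planes
#' with the requested interpolation.
#'
#' @param map a `"direction_map"`.
#' @param center defaults to the map's own center.
#' @param n_r,n_theta,r_max grid, as in [to_polar()].
#' @param interpolation interpolation for the continuous planes.
#' @return List of class `"polar_direction"` with `"polar_image"` members
#'   `label` (character values), `delta` and `magnitude`.
#' @export
to_polar_labels <- function(map, center = map$center, n_r = NULL,
                            n_theta = 360L, r_max = NULL,
                            interpolation = c("bilinear", "nearest")) {
  stopifnot(inherits(map, "direction_map"))
  interpolation <- match.arg(interpolation)
  codes <- matrix(match(map$label, c("Inward", "Outward", "Excluded")),
                  nrow(map$label), ncol(map$label))
  plab <- to_polar(codes, center, n_r = n_r, n_theta = n_theta,
                   r_max = r_max, interpolation = "nearest")
  plab$values <- matrix(c("Inward", "Outward", "Excluded")[plab$values],
                        plab$n_r, plab$n_theta)
  pdelta <- to_polar(map$delta, center, n_r = plab$n_r,
                     n_theta = plab$n_theta, r_max = plab$r_max,
                     interpolation = interpolation)
  pmag <- to_polar(map$magnitude, center, n_r = plab$n_r,
                   n_theta = plab$n_theta, r_max = plab$r_max,
                   interpolation = interpolation)
  structure(list(label = plab, delta = pdelta, magnitude = pmag),
            class = "polar_direction")
}

#' Write a polar image as TIFF plus a JSON axis sidecar
#'
#' @param pim a `"polar_image"` with numeric values.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param na_fill value substituted for outside-image samples.
#' @return `path`, invisibly.
#' @export
write_polar <- function(pim, path, na_fill = 0) {
  stopifnot(inherits(pim, "polar_image"))
  v <- pim$values
  if (!is.numeric(v)) stop("polar image is not numeric", call. = FALSE)
  v[is.na(v)] <- na_fill
  write_tiff_float32(list(v), path)
  jsonlite::write_json(
    list(r_max = pim$r_max, n_r = pim$n_r, n_theta = pim$n_theta,
         center_row = pim$center[1], center_col = pim$center[2],
         interpolation = pim$interpolation, n_outside = pim$n_outside,
         na_fill = na_fill),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
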