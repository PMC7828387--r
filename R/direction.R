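#' Angle of the pixel-to-center vector
#'
#' Four-quadrant angle `alpha` of the vector pointing from a pixel to the
#' cell center, in the package's `(x, y) = (column, row)` y-down
#' convention: `alpha = atan2(center_row - row, center_col - col)`,
#' in `(-pi, pi]`.
#'
#' @param pixel `(row, col)` position (vectors of rows/cols accepted via
#'   `row`/`col` recycling in matrix callers; this reference form takes a
#'   single pair or two equal-length vectors bound as columns).
#' @param center `(row, col)` of the cell center.
#' @return Angle(s) in radians; `NA` where the pixel coincides with the
#'   center (no direction defined).
#' @export
to_center_angle <- function(pixel, center) {
  pixel <- matrix(pixel, ncol = 2)
  dy <- center[1] - pixel[, 1]   # y is the row axis, increasing downward
  dx <- center[2] - pixel[, 2]
  out <- atan2(dy, dx)
  out[abs(dy) < 1e-9 & abs(dx) < 1e-9] <- NA_real_
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

#' Wrapped absolute angular difference
#'
#' `min(|a - b|, 2*pi - |a - b|)`, the geodesic distance on the circle,
#' always in `[0, pi]`.  Raw four-quadrant differences reach `2*pi`, so
#' the wrap is required before the inward/outward rule is applied.
#'
#' @param alpha,beta angles in radians (any finite values; reduced mod
#'   `2*pi`).
#' @return Wrapped difference(s) in `[0, pi]`.
#' @export
angle_difference <- function(alpha, beta) {
  d <- abs(alpha - beta) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Inward/outward classification of one flow vector
#'
#' The movement at a pixel is `"Inward"` when the wrapped angle between
#' the flow vector and the pixel-to-center vector satisfies
#' `0 <= delta <= pi/2` (closed interval: tangential motion at exactly
#' `pi/2` counts as inward), and `"Outward"` when `pi/2 < delta <= pi`.
#' Values within 1e-9 rad of `pi/2` are treated as on the boundary, so
#' the rule is stable under floating-point rounding of `atan2`.
#' Vectors with magnitude below `magnitude_min` are `"Excluded"`, as is
#' any pixel within `tangential_band` of `pi/2` when that option is used.
#'
#' @param delta wrapped angle difference(s) in `[0, pi]`.
#' @param magnitude flow magnitude(s), pixels/frame.
#' @param magnitude_min inclusion threshold on the magnitude.
#' @param tangential_band half-width of an optional exclusion band around
#'   `pi/2` (default 0: the literal closed-interval rule).
#' @return Character label(s): `"Inward"`, `"Outward"` or `"Excluded"`.
#' @export
classify_direction <- function(delta, magnitude, magnitude_min = 0.1,
                               tangential_band = 0) {
  # snap within 1e-9 rad of the boundary onto it, so exactly tangential
  # fields (delta = pi/2 up to atan2 rounding) take the closed-interval
  # branch deterministically
  out <- ifelse(delta <= pi / 2 + 1e-9, "Inward", "Outward")
  out[magnitude < magnitude_min] <- "Excluded"
  if (tangential_band > 0)
    out[abs(delta - pi / 2) < tangential_band] <- "Excluded"
  out[is.na(delta)] <- "Excluded"
  out
}

#' Per-pixel direction map for one flow field
#'
#' Combines a flow field and a cell center into per-pixel angles
#' (`alpha` toward the center, `beta` of the flow), their wrapped
#' difference `delta`, the flow magnitude, and the inward/outward label.
#' Pixels with invalid flow, magnitude below `magnitude_min`, or lying at
#' the center are `"Excluded"`.
#'
#' @param flow a `"flow_field"` from [compute_flow()].
#' @param center a `"center_estimate"` or a `(row, col)` numeric pair.
#' @param magnitude_min inclusion threshold, pixels/frame.
#' @param tangential_band see [classify_direction()].
#' @param cell_mask optional logical matrix restricting inclusion to the
#'   cell region (`NULL` includes all valid-flow pixels).
#' @return An object of class `"direction_map"` with matrices `alpha`,
#'   `beta`, `delta`, `magnitude`, character matrix `label`, plus `center`
#'   and `magnitude_min`.
#' @export
direction_map <- function(flow, center, magnitude_min = 0.1,
                          tangential_band = 0, cell_mask = NULL) {
  stopifnot(inherits(flow, "flow_field"))
  if (inherits(center, "center_estimate")) center <- center$center
  m <- nrow(flow$vx); n <- ncol(flow$vx)
  if (!is.null(cell_mask) && !identical(dim(cell_mask), c(m, n)))
    stop("cell_mask geometry does not match the flow field", call. = FALSE)
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  dy <- center[1] - rows
  dx <- center[2] - cols
  alpha <- atan2(dy, dx)
  at_center <- abs(dy) < 1e-9 & abs(dx) < 1e-9
  alpha[at_center] <- NA_real_
  beta <- atan2(flow$vy, flow$vx)
  delta <- angle_difference(alpha, beta)
  magnitude <- sqrt(flow$vx^2 + flow$vy^2)
  label <- matrix(classify_direction(as.vector(delta), as.vector(magnitude),
                                     magnitude_min, tangential_band), m, n)
  label[!flow$valid] <- "Excluded"
  label[at_center] <- "Excluded"
  if (!is.null(cell_mask)) label[!cell_mask] <- "Excluded"
  structure(list(alpha = alpha, beta = beta, delta = delta,
                 magnitude = magnitude, label = label,
                 valid = flow$valid,
                 center = center, magnitude_min = magnitude_min),
            class = "direction_map")
}

#' @export
print.direction_map <- function(x, ...) {
  tab <- table(factor(x$label, c("Inward", "Outward", "Excluded")))
  cat(sprintf("<direction_map> %d x %d px, center (%.2f, %.2f)\n",
              nrow(x$label), ncol(x$label), x$center[1], x$center[2]))
  cat(sprintf("  Inward %d | Outward %d | Excluded %d\n",
              tab["Inward"], tab["Outward"], tab["Excluded"]))
  invisible(x)
}

#' Per-frame summaries of a direction-map series
#'
#' For each frame pair: the number of valid flow vectors, the number
#' included after the magnitude threshold, total and mean magnitude over
#' included pixels, inward/outward counts and proportions.  Frames with no
#' included vector report `NA` proportions (undefined, not zero).
#'
#' @param maps list of `"direction_map"` objects (one per frame pair).
#' @return `data.frame` with one row per frame pair.
#' @export
summarize_series <- function(maps) {
  if (length(maps) == 0) stop("empty series", call. = FALSE)
  rows <- lapply(seq_along(maps), function(k) {
    mp <- maps[[k]]
    inc <- mp$label != "Excluded"
    n_in <- sum(mp$label == "Inward")
    n_out <- sum(mp$label == "Outward")
    nv <- n_in + n_out
    data.frame(frame = k,
               n_valid = sum(mp$valid),
               n_vectors = nv,
               total_magnitude = sum(mp$magnitude[inc]),
               mean_magnitude = if (nv > 0) mean(mp$magnitude[inc]) else NA_real_,
               n_inward = n_in, n_outward = n_out,
               prop_inward = if (nv > 0) n_in / nv else NA_real_,
               prop_outward = if (nv > 0) n_out / nv else NA_real_)
  })
  do.call(rbind, rows)
}

#' Sensitivity of the direction labels to center-localization error
#'
#' Displaces the center to `n_angles` evenly spaced positions on a circle
#' of radius `offset` around the reference center, recomputes the
#' direction map for every flow field, and measures (per offset and
#' displacement angle, aggregated over frames): the mean absolute change
#' in the wrapped angle `delta`, and the percentage of pixels included in
#' both maps whose inward/outward label flips.
#'
#' @param flows list of `"flow_field"` objects.
#' @param center_true reference `(row, col)` center.
#' @param offsets displacement radii in pixels (0 allowed: identity row).
#' @param n_angles number of evenly spaced displacement directions (>= 4
#'   whenever any offset is positive).
#' @param magnitude_min inclusion threshold passed to [direction_map()].
#' @return An object of class `"center_sensitivity"`: `per_angle`
#'   (`data.frame`: offset, angle_index, flip_percent, mean_delta_error,
#'   n_pixels) and `by_offset` (aggregated over angles).
#' @export
center_error_sensitivity <- function(flows, center_true,
                                     offsets = c(1, 2, 5, 10),
                                     n_angles = 8L, magnitude_min = 0.1) {
  if (any(offsets < 0)) stop("offsets must be >= 0", call. = FALSE)
  if (any(offsets > 0) && n_angles < 4L)
    stop("n_angles must be >= 4", call. = FALSE)
  if (!is.list(flows)) flows <- list(flows)
  m <- nrow(flows[[1]]$vx); n <- ncol(flows[[1]]$vx)
  ref <- lapply(flows, direction_map, center = center_true,
                magnitude_min = magnitude_min)
  rows <- list()
  for (d in offsets) {
    na <- if (d == 0) 1L else n_angles
    for (a in seq_len(na)) {
      phi <- 2 * pi * (a - 1L) / n_angles
      ctr <- center_true + d * c(sin(phi), cos(phi))   # (row, col)
      if (ctr[1] < 1 || ctr[1] > m || ctr[2] < 1 || ctr[2] > n) {
        message(sprintf("skipping displaced center outside image: offset %g, angle %d",
                        d, a))
        next
      }
      flips <- 0L; both <- 0L; derr <- 0; ndelta <- 0L
      for (k in seq_along(flows)) {
        mp <- direction_map(flows[[k]], ctr, magnitude_min = magnitude_min)
        inc <- ref[[k]]$label != "Excluded" & mp$label != "Excluded"
        both <- both + sum(inc)
        flips <- flips + sum(ref[[k]]$label[inc] != mp$label[inc])
        dd <- abs(mp$delta[inc] - ref[[k]]$delta[inc])
        derr <- derr + sum(dd); ndelta <- ndelta + length(dd)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        offset = d, angle_index = a,
        flip_percent = if (both > 0) 100 * flips / both else NA_real_,
        mean_delta_error = if (ndelta > 0) derr / ndelta else NA_real_,
        n_pixels = both)
    }
  }
  per_angle <- do.call(rbind, rows)
  by_offset <- do.call(rbind, lapply(split(per_angle, per_angle$offset),
    function(g) data.frame(offset = g$offset[1],
                           flip_percent = stats::weighted.mean(g$flip_percent, g$n_pixels),
                           mean_delta_error = stats::weighted.mean(g$mean_delta_error, g$n_pixels),
                           n_pixels = sum(g$n_pixels))))
  by_offset <- by_offset[order(by_offset$offset), , drop = FALSE]
  rownames(by_offset) <- NULL
  structure(list(per_angle = per_angle, by_offset = by_offset,
                 center_true = center_true, n_angles = n_angles),
            class = "center_sensitivity")
}

#' @export
print.center_sensitivity <- function(x, ...) {
  cat("<center_sensitivity> label-flip percentage by center offset:\n")
  print(x$by_offset, row.names = FALSE)
  invisible(x)
}
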