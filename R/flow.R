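#' Lucas-Kanade flow parameters
#'
#' Controls the dense Lucas-Kanade solve.  The flow at a pixel is the
#' weighted least-squares solution of the brightness-constancy constraint
#' `Ix*Vx + Iy*Vy + It = 0` over the `(2*window_radius + 1)^2` neighborhood
#' centered on the pixel, with squared window weights `W^2`:
#'
#' \deqn{[V_x, V_y]^T = M^{-1} b, \quad
#'   M = \begin{bmatrix}\sum W^2 I_x^2 & \sum W^2 I_x I_y\\
#'                      \sum W^2 I_x I_y & \sum W^2 I_y^2\end{bmatrix},\
#'   b = \begin{bmatrix}-\sum W^2 I_x I_t\\ -\sum W^2 I_y I_t\end{bmatrix}}
#'
#' A pixel is flagged invalid (flow set to 0) when the smaller eigenvalue
#' of the structure tensor `M` falls below `eigenvalue_min`: there the
#' aperture problem makes the solve ill-posed.  The threshold is applied
#' on intensity-normalized frames (the pair is divided by its joint
#' maximum before differentiation), so its scale does not depend on camera
#' gain.
#'
#' @param window_radius half-width of the square neighborhood (>= 1);
#'   the default 7 gives a 15 x 15 window.
#' @param weight_kernel `"gaussian"` (default) or `"uniform"` window `W`.
#' @param weight_sigma SD of the Gaussian window; default
#'   `window_radius / 2`.
#' @param eigenvalue_min validity threshold on the smaller structure-tensor
#'   eigenvalue (intensity-normalized units).
#' @param smoothing_sigma Gaussian pre-smoothing applied to both frames
#'   before differentiation; 0 disables.
#' @return An object of class `"flow_params"`.
#' @export
flow_params <- function(window_radius = 7L,
                        weight_kernel = c("gaussian", "uniform"),
                        weight_sigma = window_radius / 2,
                        eigenvalue_min = 1e-4,
                        smoothing_sigma = 1.0) {
  weight_kernel <- match.arg(weight_kernel)
  if (window_radius < 1L) stop("window_radius must be >= 1", call. = FALSE)
  if (eigenvalue_min < 0) stop("eigenvalue_min must be >= 0", call. = FALSE)
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0", call. = FALSE)
  structure(list(window_radius = as.integer(window_radius),
                 weight_kernel = weight_kernel,
                 weight_sigma = weight_sigma,
                 eigenvalue_min = eigenvalue_min,
                 smoothing_sigma = smoothing_sigma),
            class = "flow_params")
}

# 1-D window profile w (so that the 2-D window is W = outer(w, w)); the
# least-squares weights are W^2 = outer(w^2, w^2), which stays separable.
window_profile <- function(params) {
  r <- params$window_radius
  if (params$weight_kernel == "uniform") {
    rep(1, 2 * r + 1)
  } else {
    u <- seq(-r, r)
    exp(-u^2 / (2 * params$weight_sigma^2))
  }
}

#' Spatial and temporal image gradients
#'
#' Central-difference spatial derivatives (reflect padding) of the mean of
#' the two frames, and the two-frame temporal difference — the discrete
#' `Ix`, `Iy`, `It` of the brightness-constancy constraint.  Optional
#' Gaussian pre-smoothing is applied identically to both frames first.
#'
#' @param prev,nxt the two frames (matrices of identical shape).
#' @param smoothing_sigma Gaussian pre-smoothing SD; 0 disables.
#' @return List with matrices `Ix`, `Iy`, `It`.
#' @export
spatial_temporal_gradients <- function(prev, nxt, smoothing_sigma = 0) {
  if (!identical(dim(prev), dim(nxt)))
    stop("frames must have identical dimensions", call. = FALSE)
  if (smoothing_sigma > 0) {
    prev <- smooth_gaussian(prev, smoothing_sigma)
    nxt <- smooth_gaussian(nxt, smoothing_sigma)
  }
  avg <- (prev + nxt) / 2
  list(Ix = central_diff_x(avg), Iy = central_diff_y(avg), It = nxt - prev)
}

#' Solve the Lucas-Kanade system at one pixel
#'
#' Reference per-pixel solve of the weighted 2x2 normal equations over the
#' window centered at `pixel` (window truncated at image borders).  The
#' dense path [compute_flow()] is the vectorized equivalent.
#'
#' @param Ix,Iy,It gradient matrices from [spatial_temporal_gradients()].
#' @param pixel `(row, col)` integer position.
#' @param params a [flow_params()].
#' @return List with `vx`, `vy` (pixels/frame) and logical `valid`.
#' @export
solve_lk_pixel <- function(Ix, Iy, It, pixel, params = flow_params()) {
  r <- params$window_radius
  m <- nrow(Ix); n <- ncol(Ix)
  i <- pixel[1]; j <- pixel[2]
  if (i < 1 || i > m || j < 1 || j > n)
    stop("pixel outside image", call. = FALSE)
  rr <- max(1L, i - r):min(m, i + r)
  cc <- max(1L, j - r):min(n, j + r)
  w1 <- window_profile(params)
  Wsq <- outer(w1[rr - i + r + 1L]^2, w1[cc - j + r + 1L]^2)
  ix <- Ix[rr, cc]; iy <- Iy[rr, cc]; it <- It[rr, cc]
  a <- sum(Wsq * ix * ix); b <- sum(Wsq * ix * iy); c <- sum(Wsq * iy * iy)
  d <- -sum(Wsq * ix * it); e <- -sum(Wsq * iy * it)
  lam_min <- ((a + c) - sqrt((a - c)^2 + 4 * b^2)) / 2
  if (!is.finite(lam_min) || lam_min < params$eigenvalue_min)
    return(list(vx = 0, vy = 0, valid = FALSE))
  det <- a * c - b * b
  list(vx = (c * d - b * e) / det, vy = (a * e - b * d) / det, valid = TRUE)
}

#' Dense Lucas-Kanade optical flow between two frames
#'
#' Solves the weighted least-squares system at every pixel.  Windows are
#' truncated at the image border; gradient stencils use reflect padding.
#' The frame pair is normalized by its joint maximum before
#' differentiation so that the validity threshold `eigenvalue_min` is
#' intensity-scale free (the flow itself is invariant to global intensity
#' scaling).
#'
#' @param prev,nxt the two frames (matrices, identical shape) or a 2-frame
#'   [image_stack()] passed as `prev`.
#' @param params a [flow_params()].
#' @return An object of class `"flow_field"`: matrices `vx`, `vy`
#'   (pixels/frame, zero where invalid), logical matrix `valid`, and the
#'   `params` used.
#' @examples
#' a <- outer(1:32, 1:32, function(i, j) exp(-((i - 16)^2 + (j - 16)^2) / 8))
#' b <- outer(1:32, 1:32, function(i, j) exp(-((i - 16)^2 + (j - 17)^2) / 8))
#' fl <- compute_flow(a, b, flow_params(smoothing_sigma = 0))
#' median(fl$vx[fl$valid])  # ~ +1 px/frame along x
#' @export
compute_flow <- function(prev, nxt = NULL, params = flow_params()) {
  if (inherits(prev, "image_stack")) {
    check_stack(prev, 2L)
    nxt <- prev$frames[2, , ]
    prev <- prev$frames[1, , ]
  }
  if (!identical(dim(prev), dim(nxt)))
    stop("frames must have identical dimensions", call. = FALSE)
  peak <- max(prev, nxt)
  if (peak > 0) { prev <- prev / peak; nxt <- nxt / peak }
  g <- spatial_temporal_gradients(prev, nxt, params$smoothing_sigma)
  w1sq <- window_profile(params)^2
  S <- function(x) conv_sep(x, w1sq, pad = "zero")
  a <- S(g$Ix * g$Ix); b <- S(g$Ix * g$Iy); c <- S(g$Iy * g$Iy)
  d <- -S(g$Ix * g$It); e <- -S(g$Iy * g$It)
  lam_min <- ((a + c) - sqrt(pmax((a - c)^2 + 4 * b^2, 0))) / 2
  valid <- is.finite(lam_min) & lam_min >= params$eigenvalue_min
  det <- a * c - b * b
  det[!valid] <- 1  # avoid 0/0; overwritten below
  vx <- (c * d - b * e) / det
  vy <- (a * e - b * d) / det
  vx[!valid] <- 0; vy[!valid] <- 0
  structure(list(vx = vx, vy = vy, valid = valid, params = params),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$vx^2 + x$vy^2)[x$valid]
  cat(sprintf("<flow_field> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$vx), ncol(x$vx), sum(x$valid),
              100 * mean(x$valid)))
  if (length(mag))
    cat(sprintf("  |V|: median %.3f, max %.3f px/frame\n",
                stats::median(mag), max(mag)))
  invisible(x)
}

#' Optical flow for every adjacent frame pair of a stack
#'
#' @param stack an [image_stack()] with `N >= 2` frames.
#' @param params a [flow_params()].
#' @return List of `N - 1` `"flow_field"` objects; element `k` is the flow
#'   from frame `k` to frame `k + 1`.
#' @export
compute_flow_series <- function(stack, params = flow_params()) {
  check_stack(stack, 2L)
  N <- n_frames(stack)
  lapply(seq_len(N - 1L), function(k)
    compute_flow(stack$frames[k, , ], stack$frames[k + 1L, , ], params))
}

#' Export a flow field as a data frame
#'
#' @param flow a `"flow_field"`.
#' @param frame frame-pair index recorded in the output.
#' @param valid_only drop invalid pixels if `TRUE`.
#' @return `data.frame` with columns frame, row, col, vx, vy, valid.
#' @export
flow_as_data_frame <- function(flow, frame = 1L, valid_only = FALSE) {
  stopifnot(inherits(flow, "flow_field"))
  m <- nrow(flow$vx); n <- ncol(flow$vx)
  df <- data.frame(frame = frame,
                   row = rep(seq_len(m), n),
                   col = rep(seq_len(n), each = m),
                   vx = as.vector(flow$vx), vy = as.vector(flow$vy),
                   valid = as.vector(flow$valid))
  if (valid_only) df <- df[df$valid, , drop = FALSE]
  df
}
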