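#' Time-lapse image stack
#'
#' Container for a single-channel fluorescence time-lapse movie: an
#' `(N, m, n)` array of non-negative intensities (frame, row, column) plus
#' acquisition metadata.  All temporal operations in the package require
#' `N >= 2` frames of identical `(m, n)` shape.
#'
#' Coordinate convention used throughout the package: a pixel is addressed
#' as (row `i`, column `j`), 1-based, with pixel centers at integer
#' coordinates.  Angle arithmetic is done in `(x, y) = (column, row)` with
#' `x` increasing rightward and `y` increasing *downward*; because the same
#' convention is applied to flow vectors and to pixel-to-center vectors,
#' their angular difference is convention-independent.
#'
#' @param frames numeric array of dimension `(N, m, n)`, or a list of
#'   identically sized matrices (one per frame).
#' @param frame_interval seconds between frames (metadata only; all flow is
#'   reported in pixels/frame).
#' @param pixel_size physical units per pixel, or `NA` if unknown
#'   (metadata only).
#' @return An object of class `"image_stack"`.
#' @examples
#' st <- image_stack(array(runif(4 * 8 * 8), c(4, 8, 8)))
#' dim(st$frames)
#' @export
image_stack <- function(frames, frame_interval = 1.0, pixel_size = NA_real_) {
  if (is.list(frames)) {
    shapes <- unique(lapply(frames, dim))
    if (length(shapes) != 1L)
      stop("all frames must share identical (m, n) dimensions", call. = FALSE)
    arr <- array(NA_real_, c(length(frames), shapes[[1]][1], shapes[[1]][2]))
    for (k in seq_along(frames)) arr[k, , ] <- frames[[k]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-D (frame, row, column) array", call. = FALSE)
  storage.mode(frames) <- "double"
  if (anyNA(frames) || any(!is.finite(frames)))
    stop("intensities must be finite", call. = FALSE)
  if (any(frames < 0))
    stop("intensities must be >= 0", call. = FALSE)
  structure(
    list(frames = frames,
         frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s), %d x %d px, interval %g s\n",
              d[1], d[2], d[3], x$frame_interval))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

# number of frames
n_frames <- function(stack) dim(stack$frames)[1]

#' Extract one frame as a matrix
#'
#' @param stack an [image_stack()].
#' @param k frame index (1-based).
#' @return `m x n` numeric matrix.
#' @export
get_frame <- function(stack, k) {
  stopifnot(inherits(stack, "image_stack"))
  N <- n_frames(stack)
  if (k < 1 || k > N) stop("frame index out of range", call. = FALSE)
  stack$frames[k, , ]
}

# internal: require a stack with at least `n` frames
check_stack <- function(stack, min_frames = 2L) {
  if (!inherits(stack, "image_stack"))
    stop("expected an 'image_stack' object", call. = FALSE)
  if (n_frames(stack) < min_frames)
    stop(sprintf("operation requires at least %d frames (got %d)",
                 min_frames, n_frames(stack)), call. = FALSE)
  invisible(stack)
}
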