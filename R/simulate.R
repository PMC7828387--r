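#' Scene configuration for the synthetic vesicle-movie generator
#'
#' Describes a simulated quantum-dot-labeled vesicle movie: diffraction-
#' limited Gaussian spots over a dim circular cell body on a dark
#' background, with per-vesicle radial (inward/outward) drift plus
#' diffusive jitter and Poisson-Gaussian camera noise.  The seed fully
#' determines the movie and its ground truth.
#'
#' @param image_size `(m, n)` image dimensions in pixels.
#' @param n_frames number of frames.
#' @param cell_center true cell center `(row, col)`, continuous coordinates.
#' @param cell_radius cell body radius in pixels; must be at least
#'   `3 * psf_sigma`.
#' @param n_vesicles number of vesicles.
#' @param modes per-vesicle motion mode: `"inward"`, `"outward"` or
#'   `"diffusive"`; a single value is recycled, otherwise supply a vector
#'   of length `n_vesicles`.
#' @param radial_speed magnitude of the radial drift step, pixels/frame.
#' @param diffusion_sigma SD of the per-axis Gaussian jitter, pixels/frame.
#' @param psf_sigma SD of the isotropic Gaussian point-spread function, px.
#' @param spot_amplitude peak intensity of one spot above the local level.
#' @param cell_body_level intensity added inside the cell disk.
#' @param background_level intensity of the dark background.
#' @param noise_sigma SD of additive Gaussian read noise (0 disables);
#'   the default is 5% of `spot_amplitude`.
#' @param poisson_noise if `TRUE`, replaces each noiseless pixel value by a
#'   Poisson draw with that mean before Gaussian noise is added.
#' @param seed integer seed; identical configs produce bit-identical movies.
#' @param r_start_range initial vesicle radii as fractions of `cell_radius`.
#' @return An object of class `"scene_config"`.
#' @seealso [simulate_vesicle_movie()]
#' @export
scene_config <- function(image_size = c(128L, 128L),
                         n_frames = 12L,
                         cell_center = (image_size + 1) / 2,
                         cell_radius = 45,
                         n_vesicles = 50L,
                         modes = c("inward", "outward"),
                         radial_speed = 1.5,
                         diffusion_sigma = 0.2,
                         psf_sigma = 1.5,
                         spot_amplitude = 100,
                         cell_body_level = 20,
                         background_level = 10,
                         noise_sigma = 0.05 * spot_amplitude,
                         poisson_noise = FALSE,
                         seed = 1L,
                         r_start_range = c(0.55, 0.95)) {
  modes <- match.arg(modes, c("inward", "outward", "diffusive"),
                     several.ok = TRUE)
  if (length(modes) != n_vesicles)
    modes <- rep(modes, length.out = max(n_vesicles, 1L))
  cfg <- list(image_size = as.integer(image_size), n_frames = as.integer(n_frames),
              cell_center = as.numeric(cell_center), cell_radius = cell_radius,
              n_vesicles = as.integer(n_vesicles), modes = modes,
              radial_speed = radial_speed, diffusion_sigma = diffusion_sigma,
              psf_sigma = psf_sigma, spot_amplitude = spot_amplitude,
              cell_body_level = cell_body_level,
              background_level = background_level,
              noise_sigma = noise_sigma, poisson_noise = poisson_noise,
              seed = as.integer(seed), r_start_range = r_start_range)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

#' Peripheral-fluctuation scene preset
#'
#' A [scene_config()] emulating the regime the center estimator assumes:
#' a dense population of vesicles jittering in the cell periphery
#' (annulus 0.45-0.95 of the cell radius) around a quiet interior.  Used
#' to validate cell-center recovery.
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [scene_config()].
#' @return A `"scene_config"`.
#' @export
scene_config_peripheral <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_vesicles = 400L, modes = "diffusive",
         diffusion_sigma = 1.5, r_start_range = c(0.45, 0.95),
         n_frames = 20L),
    list(...))
  do.call(scene_config, args)
}

validate_scene_config <- function(cfg) {
  bad <- character()
  if (length(cfg$image_size) != 2L || any(cfg$image_size < 8L))
    bad <- c(bad, "image_size must be two integers >= 8")
  if (cfg$n_frames < 2L) bad <- c(bad, "n_frames must be >= 2")
  if (cfg$cell_radius < 3 * cfg$psf_sigma)
    bad <- c(bad, "cell_radius must be >= 3 * psf_sigma")
  if (cfg$n_vesicles >= 1L && length(cfg$modes) != cfg$n_vesicles)
    bad <- c(bad, "modes must have length n_vesicles")
  if (cfg$radial_speed < 0 || cfg$diffusion_sigma < 0 || cfg$noise_sigma < 0)
    bad <- c(bad, "speeds and noise levels must be >= 0")
  if (any(cfg$r_start_range < 0) || any(cfg$r_start_range > 1) ||
      diff(cfg$r_start_range) < 0)
    bad <- c(bad, "r_start_range must be an increasing pair in [0, 1]")
  if (length(bad))
    stop("invalid scene_config: ", paste(bad, collapse = "; "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %dx%d px, %d frames, %d vesicle(s), seed %d\n",
              x$image_size[1], x$image_size[2], x$n_frames, x$n_vesicles,
              x$seed))
  if (x$n_vesicles > 0)
    cat("  modes:", paste(sprintf("%s=%d", names(table(x$modes)),
                                  table(x$modes)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a ground-truthed vesicle movie
#'
#' Renders, frame by frame: `background_level`, plus `cell_body_level`
#' inside the disk of `cell_radius` about the true center, plus one
#' isotropic Gaussian spot per vesicle at its current position.  Between
#' frames each vesicle takes a step of `radial_speed` pixels along the
#' radial direction (toward the center for inward vesicles, away for
#' outward; diffusive vesicles do not drift) plus independent
#' `N(0, diffusion_sigma^2)` jitter on each axis.  An inward vesicle
#' freezes once it comes within 1 px of the center; an outward one freezes
#' at the cell boundary.  Poisson and/or Gaussian noise is applied last
#' and the result clamped at zero.
#'
#' @param config a [scene_config()].
#' @return A list with components `stack` (an [image_stack()]) and `truth`
#'   (class `"vesicle_truth"`: `positions` array `(n_frames, n_vesicles, 2)`
#'   in (row, col), per-vesicle `modes`, and `cell_center`).
#' @examples
#' sim <- simulate_vesicle_movie(scene_config(image_size = c(48, 48),
#'   n_frames = 4, n_vesicles = 5, cell_radius = 15, seed = 7))
#' sim$stack
#' @export
simulate_vesicle_movie <- function(config) {
  validate_scene_config(config)
  withr::with_seed(config$seed, simulate_vesicle_movie_impl(config))
}

simulate_vesicle_movie_impl <- function(cfg) {
  m <- cfg$image_size[1]; n <- cfg$image_size[2]
  nv <- cfg$n_vesicles; nf <- cfg$n_frames
  ctr <- cfg$cell_center

  pos <- array(NA_real_, c(nf, max(nv, 1L), 2L))
  frozen <- rep(FALSE, max(nv, 1L))
  if (nv > 0) {
    r0 <- stats::runif(nv, cfg$r_start_range[1], cfg$r_start_range[2]) *
      cfg$cell_radius
    th0 <- stats::runif(nv, 0, 2 * pi)
    pos[1, , 1] <- ctr[1] + r0 * sin(th0)
    pos[1, , 2] <- ctr[2] + r0 * cos(th0)
    for (k in seq_len(nf - 1L)) {
      cur <- pos[k, , , drop = FALSE]
      nxt <- matrix(NA_real_, nv, 2)
      for (v in seq_len(nv)) {
        p <- c(pos[k, v, 1], pos[k, v, 2])
        if (frozen[v]) { nxt[v, ] <- p; next }
        d <- sqrt(sum((p - ctr)^2))
        u <- if (d > 1e-12) (p - ctr) / d else c(0, 0)
        step <- switch(cfg$modes[v],
                       inward  = -cfg$radial_speed * u,
                       outward =  cfg$radial_speed * u,
                       diffusive = c(0, 0))
        q <- p + step + stats::rnorm(2, 0, cfg$diffusion_sigma)
        dq <- sqrt(sum((q - ctr)^2))
        if (cfg$modes[v] == "inward" && dq < 1) {
          frozen[v] <- TRUE
        } else if (cfg$modes[v] == "outward" && dq >= cfg$cell_radius) {
          # clamp on the boundary along the current direction
          q <- ctr + (q - ctr) * (cfg$cell_radius / dq)
          frozen[v] <- TRUE
        }
        nxt[v, ] <- q
      }
      pos[k + 1L, , ] <- nxt
    }
  }

  # static scene: background + cell disk
  rows <- matrix(seq_len(m), m, n)
  cols <- matrix(seq_len(n), m, n, byrow = TRUE)
  disk <- ((rows - ctr[1])^2 + (cols - ctr[2])^2) <= cfg$cell_radius^2
  base <- matrix(cfg$background_level, m, n) + cfg$cell_body_level * disk

  frames <- array(0, c(nf, m, n))
  wr <- ceiling(4 * cfg$psf_sigma)
  for (k in seq_len(nf)) {
    fr <- base
    if (nv > 0) {
      for (v in seq_len(nv)) {
        pr <- pos[k, v, 1]; pc <- pos[k, v, 2]
        r1 <- max(1L, floor(pr) - wr); r2 <- min(m, ceiling(pr) + wr)
        c1 <- max(1L, floor(pc) - wr); c2 <- min(n, ceiling(pc) + wr)
        if (r1 > r2 || c1 > c2) next
        rr <- r1:r2; cc <- c1:c2
        g <- cfg$spot_amplitude *
          exp(-outer((rr - pr)^2, (cc - pc)^2, "+") / (2 * cfg$psf_sigma^2))
        fr[rr, cc] <- fr[rr, cc] + g
      }
    }
    if (cfg$poisson_noise)
      fr <- matrix(stats::rpois(length(fr), lambda = fr), m, n)
    if (cfg$noise_sigma > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), 0, cfg$noise_sigma), m, n)
    frames[k, , ] <- pmax(fr, 0)
  }

  truth <- structure(
    list(positions = pos[, seq_len(max(nv, 1L)), , drop = FALSE],
         modes = if (nv > 0) cfg$modes else character(),
         cell_center = ctr,
         cell_radius = cfg$cell_radius,
         config = cfg),
    class = "vesicle_truth")
  if (nv == 0) truth$positions <- array(NA_real_, c(nf, 0L, 2L))
  list(stack = image_stack(frames), truth = truth)
}

#' @export
print.vesicle_truth <- function(x, ...) {
  cat(sprintf("<vesicle_truth> %d frame(s), %d vesicle(s), center (%.2f, %.2f)\n",
              dim(x$positions)[1], dim(x$positions)[2],
              x$cell_center[1], x$cell_center[2]))
  invisible(x)
}

#' Per-vesicle ground-truth direction label for one frame pair
#'
#' Labels each vesicle `"Inward"` if its distance to the true center
#' decreased by more than `tol` pixels between frames `k` and `k + 1`,
#' `"Outward"` if it increased by more, and `"Static"` otherwise.
#'
#' @param truth a `"vesicle_truth"` object from [simulate_vesicle_movie()].
#' @param k index of the first frame of the pair.
#' @param tol dead-band on the distance change, pixels.
#' @return Character vector of length `n_vesicles`.
#' @export
ground_truth_direction <- function(truth, k, tol = 0.25) {
  stopifnot(inherits(truth, "vesicle_truth"))
  nf <- dim(truth$positions)[1]
  if (k < 1 || k > nf - 1L)
    stop("frame pair index out of range", call. = FALSE)
  nv <- dim(truth$positions)[2]
  if (nv == 0) return(character())
  d1 <- sqrt((truth$positions[k, , 1] - truth$cell_center[1])^2 +
             (truth$positions[k, , 2] - truth$cell_center[2])^2)
  d2 <- sqrt((truth$positions[k + 1L, , 1] - truth$cell_center[1])^2 +
             (truth$positions[k + 1L, , 2] - truth$cell_center[2])^2)
  ifelse(d2 < d1 - tol, "Inward", ifelse(d2 > d1 + tol, "Outward", "Static"))
}

#' Ground truth as a long-format data frame
#'
#' @param truth a `"vesicle_truth"` object.
#' @return `data.frame` with columns frame, vesicle, row, col, mode.
#' @export
truth_as_data_frame <- function(truth) {
  stopifnot(inherits(truth, "vesicle_truth"))
  nf <- dim(truth$positions)[1]; nv <- dim(truth$positions)[2]
  if (nv == 0)
    return(data.frame(frame = integer(), vesicle = integer(),
                      row = numeric(), col = numeric(), mode = character()))
  data.frame(
    frame = rep(seq_len(nf), times = nv),
    vesicle = rep(seq_len(nv), each = nf),
    row = as.vector(truth$positions[, , 1]),
    col = as.vector(truth$positions[, , 2]),
    mode = rep(truth$modes, each = nf))
}
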