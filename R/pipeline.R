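#' Fit the whole-cell vesicle transport direction model to a stack
#'
#' The package's central entry point.  Runs the full analysis on a
#' time-lapse stack: dense Lucas-Kanade optical flow between every
#' adjacent frame pair, geometric cell-center estimation from the
#' temporal intensity STD map, per-pixel inward/outward classification of
#' each flow vector relative to the center, and per-frame summaries.
#'
#' @param stack an [image_stack()] (or a path passed to [read_stack()]).
#' @param flow_params a [flow_params()].
#' @param center_mode `"masked"` (background-restricted, default) or
#'   `"literal"`; see [estimate_center()].
#' @param center optional known `(row, col)` center; skips estimation
#'   (useful with synthetic ground truth).
#' @param magnitude_min inclusion threshold on flow magnitude, px/frame.
#' @param tangential_band optional exclusion band around `pi/2`; see
#'   [classify_direction()].
#' @param restrict_to_cell restrict classification to the Otsu cell
#'   region (only available in `"masked"` mode); default `FALSE`
#'   (all valid-flow pixels are classified).
#' @return An object of class `"vesicleflow"` with components `stack`,
#'   `flows` (list of `"flow_field"`), `center` (a `"center_estimate"` or
#'   the supplied coordinates), `maps` (list of `"direction_map"`),
#'   `summaries` (`data.frame`), and `call`.
#' @examples
#' sim <- simulate_vesicle_movie(scene_config_peripheral(seed = 11,
#'   image_size = c(64, 64), cell_radius = 22, n_vesicles = 150,
#'   n_frames = 10))
#' fit <- vesicleflow(sim$stack)
#' summary(fit)
#' @export
vesicleflow <- function(stack,
                        flow_params = vesicleflow::flow_params(),
                        center_mode = c("masked", "literal"),
                        center = NULL,
                        magnitude_min = 0.1,
                        tangential_band = 0,
                        restrict_to_cell = FALSE) {
  cl <- match.call()
  center_mode <- match.arg(center_mode)
  if (is.character(stack)) stack <- read_stack(stack)
  check_stack(stack, 2L)
  flows <- compute_flow_series(stack, flow_params)
  cell_mask <- NULL
  if (is.null(center)) {
    center <- estimate_center(stack, mode = center_mode)
    if (restrict_to_cell) cell_mask <- center$cell_mask
  } else if (restrict_to_cell) {
    stop("restrict_to_cell requires an estimated center", call. = FALSE)
  }
  maps <- lapply(flows, direction_map, center = center,
                 magnitude_min = magnitude_min,
                 tangential_band = tangential_band, cell_mask = cell_mask)
  summaries <- summarize_series(maps)
  structure(list(stack = stack, flows = flows, center = center,
                 maps = maps, summaries = summaries,
                 magnitude_min = magnitude_min, call = cl),
            class = "vesicleflow")
}

center_coords <- function(center) {
  if (inherits(center, "center_estimate")) center$center else center
}

#' @export
print.vesicleflow <- function(x, ...) {
  ctr <- center_coords(x$center)
  cat(sprintf("<vesicleflow> %d frame pair(s), %d x %d px\n",
              length(x$flows), dim(x$stack)[2], dim(x$stack)[3]))
  cat(sprintf("  cell center (row, col): (%.2f, %.2f)%s\n", ctr[1], ctr[2],
              if (inherits(x$center, "center_estimate"))
                sprintf(" [%s mode]", x$center$mode) else " [supplied]"))
  ok <- !is.na(x$summaries$prop_inward)
  if (any(ok))
    cat(sprintf("  overall inward proportion: %.3f (%d vectors)\n",
                sum(x$summaries$n_inward[ok]) / sum(x$summaries$n_vectors[ok]),
                sum(x$summaries$n_vectors)))
  invisible(x)
}

#' @export
summary.vesicleflow <- function(object, ...) {
  print(object)
  cat("\nPer-frame summaries:\n")
  print(object$summaries, row.names = FALSE, digits = 4)
  invisible(object$summaries)
}

#' @param x a `"vesicleflow"` fit.
#' @param frame frame-pair index to render in the map panel.
#' @param which `"summary"` (time-series panels) or `"map"` (diverging
#'   rendering of one direction map, drawn with [graphics::rasterImage()]).
#' @param ... unused.
#' @rdname vesicleflow
#' @export
plot.vesicleflow <- function(x, frame = 1L, which = c("summary", "map"), ...) {
  which <- match.arg(which)
  if (which == "summary") {
    s <- x$summaries
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(s$frame, s$n_vectors, type = "o", pch = 16,
                   xlab = "frame pair", ylab = "detected vectors")
    graphics::plot(s$frame, s$prop_inward, type = "o", pch = 16, col = "red3",
                   ylim = c(0, 1), xlab = "frame pair", ylab = "proportion")
    graphics::lines(s$frame, s$prop_outward, type = "o", pch = 16,
                    col = "blue3")
  } else {
    img <- render_diverging(x$maps[[frame]])
    graphics::plot(0:1, 0:1, type = "n", axes = FALSE, xlab = "", ylab = "",
                   asp = ncol(img) / nrow(img))
    graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
  }
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; unknown keys are rejected.  Recognized keys mirror the
#' arguments of [scene_config()], [flow_params()] and [vesicleflow()]:
#' `input`, `scene` (a list of scene_config arguments), `flow` (a list of
#' flow_params arguments), `center_mode`, `magnitude_min`,
#' `tangential_band`, `restrict_to_cell`, `polar` (list: `n_r`,
#' `n_theta`, `r_max`), `render` (list of render_config arguments),
#' `offsets`, `n_angles`, `seed`, `out_dir`.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return Named list with resolved defaults.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("input", "scene", "flow", "center_mode", "magnitude_min",
             "tangential_band", "restrict_to_cell", "polar", "render",
             "offsets", "n_angles", "seed", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  defaults <- list(center_mode = "masked", magnitude_min = 0.1,
                   tangential_band = 0, restrict_to_cell = FALSE,
                   offsets = c(1, 2, 5, 10), n_angles = 8L, seed = 1L,
                   polar = list(), flow = list(), render = list())
  utils::modifyList(defaults, cfg)
}

#' Run the full pipeline and write an output bundle
#'
#' Chains simulation (or reading), flow, center estimation, direction
#' classification, summaries, polar transform and rendering, and writes
#' every product plus the effective configuration to `out_dir`.  The run
#' is deterministic given the config (including the seed of a synthetic
#' scene).
#'
#' @param config list from [read_pipeline_config()], or a path to a
#'   config file.  Must contain either `input` (a TIFF path) or `scene`.
#' @param out_dir output directory (created if missing); overrides any
#'   `out_dir` in the config.
#' @return The `"vesicleflow"` fit, invisibly.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  if (is.null(config$input) && is.null(config$scene))
    stop("config must provide 'input' or 'scene'", call. = FALSE)
  if (!is.null(config$input) && !file.exists(config$input))
    stop("input not found: ", config$input, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message(sprintf(...))

  truth <- NULL
  if (!is.null(config$input)) {
    msg("[input] reading %s", config$input)
    stack <- read_stack(config$input)
  } else {
    sc <- do.call(scene_config, utils::modifyList(as.list(config$scene),
                                                  list(seed = config$seed)))
    msg("[simulate] %dx%d px, %d frames, %d vesicles, seed %d",
        sc$image_size[1], sc$image_size[2], sc$n_frames, sc$n_vesicles,
        sc$seed)
    sim <- simulate_vesicle_movie(sc)
    stack <- sim$stack
    truth <- sim$truth
    write_stack(stack, file.path(out_dir, "movie.tif"))
    utils::write.csv(truth_as_data_frame(truth),
                     file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }

  fp <- do.call(flow_params, config$flow)
  msg("[flow] window_radius=%d kernel=%s smoothing_sigma=%g",
      fp$window_radius, fp$weight_kernel, fp$smoothing_sigma)
  msg("[center] mode=%s; [classify] magnitude_min=%g",
      config$center_mode, config$magnitude_min)
  fit <- vesicleflow(stack, flow_params = fp,
                     center_mode = config$center_mode,
                     magnitude_min = config$magnitude_min,
                     tangential_band = config$tangential_band,
                     restrict_to_cell = isTRUE(config$restrict_to_cell))

  # flow + direction exports
  utils::write.csv(do.call(rbind, lapply(seq_along(fit$flows), function(k)
    flow_as_data_frame(fit$flows[[k]], frame = k, valid_only = TRUE))),
    file.path(out_dir, "flow.csv"), row.names = FALSE)
  if (inherits(fit$center, "center_estimate")) {
    write_center_json(fit$center, file.path(out_dir, "center.json"))
    write_stack(image_stack(array(fit$center$std_map,
                                  c(1, dim(fit$center$std_map)))),
                file.path(out_dir, "std_map.tif"))
  }
  utils::write.csv(fit$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)

  # polar view and renders of the first frame pair
  ctr <- center_coords(fit$center)
  pol <- do.call(to_polar_labels,
                 c(list(map = fit$maps[[1]], center = ctr), config$polar))
  write_polar(pol$delta, file.path(out_dir, "polar_delta.tif"))
  rc <- do.call(render_config, config$render)
  write_render(render_diverging(fit$maps[[1]], rc),
               file.path(out_dir, "direction_diverging.png"))
  write_render(render_hsv(fit$flows[[1]], rc),
               file.path(out_dir, "flow_hsv.png"))
  render_summary_panels(fit$summaries, file.path(out_dir, "summaries.png"))

  # effective config echo
  eff <- config
  eff$flow <- unclass(fp)
  eff$out_dir <- out_dir
  yaml::write_yaml(eff, file.path(out_dir, "effective_config.yaml"))
  msg("[done] outputs in %s", out_dir)
  invisible(fit)
}

#' Run the center-error sensitivity analysis and write its products
#'
#' @param config as in [run_pipeline()]; `offsets` and `n_angles` control
#'   the displacements.
#' @param out_dir output directory.
#' @return The `"center_sensitivity"` object, invisibly.
#' @export
run_sensitivity <- function(config, out_dir = config$out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$input)) {
    stack <- read_stack(config$input)
    fp <- do.call(flow_params, config$flow)
    flows <- compute_flow_series(stack, fp)
    ctr <- estimate_center(stack, mode = config$center_mode)$center
  } else {
    sc <- do.call(scene_config, utils::modifyList(as.list(config$scene),
                                                  list(seed = config$seed)))
    sim <- simulate_vesicle_movie(sc)
    fp <- do.call(flow_params, config$flow)
    flows <- compute_flow_series(sim$stack, fp)
    ctr <- sim$truth$cell_center
  }
  sens <- center_error_sensitivity(flows, ctr, offsets = config$offsets,
                                   n_angles = config$n_angles,
                                   magnitude_min = config$magnitude_min)
  utils::write.csv(sens$per_angle, file.path(out_dir, "sensitivity.csv"),
                   row.names = FALSE)
  utils::write.csv(sens$by_offset,
                   file.path(out_dir, "sensitivity_by_offset.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(out_dir, "sensitivity.png"), 700, 500)
  graphics::plot(sens$by_offset$offset, sens$by_offset$flip_percent,
                 type = "o", pch = 16, xlab = "center offset (px)",
                 ylab = "label flips (%)",
                 main = "Direction-label sensitivity to center error")
  grDevices::dev.off()
  invisible(sens)
}
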