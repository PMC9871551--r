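# Orchestration: reproducible runs tying the modules together. Each command
# writes its resolved configuration next to its outputs so a run can be
# reproduced from the output directory alone.

default_run_config <- function() {
  list(
    seed = 1L,
    n = 10L,
    geometry = list(m = 8, degree = 3, row_offsets = c(30, 60),
                    anchor_index = 50, d_max = 1.5, tolerance = 10),
    scene = list(tilt_range = c(10, 50),
                 modes = c("cloudy", "direct_sun", "backlight"),
                 years = 1:3),
    train = list(lr = 0.01, batch_size = 2, momentum = 0.9,
                 weight_decay = 1e-4, epochs = 30,
                 smoke = list(n_images = 16, image_px = 128, epochs = 5,
                              steps_per_epoch = 10, lr = 1.0))
  )
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over the package defaults (geometry
#' defaults: bark consumption m = 8 px, cubic smoothing, side offsets 30/60,
#' 50-point seed, step constraint 1.5 px, success tolerance 10 px; recorded
#' reference training schedule: lr 0.01, batch 2, momentum 0.9, weight decay
#' 1e-4, 30 epochs).
#'
#' @param path Optional YAML file; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
}

#' Generate a synthetic dataset on disk
#'
#' @param out_dir Output directory.
#' @param config Run configuration (see [load_run_config()]).
#' @return The manifest data frame, invisibly.
#' @export
cmd_synth <- function(out_dir, config = load_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- make_dataset(config$n, seed = config$seed,
                     tilt_range = config$scene$tilt_range,
                     modes = config$scene$modes,
                     years = config$scene$years,
                     out_dir = out_dir)
  write_resolved_config(config, out_dir)
  message(sprintf("wrote %d samples to %s", config$n, out_dir))
  invisible(ds$manifest)
}

#' Locate new tapping lines for a directory of masks
#'
#' Mask mode: every `mask_*.png` in `in_dir` is processed; per-image failures
#' are logged and the run continues. Results (coefficients, raw and smoothed
#' points as `[col, row]`, diagnostics) go to one JSON per image.
#'
#' @param in_dir Directory with mask PNGs.
#' @param out_dir Output directory.
#' @param config Run configuration.
#' @return Named list of `tapping_line_result` (or `NULL` for failures),
#'   invisibly.
#' @export
cmd_locate <- function(in_dir, out_dir, config = load_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  masks <- sort(list.files(in_dir, pattern = "^mask_.*\\.png$",
                           full.names = TRUE))
  if (!length(masks)) stopf("no mask_*.png files in %s", in_dir)
  g <- config$geometry
  results <- list()
  n_fail <- 0L
  for (mp in masks) {
    id <- sub("^mask_", "", sub("\\.png$", "", basename(mp)))
    res <- tryCatch(
      locate_new_line(read_mask_png(mp), m = g$m, degree = g$degree,
                      row_offsets = g$row_offsets,
                      anchor_index = g$anchor_index, d_max = g$d_max),
      error = function(e) {
        message(sprintf("sample %s failed: %s", id, conditionMessage(e)))
        NULL
      })
    results[[id]] <- res
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    out <- list(
      coefficients = as.list(res$coefficients),
      m = res$m, degree = res$degree,
      # [col, row] point order for file outputs
      existing_line = unname(res$existing_line$points[, c("c", "r")]),
      new_line_raw = unname(res$Q1[, c("c", "r")]),
      new_line_smoothed = unname(res$Q2[, c("c", "r")]),
      box_new = as.list(res$box_new),
      timings_s = as.list(res$diagnostics$timings)
    )
    jsonlite::write_json(out, file.path(out_dir, sprintf("line_%s.json", id)),
                         auto_unbox = TRUE, digits = NA)
  }
  write_resolved_config(config, out_dir)
  message(sprintf("located %d/%d lines", length(masks) - n_fail,
                  length(masks)))
  invisible(results)
}

#' Smoke-train the small detector on a synthetic set
#'
#' Trains on a small set of low-resolution scenes and writes the loss curve
#' as CSV. Fails (error) if the loss diverges to NaN; warns if the smoothed
#' loss does not decrease.
#'
#' @param out_dir Output directory (`loss_log.csv`, `resolved_config.yaml`).
#' @param config Run configuration (uses `config$train$smoke`).
#' @return The trained `smoke_detector`, invisibly.
#' @export
cmd_train_smoke <- function(out_dir, config = load_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sm <- config$train$smoke
  if (sm$epochs < 1) stopf("no training requested: smoke epochs < 1")
  ds <- make_dataset(sm$n_images, seed = config$seed,
                     config = smoke_scene_config(sm$image_px, seed = 1L))
  model <- train_smoke_detector(ds$samples, epochs = sm$epochs,
                                steps_per_epoch = sm$steps_per_epoch,
                                lr = sm$lr, seed = config$seed)
  if (any(!is.finite(model$loss_log$L))) stopf("training diverged (NaN loss)")
  utils::write.csv(model$loss_log, file.path(out_dir, "loss_log.csv"),
                   row.names = FALSE)
  write_resolved_config(config, out_dir)
  L <- model$loss_log$L
  if (utils::tail(L, 1) >= L[1]) {
    warning("smoothed loss did not decrease", call. = FALSE)
  }
  message(sprintf("loss %.4f -> %.4f over %d steps", L[1], utils::tail(L, 1),
                  length(L)))
  invisible(model)
}

#' Scene configuration scaled down for smoke training
#'
#' A proportionally shrunken panel in a small image, for cheap training
#' batches.
#'
#' @param image_px Square image side (default 128).
#' @param seed Seed.
#' @param ... Overrides passed to [scene_config()].
#' @return A `scene_config`.
#' @export
smoke_scene_config <- function(image_px = 128, seed = 1L, ...) {
  scene_config(height_px = image_px, width_px = image_px,
               panel_tilt_deg = 25, panel_width_px = 70,
               panel_height_px = 66, trunk_band = c(16, image_px - 16),
               corner_overhang_px = 4, panel_lean_px = 4,
               line_thickness_px = 2, seed = seed, ...)
}

#' Evaluate located lines against a dataset
#'
#' @param data_dir Directory written by [cmd_synth()].
#' @param results Named list from [cmd_locate()] (or predictions with
#'   `box_new`).
#' @param out_dir Output directory for `report.csv` / `report.json`.
#' @param config Run configuration.
#' @return The report data frame, invisibly.
#' @export
cmd_eval <- function(data_dir, results, out_dir,
                     config = load_run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  preds <- lapply(results, function(r) {
    if (is.null(r)) NULL else list(box_new = r$box_new)
  })
  # ground-truth new-line rectangles from regenerated samples
  gt_boxes <- lapply(seq_len(nrow(manifest)), function(i) {
    cfgi <- scene_config(panel_tilt_deg = manifest$panel_tilt_deg[i],
                         panel_width_px = manifest$panel_width_px[i],
                         panel_height_px = manifest$panel_height_px[i],
                         illumination_mode = manifest$illumination_mode[i],
                         seed = manifest$seed[i])
    s <- generate_sample(cfgi)
    c(c_min = min(s$gt_new_line[, "c"]), r_min = min(s$gt_new_line[, "r"]),
      c_max = max(s$gt_new_line[, "c"]), r_max = max(s$gt_new_line[, "r"]))
  })
  names(gt_boxes) <- manifest$id
  names(preds) <- sub("^", "sample_", names(preds))
  report <- evaluate_run(manifest, preds, gt_boxes,
                         tolerance = config$geometry$tolerance,
                         out_csv = file.path(out_dir, "report.csv"),
                         out_json = file.path(out_dir, "report.json"))
  write_resolved_config(config, out_dir)
  invisible(report)
}
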