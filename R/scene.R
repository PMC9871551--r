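# Synthetic trunk/panel scene generator.
#
# Every downstream stage of the pipeline is tested against scenes produced
# here: a tilted quadrilateral "tapped panel" sits on a trunk band, its
# lower-left boundary is the existing tapping line, and the analytic new
# tapping line (the existing line displaced by the bark-consumption distance
# along the panel centre-line direction) is carried as exact ground truth.

#' Scene configuration for the synthetic generator
#'
#' Coordinates are `(r, c)` with `r` increasing downwards; all sizes in
#' pixels. The panel is a five-vertex polygon: the tapping line runs from the
#' bottom-right corner `B` up-left to `C`; one row above `C` the left boundary
#' jogs `corner_overhang_px` further left (the top-left corner of a real panel
#' overhangs the line start, which is what terminates the step-distance filter
#' there); the left edge then leans `panel_lean_px` leftwards up to the top,
#' and the right edge is vertical.
#'
#' @param height_px,width_px Image size (default the working resolution
#'   652x552 used throughout the package).
#' @param panel_tilt_deg Slope of the tapping line from horizontal, degrees.
#'   Realistic cuts span roughly 10-50 degrees.
#' @param panel_width_px Horizontal extent of the tapping line. `NULL` picks
#'   the widest panel (capped at 340) that fits vertically at this tilt.
#' @param panel_height_px Vertical extent of the side edges above the line.
#' @param trunk_band Columns `[c_left, c_right]` covered by the trunk.
#' @param illumination_mode One of `"cloudy"`, `"direct_sun"`, `"backlight"`.
#' @param noise_sd Gaussian pixel noise, gray levels.
#' @param line_thickness_px Rendered groove thickness of the existing cut.
#' @param corner_overhang_px Leftward jog of the boundary just above the line
#'   start (>= 2 so the step-distance gap exceeds 1.5 px).
#' @param panel_lean_px Leftward lean of the left edge from jog to top.
#' @param offset_m_px Bark consumption: displacement of the new line from the
#'   existing line along the centre-line direction (paper default 8).
#' @param seed Integer seed; all randomness in the scene derives from it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height_px = 552, width_px = 652,
                         panel_tilt_deg = 25,
                         panel_width_px = NULL,
                         panel_height_px = 180,
                         trunk_band = c(120, 540),
                         illumination_mode = c("cloudy", "direct_sun", "backlight"),
                         noise_sd = 6,
                         line_thickness_px = 3,
                         corner_overhang_px = 6,
                         panel_lean_px = 10,
                         offset_m_px = 8,
                         seed = 1L) {
  illumination_mode <- match.arg(illumination_mode)
  if (panel_tilt_deg < 0 || panel_tilt_deg > 50) {
    stopf("`panel_tilt_deg` must lie in [0, 50], got %g", panel_tilt_deg)
  }
  if (corner_overhang_px < 2) stopf("`corner_overhang_px` must be >= 2")
  tanb <- tan(panel_tilt_deg * pi / 180)
  if (is.null(panel_width_px)) {
    avail <- height_px - 60 - panel_height_px
    panel_width_px <- if (tanb > 0) min(340, floor(avail / tanb)) else 340
  }
  cfg <- structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    panel_tilt_deg = panel_tilt_deg,
    panel_width_px = as.integer(panel_width_px),
    panel_height_px = as.integer(panel_height_px),
    trunk_band = as.integer(trunk_band),
    illumination_mode = illumination_mode,
    noise_sd = noise_sd,
    line_thickness_px = as.integer(line_thickness_px),
    corner_overhang_px = as.integer(corner_overhang_px),
    panel_lean_px = as.integer(panel_lean_px),
    offset_m_px = offset_m_px,
    seed = as.integer(seed)
  ), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  g <- scene_geometry(cfg)
  if (g$r_top < 2 || g$r_B > cfg$height_px - 1) {
    stopf("panel does not fit vertically: rows %d..%d in image of height %d",
          g$r_top, g$r_B, cfg$height_px)
  }
  left_most <- g$c_L - cfg$corner_overhang_px - cfg$panel_lean_px
  if (left_most <= cfg$trunk_band[1] || g$c_R >= cfg$trunk_band[2]) {
    stopf("panel does not fit inside the trunk band [%d, %d]",
          cfg$trunk_band[1], cfg$trunk_band[2])
  }
  if (cfg$trunk_band[1] < 1 || cfg$trunk_band[2] > cfg$width_px) {
    stopf("trunk band exceeds image bounds")
  }
  # side-edge sampling reaches 60 rows above the line start; the panel's
  # side edges must extend at least that far
  if (cfg$panel_height_px < 66) stopf("`panel_height_px` must be >= 66")
  invisible(cfg)
}

# Analytic corner/edge geometry shared by rendering and ground truth.
scene_geometry <- function(cfg) {
  tanb <- tan(cfg$panel_tilt_deg * pi / 180)
  w <- cfg$panel_width_px
  h <- cfg$panel_height_px
  rowspan <- round(w * tanb)
  c_mid <- round(mean(cfg$trunk_band))
  c_L <- c_mid - w %/% 2
  c_R <- c_L + w
  margin_bottom <- max(10, cfg$height_px %/% 20)
  r_B <- cfg$height_px - margin_bottom
  r_C <- r_B - rowspan
  r_top <- r_C - h
  list(r_B = r_B, r_C = r_C, r_top = r_top, c_L = c_L, c_R = c_R,
       rowspan = rowspan)
}

# Column of the (analytic) left edge at row r, for rows r_top..r_C-1.
left_edge_col <- function(cfg, g, r) {
  jog <- g$c_L - cfg$corner_overhang_px
  span <- (g$r_C - 1) - g$r_top
  jog - cfg$panel_lean_px * ((g$r_C - 1) - r) / span
}

# Downward unit vector of the centre line F2 -> F1 (analytic counterpart of
# the midpoint construction on the rasterized edges).
centre_direction <- function(cfg, g, row_offsets = c(30, 60)) {
  d1 <- c(g$r_C - row_offsets[1], left_edge_col(cfg, g, g$r_C - row_offsets[1]))
  d2 <- c(g$r_C - row_offsets[2], left_edge_col(cfg, g, g$r_C - row_offsets[2]))
  e1 <- c(g$r_B - row_offsets[1], g$c_R)
  e2 <- c(g$r_B - row_offsets[2], g$c_R)
  f1 <- (d1 + e1) / 2
  f2 <- (d2 + e2) / 2
  v <- f1 - f2
  v / sqrt(sum(v^2))
}

#' Generate one synthetic trunk/panel scene
#'
#' @param config A [scene_config()].
#' @return An object of class `synthetic_sample` with elements `image`
#'   (H x W x 3 array, 0-255), `mask` (H x W, 0/255), `gt_existing_line` and
#'   `gt_new_line` (matrices with columns `r`, `c`, ordered from the line end
#'   `B1` at the bottom to the start `C1` at the top), `gt_box`
#'   (`c_min, r_min, c_max, r_max`), `annotation` (polygon vertices, `(r, c)`)
#'   and `config_used`.
#' @export
generate_sample <- function(config) {
  cfg <- validate_scene_config(config)
  g <- scene_geometry(cfg)

  poly <- rbind(
    B  = c(g$r_B, g$c_R),
    C  = c(g$r_C, g$c_L),
    J  = c(g$r_C - 1, g$c_L - cfg$corner_overhang_px),
    TL = c(g$r_top, g$c_L - cfg$corner_overhang_px - cfg$panel_lean_px),
    # top edge parallel to the tapping line
    TR = c(g$r_top + g$rowspan, g$c_R)
  )
  mask <- rasterize_polygon(poly, cfg$height_px, cfg$width_px)

  # existing tapping line: one point per integer row from B up to C
  # (per integer column for the degenerate horizontal case); pixel-centre
  # rasterization can leave the exact apex row empty, so the line is
  # clipped to the realized bottom row of the mask
  r_bottom <- max(which(rowSums(mask) > 0))
  r_bottom <- min(r_bottom, g$r_B)
  if (g$r_B > g$r_C) {
    rs <- r_bottom:g$r_C
    cs <- g$c_L + (rs - g$r_C) * (g$c_R - g$c_L) / (g$r_B - g$r_C)
  } else {
    cs <- g$c_R:g$c_L
    rs <- rep(r_bottom, length(cs))
  }
  gt_existing <- cbind(r = rs, c = cs)
  u <- centre_direction(cfg, g)
  gt_new <- cbind(r = rs + cfg$offset_m_px * u[1],
                  c = cs + cfg$offset_m_px * u[2])

  image <- with_seed(cfg$seed, render_scene(cfg, g, mask, gt_existing))

  structure(list(
    image = image, mask = ifelse(mask, 255L, 0L),
    gt_existing_line = gt_existing, gt_new_line = gt_new,
    gt_box = mask_bbox(mask),
    annotation = poly,
    centre_direction = u,
    config_used = cfg
  ), class = "synthetic_sample")
}

# Render the RGB raster for a scene (called inside with_seed()).
render_scene <- function(cfg, g, mask, line_pts) {
  H <- cfg$height_px; W <- cfg$width_px
  img <- array(0, dim = c(H, W, 3))
  # forest background
  base_bg <- c(72, 86, 62)
  # bark with vertical streak texture
  bark <- c(112, 92, 74)
  streak <- 12 * sin(seq_len(W) / 3.5) + stats::rnorm(W, 0, 4)
  in_band <- seq_len(W) >= cfg$trunk_band[1] & seq_len(W) <= cfg$trunk_band[2]
  for (ch in 1:3) {
    lay <- matrix(base_bg[ch], H, W)
    lay[, in_band] <- bark[ch] + rep(streak[in_band], each = H)
    img[, , ch] <- lay
  }
  # exposed panel wood
  panel_col <- c(186, 150, 112)
  for (ch in 1:3) {
    lay <- img[, , ch]
    lay[mask] <- panel_col[ch] + stats::rnorm(sum(mask), 0, 3)
    img[, , ch] <- lay
  }
  # dark groove of the existing cut, drawn just below the boundary so the
  # mask itself is untouched by rendering choices
  groove <- c(58, 44, 34)
  for (t in seq_len(cfg$line_thickness_px)) {
    rr <- round(line_pts[, "r"]) + t
    cc <- round(line_pts[, "c"])
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    idx <- cbind(rr[ok], cc[ok])
    for (ch in 1:3) {
      lay <- img[, , ch]
      lay[idx] <- groove[ch]
      img[, , ch] <- lay
    }
  }
  # illumination
  if (cfg$illumination_mode == "direct_sun") {
    ctr_r <- mean(range(which(rowSums(mask) > 0)))
    ctr_c <- mean(range(which(colSums(mask) > 0)))
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    blob <- exp(-(((rr - ctr_r) / (0.5 * H))^2 + ((cc - ctr_c) / (0.3 * W))^2))
    img <- img + 35 + array(95 * blob, dim = dim(img))
  } else if (cfg$illumination_mode == "backlight") {
    img <- img * 0.45 + 18
  }
  if (cfg$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, cfg$noise_sd), dim = dim(img))
  }
  round(clamp(img, 0, 255))
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cfg <- x$config_used
  cat(sprintf(
    "<synthetic_sample> %dx%d, tilt %.1f deg, panel %dx%d, %s, seed %d\n",
    cfg$height_px, cfg$width_px, cfg$panel_tilt_deg, cfg$panel_width_px,
    cfg$panel_height_px, cfg$illumination_mode, cfg$seed))
  cat(sprintf("  tapped area: %d px, box [(%d,%d),(%d,%d)]\n",
              sum(x$mask > 0), x$gt_box["c_min"], x$gt_box["r_min"],
              x$gt_box["c_max"], x$gt_box["r_max"]))
  invisible(x)
}

#' @export
plot.synthetic_sample <- function(x, ...) {
  img <- x$image / 255
  grDevices::dev.hold()
  on.exit(grDevices::dev.flush())
  plot(c(1, ncol(x$mask)), c(1, nrow(x$mask)), type = "n", asp = 1,
       xlab = "column", ylab = "row", ylim = c(nrow(x$mask), 1), ...)
  graphics::rasterImage(img, 1, nrow(x$mask), ncol(x$mask), 1)
  graphics::lines(x$gt_existing_line[, "c"], x$gt_existing_line[, "r"],
                  col = "red", lwd = 2)
  graphics::lines(x$gt_new_line[, "c"], x$gt_new_line[, "r"],
                  col = "cyan", lwd = 2)
  invisible(x)
}

#' Generate a reproducible dataset of synthetic scenes
#'
#' Per-sample seeds derive from the master seed, so the dataset is fully
#' reproducible. When `config` is `NULL`, scene parameters are drawn per
#' sample: tilt uniform over `tilt_range`, illumination uniform over `modes`,
#' and panel size from the years-of-cutting classes (1/2/3 years give side
#' heights 140/180/220 px).
#'
#' @param n Number of samples (>= 1).
#' @param config Optional fixed [scene_config()] reused for every sample
#'   (only the seed varies).
#' @param seed Master seed.
#' @param tilt_range Tilt bounds in degrees, used when `config` is `NULL`.
#' @param modes Illumination modes to draw from.
#' @param years Panel-age classes to draw from.
#' @param out_dir Optional directory; when given, writes per-sample
#'   `image_###.png`, `mask_###.png`, `ann_###.json` and `manifest.csv`.
#' @return List with elements `samples` (list of `synthetic_sample`) and
#'   `manifest` (data.frame).
#' @export
make_dataset <- function(n, config = NULL, seed = 1L,
                         tilt_range = c(10, 50),
                         modes = c("cloudy", "direct_sun", "backlight"),
                         years = 1:3,
                         out_dir = NULL) {
  if (!is_count(n) || n < 1) stopf("`n` must be a positive integer")
  seeds <- derive_seeds(seed, n)
  draw <- with_seed(seed, list(
    tilt = stats::runif(n, tilt_range[1], tilt_range[2]),
    mode = sample(modes, n, replace = TRUE),
    year = sample(years, n, replace = TRUE)
  ))
  heights <- c(140L, 180L, 220L)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- if (is.null(config)) {
      scene_config(panel_tilt_deg = draw$tilt[i],
                   panel_height_px = heights[draw$year[i]],
                   illumination_mode = draw$mode[i],
                   seed = seeds[i])
    } else {
      cfg_i <- config
      cfg_i$seed <- seeds[i]
      validate_scene_config(cfg_i)
    }
    s <- generate_sample(cfg)
    samples[[i]] <- s
    rows[[i]] <- data.frame(
      id = sprintf("sample_%03d", i), seed = cfg$seed,
      panel_tilt_deg = cfg$panel_tilt_deg,
      panel_width_px = cfg$panel_width_px,
      panel_height_px = cfg$panel_height_px,
      illumination_mode = cfg$illumination_mode,
      year = if (is.null(config)) draw$year[i] else NA_integer_,
      c_min = s$gt_box["c_min"], r_min = s$gt_box["r_min"],
      c_max = s$gt_box["c_max"], r_max = s$gt_box["r_max"],
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      s <- samples[[i]]
      write_image_png(s$image, file.path(out_dir, sprintf("image_%03d.png", i)))
      write_mask_png(s$mask, file.path(out_dir, sprintf("mask_%03d.png", i)))
      export_labelme(s, file.path(out_dir, sprintf("ann_%03d.json", i)))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Export a sample's annotation as a Labelme-style JSON file
#'
#' Points are written `[x, y] = [col, row]`, 0-based, matching the on-disk
#' convention of Labelme polygons.
#'
#' @param sample A `synthetic_sample` (or any list with `mask`, `annotation`
#'   and image dimensions recoverable from `mask`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_labelme <- function(sample, path) {
  if (sum(sample$mask > 0) == 0) stopf("refusing to export an empty mask")
  pts <- lapply(seq_len(nrow(sample$annotation)), function(i) {
    c(sample$annotation[i, 2] - 1, sample$annotation[i, 1] - 1)  # (x, y)
  })
  obj <- list(
    version = "5.0.1",
    flags = stats::setNames(list(), character(0)),
    shapes = list(list(
      label = "tapped_area",
      points = pts,
      group_id = NULL,
      shape_type = "polygon",
      flags = stats::setNames(list(), character(0))
    )),
    imagePath = "image.png",
    imageHeight = nrow(sample$mask),
    imageWidth = ncol(sample$mask)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
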