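# Image and annotation I/O, resizing, augmentation, dataset splitting.
#
# Convention used everywhere in this package: rasters are indexed (r, c),
# 1-based, r increasing downwards. On-disk polygon points are [x, y] =
# [col, row], 0-based. Pixel values are 0-255 doubles/integers.

#' Read an 8-bit RGB PNG into an H x W x 3 array (0-255)
#' @param path PNG file path.
#' @return Numeric array `H x W x 3`.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' Write an H x W x 3 (or H x W) array of 0-255 values as PNG
#' @param image Array of pixel values in 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Read a binary mask PNG (any nonzero pixel is foreground)
#' @param path PNG file path.
#' @return Integer matrix of 0/255.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  ifelse(a > 0.5, 255L, 0L)
}

#' @rdname read_mask_png
#' @param mask 0/255 (or logical) matrix to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask != 0, 1, 0), path)
  invisible(path)
}

#' Bilinear image resize
#'
#' Half-pixel-centred sampling: output pixel centre `i` (1-based) maps to
#' source coordinate `(i - 0.5) * scale + 0.5`, the `align_corners = FALSE`
#' convention. Border samples clamp to the edge pixels.
#'
#' @param image Matrix or H x W x C array.
#' @param out_w,out_h Target width and height in pixels (>= 1).
#' @return Resized array with dimensions `out_h x out_w (x C)`.
#' @export
resize_bilinear <- function(image, out_w, out_h) {
  d <- dim(image)
  if (is.null(d) || any(d[1:2] < 1)) stopf("`image` must be a non-empty raster")
  if (out_w < 1 || out_h < 1) stopf("target size must be >= 1")
  H <- d[1]; W <- d[2]
  if (out_h == H && out_w == W) return(image)
  src_r <- (seq_len(out_h) - 0.5) * (H / out_h) + 0.5
  src_c <- (seq_len(out_w) - 0.5) * (W / out_w) + 0.5
  r0 <- clamp(floor(src_r), 1, H); r1 <- clamp(r0 + 1, 1, H)
  c0 <- clamp(floor(src_c), 1, W); c1 <- clamp(c0 + 1, 1, W)
  fr <- clamp(src_r - r0, 0, 1); fc <- clamp(src_c - c0, 0, 1)
  FC <- matrix(fc, out_h, out_w, byrow = TRUE)
  FR <- matrix(fr, out_h, out_w)
  resize_plane <- function(p) {
    top <- p[r0, c0, drop = FALSE] * (1 - FC) + p[r0, c1, drop = FALSE] * FC
    bot <- p[r1, c0, drop = FALSE] * (1 - FC) + p[r1, c1, drop = FALSE] * FC
    top * (1 - FR) + bot * FR
  }
  if (length(d) == 2) return(resize_plane(image))
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- resize_plane(image[, , ch])
  out
}

#' Randomly perturb brightness, colour, contrast and noise
#'
#' Each of the four perturbations is applied independently with its
#' configured probability; magnitudes are drawn uniformly from the given
#' ranges. Deterministic for a fixed seed. With all probabilities zero the
#' image is returned unchanged.
#'
#' @param image H x W x 3 array, 0-255.
#' @param seed Integer seed.
#' @param p Named probabilities `brightness`, `color`, `contrast`, `noise`.
#' @param brightness_range Additive gray-level shift bounds.
#' @param color_range Per-channel multiplicative factor bounds.
#' @param contrast_range Contrast factor bounds (about the image mean).
#' @param noise_sd Gaussian noise standard deviation, gray levels.
#' @return Perturbed image, same shape, clipped to 0-255.
#' @export
augment <- function(image, seed = 1L,
                    p = c(brightness = 0.5, color = 0.5, contrast = 0.5,
                          noise = 0.5),
                    brightness_range = c(-40, 40),
                    color_range = c(0.8, 1.2),
                    contrast_range = c(0.7, 1.3),
                    noise_sd = 8) {
  d <- dim(image)
  with_seed(seed, {
    out <- image
    if (stats::runif(1) < p[["brightness"]]) {
      out <- out + stats::runif(1, brightness_range[1], brightness_range[2])
    }
    if (stats::runif(1) < p[["color"]]) {
      f <- stats::runif(3, color_range[1], color_range[2])
      for (ch in 1:3) out[, , ch] <- out[, , ch] * f[ch]
    }
    if (stats::runif(1) < p[["contrast"]]) {
      f <- stats::runif(1, contrast_range[1], contrast_range[2])
      mu <- mean(out)
      out <- (out - mu) * f + mu
    }
    if (stats::runif(1) < p[["noise"]]) {
      out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim = d)
    }
    clamp(out, 0, 255)
  })
}

#' Parse a Labelme-style polygon annotation
#'
#' Reads the JSON, keeps shapes whose label matches `label`, rasterizes the
#' polygons by the even-odd rule and returns the mask with its tight bounding
#' box.
#'
#' @param json_path Path to the annotation file.
#' @param label Class label of the tapped area.
#' @return List with `polygons` (list of `(r, c)` vertex matrices, 1-based),
#'   `mask` (logical matrix), `box` (`c_min, r_min, c_max, r_max`) and
#'   `image_size` (`c(H, W)`).
#' @export
parse_labelme <- function(json_path, label = "tapped_area") {
  if (!file.exists(json_path)) stopf("no such file: %s", json_path)
  obj <- tryCatch(jsonlite::fromJSON(json_path, simplifyVector = FALSE),
                  error = function(e) stopf("malformed JSON: %s", conditionMessage(e)))
  H <- obj$imageHeight; W <- obj$imageWidth
  if (is.null(H) || is.null(W)) stopf("annotation lacks image dimensions")
  shapes <- Filter(function(s) identical(s$label, label), obj$shapes)
  if (!length(shapes)) stopf("no '%s' polygon in %s", label, json_path)
  polys <- lapply(shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    if (nrow(pts) >= 2 && all(pts[1, ] == pts[nrow(pts), ])) {
      pts <- pts[-nrow(pts), , drop = FALSE]
    }
    if (nrow(pts) < 3) stopf("polygon with fewer than 3 vertices")
    cbind(r = pts[, 2] + 1, c = pts[, 1] + 1)  # [x,y] 0-based -> (r,c) 1-based
  })
  mask <- matrix(FALSE, H, W)
  for (p in polys) mask <- mask | rasterize_polygon(p, H, W)
  list(polygons = polys, mask = mask, box = mask_bbox(mask),
       image_size = c(H, W))
}

#' Random train/test split of sample ids
#'
#' @param n_total Total number of samples.
#' @param n_test Size of the test set (0 < n_test < n_total).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive, both sorted).
#' @export
split_dataset <- function(n_total, n_test, seed = 1L) {
  if (!is_count(n_total) || !is_count(n_test)) stopf("counts must be integers")
  if (n_test <= 0 || n_test >= n_total) {
    stopf("need 0 < n_test < n_total, got %d / %d", n_test, n_total)
  }
  test <- sort(with_seed(seed, sample.int(n_total, n_test)))
  list(train = setdiff(seq_len(n_total), test), test = test)
}
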