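# Shared fixtures, all built in code.

# A mid-size scene that is quick to process.
test_scene <- function(seed = 1L, tilt = 25, mode = "cloudy", h = 180, ...) {
  scene_config(seed = seed, panel_tilt_deg = tilt, illumination_mode = mode,
               panel_height_px = h, ...)
}

# Rectangle outline as a logical edge map: rows r0..r1, cols c0..c1.
rect_outline <- function(H, W, r0, c0, r1, c1) {
  e <- matrix(FALSE, H, W)
  e[r0:r1, c(c0, c1)] <- TRUE
  e[c(r0, r1), c0:c1] <- TRUE
  e
}

# Filled rectangle mask (0/255).
rect_mask <- function(H, W, r0, c0, r1, c1) {
  m <- matrix(0L, H, W)
  m[r0:r1, c0:c1] <- 255L
  m
}

# Ground-truth new-line bounding rectangle of a synthetic sample.
gt_new_box <- function(s) {
  c(c_min = min(s$gt_new_line[, "c"]), r_min = min(s$gt_new_line[, "r"]),
    c_max = max(s$gt_new_line[, "c"]), r_max = max(s$gt_new_line[, "r"]))
}

# Distance from points to a polyline (true point-to-segment distance; the
# ground-truth vertices are sampled per row, so nearest-vertex distance
# would overstate the error for shallow lines).
line_dists <- function(pts, gt) {
  a <- gt[-nrow(gt), c("r", "c"), drop = FALSE]
  b <- gt[-1, c("r", "c"), drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), 1e-12)
  apply(pts[, c("r", "c"), drop = FALSE], 1, function(p) {
    t <- pmin(pmax(((p[1] - a[, 1]) * ab[, 1] + (p[2] - a[, 2]) * ab[, 2]) /
                     len2, 0), 1)
    min(sqrt((a[, 1] + t * ab[, 1] - p[1])^2 +
               (a[, 2] + t * ab[, 2] - p[2])^2))
  })
}

mean_line_dist <- function(Q2, gt) mean(line_dists(Q2, gt))

# Independent flood-fill hysteresis oracle: iterative dilation to fixpoint.
hysteresis_oracle <- function(thinned, t_low, t_high) {
  strong <- thinned >= t_high & thinned > 0
  cand <- thinned >= t_low & thinned > 0
  keep <- strong
  H <- nrow(keep); W <- ncol(keep)
  repeat {
    grown <- keep
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        src_r <- max(1, 1 - dr):min(H, H - dr)
        src_c <- max(1, 1 - dc):min(W, W - dc)
        shifted <- matrix(FALSE, H, W)
        shifted[src_r + dr, src_c + dc] <- keep[src_r, src_c]
        grown <- grown | (shifted & cand)
      }
    }
    if (identical(grown, keep)) break
    keep <- grown
  }
  keep
}

# Per-pixel loop oracle for the 2x2 gradient operators.
gradient_oracle <- function(P) {
  H <- nrow(P); W <- ncol(P)
  Gx <- matrix(0, H - 1, W - 1); Gy <- matrix(0, H - 1, W - 1)
  for (r in seq_len(H - 1)) {
    for (c in seq_len(W - 1)) {
      Gx[r, c] <- (P[r, c + 1] - P[r, c] + P[r + 1, c + 1] - P[r + 1, c]) / 2
      Gy[r, c] <- (P[r, c] - P[r + 1, c] + P[r, c + 1] - P[r + 1, c + 1]) / 2
    }
  }
  list(Gx = Gx, Gy = Gy, S = sqrt(Gx^2 + Gy^2))
}
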