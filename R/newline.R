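# Position calculation of the new tapping line.
#
# Side edge points are sampled 30 and 60 rows above the line start C1 (left
# edge, minimum column) and above the line end B1 (right edge, maximum
# column); their midpoints give the panel centre line F1F2. Every point of
# the existing line is displaced by the bark consumption m along the downward
# centre-line direction, and the displaced points are smoothed with a cubic
# polynomial fitted by least squares (row as a polynomial in column).

#' Side-edge sample points above the line endpoints
#'
#' @param edges An `edge_map` or logical matrix.
#' @param C1,B1 Line start/end points `(r, c)` from the existing line.
#' @param row_offsets Rows above `C1`/`B1` to sample (default `c(30, 60)`;
#'   scale them down for panels shorter than 60 rows above the line).
#' @return List with `(r, c)` points `D1`, `D2` (left edge) and `E1`, `E2`
#'   (right edge).
#' @export
side_edges <- function(edges, C1, B1, row_offsets = c(30, 60)) {
  e <- if (inherits(edges, "edge_map")) edges$edges else edges != 0
  row_pick <- function(r0, what) {
    # line coordinates carry a half-pixel offset relative to the edge
    # raster; allow one row of rasterization jitter before giving up
    for (r in floor(r0) + c(0L, 1L, -1L)) {
      if (r >= 1 && r <= nrow(e) && any(e[r, ])) {
        cols <- which(e[r, ])
        cc <- if (what == "min") min(cols) else max(cols)
        return(c(r = r + 0.5, c = cc + 0.5))
      }
    }
    stopf("panel too short: no edge pixel in row %d", floor(r0))
  }
  list(D1 = row_pick(C1[1] - row_offsets[1], "min"),
       D2 = row_pick(C1[1] - row_offsets[2], "min"),
       E1 = row_pick(B1[1] - row_offsets[1], "max"),
       E2 = row_pick(B1[1] - row_offsets[2], "max"))
}

#' Centre line of the panel's left and right edges
#'
#' `F1` and `F2` are the exact midpoints of `(D1, E1)` and `(D2, E2)`; the
#' direction is the unit vector from `F2` towards `F1`, i.e. pointing down
#' the trunk.
#'
#' @param points List from [side_edges()].
#' @return List with `F1`, `F2` and unit `direction` (`(dr, dc)`).
#' @export
center_line <- function(points) {
  F1 <- (points$D1 + points$E1) / 2
  F2 <- (points$D2 + points$E2) / 2
  v <- F1 - F2
  len <- sqrt(sum(v^2))
  if (len == 0) stopf("degenerate centre line: F1 == F2")
  list(F1 = stats::setNames(F1, c("r", "c")),
       F2 = stats::setNames(F2, c("r", "c")),
       direction = stats::setNames(v / len, c("dr", "dc")))
}

#' Offset the existing line along the centre-line direction
#'
#' Each point moves exactly `m` pixels along the downward unit vector of the
#' centre line (of the two points at distance `m` on the centre-line
#' direction, the one with increasing row is taken).
#'
#' @param line An `existing_line` (or a point matrix with columns `r`, `c`).
#' @param center A [center_line()] result.
#' @param m Bark consumption in pixels (default 8).
#' @return Matrix of raw new-line points `Q1` (columns `r`, `c`).
#' @export
offset_line <- function(line, center, m = 8) {
  if (m < 0) stopf("`m` must be >= 0")
  Q <- if (inherits(line, "existing_line")) line$points else as.matrix(line)
  u <- center$direction
  if (u[1] < 0) u <- -u  # downward root
  cbind(r = Q[, "r"] + m * u[1], c = Q[, "c"] + m * u[2])
}

#' Least-squares polynomial smoothing of the new tapping line
#'
#' Fits row as a degree-`degree` polynomial in column,
#' `r = sum_k a_k c^k`, via a QR least-squares solve of the Vandermonde
#' system (numerically stabler than forming the normal equations, whose
#' solution it equals), then samples the polynomial at every integer column
#' of the fitted span.
#'
#' @param Q1 Matrix of raw new-line points (columns `r`, `c`).
#' @param degree Polynomial degree (default 3, cubic).
#' @return List with `coefficients` (`a_0 .. a_degree`), `Q2` (matrix of
#'   smoothed points, exact values; `r_half` column holds rows rounded to
#'   half-pixel for rendering) and `residual_rms`.
#' @export
fit_cubic <- function(Q1, degree = 3) {
  cc <- Q1[, "c"]; rr <- Q1[, "r"]
  if (length(unique(cc)) < degree + 1) {
    stopf("need at least %d distinct columns to fit degree %d",
          degree + 1, degree)
  }
  # centre/scale the column for conditioning, then map coefficients back
  mu <- mean(cc); sc <- max(stats::sd(cc), 1e-12)
  z <- (cc - mu) / sc
  V <- outer(z, 0:degree, `^`)
  qrV <- qr(V)
  b <- qr.coef(qrV, rr)
  # expand p(z((c - mu)/sc)) back into monomial coefficients in c
  a <- rep(0, degree + 1)
  for (k in 0:degree) {
    # b_k * ((c - mu)/sc)^k contributes binomial terms
    for (j in 0:k) {
      a[j + 1] <- a[j + 1] +
        b[k + 1] * choose(k, j) * (-mu)^(k - j) / sc^k
    }
  }
  cols <- seq(ceiling(min(cc)), floor(max(cc)))
  fit_at <- function(x) drop(outer((x - mu) / sc, 0:degree, `^`) %*% b)
  rows <- fit_at(cols)
  res <- rr - fit_at(cc)
  list(coefficients = stats::setNames(a, paste0("a", 0:degree)),
       Q2 = cbind(r = rows, c = cols, r_half = round(rows * 2) / 2),
       residual_rms = sqrt(mean(res^2)))
}

#' Locate the new tapping line
#'
#' Full chain from a rough tapped-area mask (or an image plus detector) to
#' the smoothed new tapping line: edge detection, line extraction, side-edge
#' centre line, m-pixel offset, cubic smoothing.
#'
#' @param x Binary mask (matrix; geometric mode) or RGB image array
#'   (requires `model`).
#' @param model Optional detector model for image mode (see
#'   [run_detector()]).
#' @param m Bark consumption in pixels (default 8).
#' @param degree Smoothing polynomial degree (default 3).
#' @param row_offsets Side-edge sampling offsets (default `c(30, 60)`).
#' @param anchor_index,d_max Line-extraction parameters.
#' @param ... Further arguments to [mask_to_edges()].
#' @return Object of class `tapping_line_result`: the existing line (`Q`,
#'   `B1`, `C1`), raw offset points `Q1`, smoothed line `Q2` with
#'   `coefficients`, the new-line bounding rectangle `box_new`
#'   (`c_min, r_min, c_max, r_max`), and `diagnostics` (extremes, side
#'   points, centre line, per-stage timings in seconds).
#' @export
locate_new_line <- function(x, model = NULL, m = 8, degree = 3,
                            row_offsets = c(30, 60),
                            anchor_index = 50, d_max = 1.5, ...) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  if (length(dim(x)) == 3) {
    if (is.null(model)) stopf("image mode needs a detector `model`")
    inst <- run_detector(x, model)
    if (!length(inst)) stopf("stage detect: no tapped area found")
    mask <- inst[[1]]$mask
    timings["detect"] <- proc.time()[["elapsed"]] - t0
  } else {
    mask <- x
  }
  tick <- function() proc.time()[["elapsed"]]
  t1 <- tick()
  line <- tryCatch(
    extract_existing_line(mask, anchor_index = anchor_index, d_max = d_max, ...),
    error = function(e) stopf("stage extract_line: %s", conditionMessage(e)))
  timings["extract_line"] <- tick() - t1
  t2 <- tick()
  se <- tryCatch(side_edges(line$edges, line$C1, line$B1, row_offsets),
                 error = function(e) stopf("stage side_edges: %s",
                                           conditionMessage(e)))
  ctr <- center_line(se)
  Q1 <- offset_line(line, ctr, m)
  timings["offset"] <- tick() - t2
  t3 <- tick()
  fit <- fit_cubic(Q1, degree)
  timings["fit"] <- tick() - t3
  box_new <- c(c_min = min(fit$Q2[, "c"]), r_min = min(fit$Q2[, "r"]),
               c_max = max(fit$Q2[, "c"]), r_max = max(fit$Q2[, "r"]))
  structure(list(
    existing_line = line, Q1 = Q1, Q2 = fit$Q2,
    coefficients = fit$coefficients, m = m, degree = degree,
    box_new = box_new,
    diagnostics = list(A1 = line$A1, B1 = line$B1, C1 = line$C1,
                       side_points = se, center = ctr,
                       residual_rms = fit$residual_rms,
                       timings = timings)
  ), class = "tapping_line_result")
}

#' @export
print.tapping_line_result <- function(x, ...) {
  cat(sprintf("<tapping_line_result> m=%g px, degree %d\n", x$m, x$degree))
  cat(sprintf("  existing line: %d points, B1=(%.1f,%.1f) C1=(%.1f,%.1f)\n",
              x$existing_line$n_points,
              x$existing_line$B1[1], x$existing_line$B1[2],
              x$existing_line$C1[1], x$existing_line$C1[2]))
  a <- x$coefficients
  cat("  cubic coefficients:", paste(sprintf("%s=%.4g", names(a), a),
                                     collapse = ", "), "\n")
  cat(sprintf("  new line box: [(%.1f,%.1f),(%.1f,%.1f)]\n",
              x$box_new["c_min"], x$box_new["r_min"],
              x$box_new["c_max"], x$box_new["r_max"]))
  invisible(x)
}
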