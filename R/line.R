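# Fine segmentation of the existing tapping line from an edge map.
#
# The existing cut is the lower-left boundary of the tapped area. From the
# edge map we take the extreme points A1 (upper-left) and B1 (lower-right),
# trace the minimum-column edge pixel of every row from B1 up to A1, seed the
# first 50 trace points, then apply an angle filter (chord to the anchor must
# point into the up-left quadrant, 0 <= a <= pi/2) and a step-distance filter
# (consecutive steps <= 1.5 px; the first violation - e.g. the corner jog at
# the line start - terminates the line and defines C1).

#' Extreme points of an edge map
#'
#' `A1` is the edge pixel with minimum row (ties: minimum column); `B1` has
#' maximum row (ties: maximum column). The tie rule makes axis-aligned
#' rectangles yield their upper-left/lower-right corners.
#'
#' @param edges An `edge_map` or logical matrix.
#' @return List with integer `(r, c)` vectors `A1` and `B1`.
#' @export
extreme_points <- function(edges) {
  e <- if (inherits(edges, "edge_map")) edges$edges else edges != 0
  idx <- which(e, arr.ind = TRUE)
  if (!nrow(idx)) stopf("empty edge map")
  rmin <- min(idx[, 1])
  A1 <- c(rmin, min(idx[idx[, 1] == rmin, 2]))
  rmax <- max(idx[, 1])
  B1 <- c(rmax, max(idx[idx[, 1] == rmax, 2]))
  list(A1 = stats::setNames(A1, c("r", "c")),
       B1 = stats::setNames(B1, c("r", "c")))
}

#' Lower-left boundary trace
#'
#' Scans from `B1` towards `A1` along one image axis and emits the extreme
#' edge pixel of each scanline: per row the minimum column, or per column
#' the maximum row. Scanlines without edge pixels are skipped (the distance
#' filter later truncates across any resulting gap).
#'
#' The scan axis matters: one trace point per scanline is only 8-connected
#' along the line's dominant axis, and the step-distance constraint
#' (`d <= 1.5`) rejects anything less connected. `scan = "auto"` (default)
#' therefore scans per column when the `A1`-`B1` column span is at least the
#' row span (lines shallower than 45 degrees, the common panel shape with
#' aspect ratios 1-2) and per row otherwise.
#'
#' @param edges An `edge_map` or logical matrix.
#' @param A1,B1 Extreme points; computed with [extreme_points()] if missing.
#' @param scan `"auto"`, `"row"` (min column per row) or `"column"` (max row
#'   per column).
#' @return Matrix with columns `r`, `c`; first point is `B1`, scan
#'   coordinate strictly monotone towards `A1`.
#' @export
trace_lower_left <- function(edges, A1 = NULL, B1 = NULL,
                             scan = c("auto", "row", "column")) {
  scan <- match.arg(scan)
  e <- if (inherits(edges, "edge_map")) edges$edges else edges != 0
  if (is.null(A1) || is.null(B1)) {
    ex <- extreme_points(e)
    A1 <- ex$A1; B1 <- ex$B1
  }
  if (scan == "auto") {
    # A1..B1 spans include the panel sides, so this is only a coarse guess;
    # extract_existing_line() tries both axes and keeps the longer line.
    scan <- if (abs(B1[2] - A1[2]) >= abs(B1[1] - A1[1])) "column" else "row"
  }
  idx <- which(e, arr.ind = TRUE)
  if (scan == "row") {
    lines_seq <- B1[1]:A1[1]
    keep <- idx[, 1] >= min(lines_seq) & idx[, 1] <= max(lines_seq)
    idx <- idx[keep, , drop = FALSE]
    agg <- tapply(idx[, 2], idx[, 1], min)
    val <- rep(NA_integer_, length(lines_seq))
    val[match(as.integer(names(agg)), lines_seq)] <- as.integer(agg)
    ok <- !is.na(val)
    cbind(r = lines_seq[ok], c = val[ok])
  } else {
    lines_seq <- B1[2]:A1[2]
    keep <- idx[, 2] >= min(lines_seq) & idx[, 2] <= max(lines_seq)
    idx <- idx[keep, , drop = FALSE]
    agg <- tapply(idx[, 1], idx[, 2], max)
    val <- rep(NA_integer_, length(lines_seq))
    val[match(as.integer(names(agg)), lines_seq)] <- as.integer(agg)
    ok <- !is.na(val)
    cbind(r = val[ok], c = lines_seq[ok])
  }
}

#' Angle filter on the boundary trace
#'
#' The first `min(anchor_index, n)` trace points are pre-seeded; the anchor is
#' the trace point at that index and stays fixed. Each later point `P_next`
#' is kept iff the chord from the anchor to it makes an angle
#' `0 <= a <= pi/2` with the column axis, where
#' `a = atan2(r_anchor - r_next, c_anchor - c_next)`: measured from the
#' leftward column direction with "up" positive, matching the bottom-right to
#' upper-left trace direction.
#'
#' @param trace Matrix from [trace_lower_left()].
#' @param anchor_index Seed count (default 50; shorter traces use their
#'   length).
#' @param advancing Advance the anchor to each accepted point instead of
#'   keeping it fixed.
#' @param inclusive Treat `a = pi/2` exactly as passing (default TRUE).
#' @param convention `"unsigned"` (default) measures the angle between the
#'   chord and the column-axis line, `a = |atan2(dr, dc)|`, so the constraint
#'   keeps every chord pointing into the forward (leftward) half-plane and
#'   only discards backtracking chords. `"signed"` additionally requires the
#'   chord not to dip below the anchor (`a >= 0`), which is stricter than
#'   rasterized boundaries support.
#' @return List with `N` (kept points matrix), `anchor` (the `P_start`
#'   point) and `anchor_index`.
#' @export
filter_angle <- function(trace, anchor_index = 50, advancing = FALSE,
                         inclusive = TRUE,
                         convention = c("unsigned", "signed")) {
  convention <- match.arg(convention)
  n <- nrow(trace)
  if (is.null(n) || n < 2) stopf("trace needs at least 2 points")
  k <- min(anchor_index, n)
  keep <- logical(n)
  keep[seq_len(k)] <- TRUE
  anchor <- trace[k, ]
  hi <- pi / 2 + if (inclusive) 1e-12 else -1e-12
  if (k < n) {
    for (i in (k + 1):n) {
      a <- atan2(anchor[1] - trace[i, 1], anchor[2] - trace[i, 2])
      ok <- if (convention == "unsigned") abs(a) <= hi else (a >= 0 && a <= hi)
      if (ok) {
        keep[i] <- TRUE
        if (advancing) anchor <- trace[i, ]
      }
    }
  }
  list(N = trace[keep, , drop = FALSE], anchor = trace[k, ], anchor_index = k)
}

#' Step-distance filter: isolate the existing tapping line
#'
#' Walks the angle-filtered set from the anchor with an advancing current
#' point, appending while the consecutive Euclidean step is `<= d_max`; the
#' first violation (for instance the corner jog above the line start)
#' terminates the walk. The seeded points below the anchor are always part of
#' the line.
#'
#' @param N Point matrix from [filter_angle()] (component `N`).
#' @param anchor_index Index of the anchor within `N`.
#' @param d_max Maximum step distance (default 1.5; 8-connected steps are at
#'   most sqrt(2) ~ 1.414 and always pass).
#' @return Object of class `existing_line`: list with `points` (matrix `Q`,
#'   ordered from `B1` to `C1`), `B1` (line end), `C1` (line start) and
#'   `n_points`.
#' @export
filter_distance <- function(N, anchor_index = min(50, nrow(N)), d_max = 1.5) {
  n <- nrow(N)
  k <- min(anchor_index, n)
  keep <- seq_len(k)
  cur <- N[k, ]
  if (k < n) {
    for (i in (k + 1):n) {
      d <- sqrt(sum((N[i, ] - cur)^2))
      if (d > d_max) break
      keep <- c(keep, i)
      cur <- N[i, ]
    }
  }
  Q <- N[keep, , drop = FALSE]
  structure(list(points = Q,
                 B1 = Q[1, ], C1 = Q[nrow(Q), ],
                 n_points = nrow(Q)),
            class = "existing_line")
}

#' @export
print.existing_line <- function(x, ...) {
  cat(sprintf("<existing_line> %d points, B1=(%.1f,%.1f) C1=(%.1f,%.1f)\n",
              x$n_points, x$B1[1], x$B1[2], x$C1[1], x$C1[2]))
  invisible(x)
}

#' Extract the existing tapping line from a tapped-area mask
#'
#' Composition of the full fine-segmentation stage: edge detection on the
#' rough mask, extreme points, lower-left boundary trace, angle filter,
#' step-distance filter.
#'
#' @param mask Binary tapped-area mask (0/255 or logical).
#' @param anchor_index Seed count for the filters (default 50).
#' @param d_max Step-distance constraint (default 1.5).
#' @param scan Scan axis for [trace_lower_left()]; `"auto"` (default) runs
#'   the filter chain on both axes and keeps the longer recovered line (only
#'   a scan along the line's dominant axis yields 8-connected steps, so the
#'   wrong axis truncates at the anchor and loses).
#' @param ... Passed to [mask_to_edges()].
#' @return An `existing_line`; attribute-like elements `edges`, `trace` and
#'   `N` carry the intermediate stages for diagnostics.
#' @export
extract_existing_line <- function(mask, anchor_index = 50, d_max = 1.5,
                                  scan = "auto", ...) {
  em <- mask_to_edges(mask, ...)
  ex <- extreme_points(em)
  run <- function(axis) {
    tr <- trace_lower_left(em, ex$A1, ex$B1, scan = axis)
    fa <- filter_angle(tr, anchor_index)
    line <- filter_distance(fa$N, fa$anchor_index, d_max)
    # gradient cell (r, c) spans pixels (r..r+1, c..c+1): shift the emitted
    # geometry by half a pixel so line coordinates are unbiased estimates of
    # the true boundary position
    line$points <- line$points + 0.5
    line$B1 <- line$B1 + 0.5
    line$C1 <- line$C1 + 0.5
    line$A1 <- ex$A1 + 0.5
    line$edges <- em
    line$trace <- tr
    line$N <- fa$N
    line$scan <- axis
    line
  }
  if (scan != "auto") return(run(scan))
  cand_col <- run("column")
  cand_row <- run("row")
  if (cand_col$n_points >= cand_row$n_points) cand_col else cand_row
}
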