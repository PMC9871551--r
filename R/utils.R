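# Internal helpers shared across the pipeline.

#' @keywords internal
"_PACKAGE"

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global random state so seeded components never leak
#' randomness into (or absorb it from) the caller.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stopf("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Label connected components of a binary raster
#'
#' Breadth-first labelling over a logical matrix. Used by hysteresis edge
#' linking and by mask post-processing in the detector.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in first-encounter order.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else stopf("`connectivity` must be 4 or 8")
  nlab <- 0L
  idx_fg <- which(mask)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    frontier <- start
    lab[start] <- nlab
    while (length(frontier)) {
      r <- ((frontier - 1L) %% H) + 1L
      c <- ((frontier - 1L) %/% H) + 1L
      nxt <- integer(0)
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- c + dc[k]
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        if (!any(ok)) next
        id <- (cc[ok] - 1L) * H + rr[ok]
        id <- id[mask[id] & lab[id] == 0L]
        if (length(id)) {
          lab[id] <- nlab
          nxt <- c(nxt, id)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Rasterize a polygon by the even-odd rule
#'
#' A pixel belongs to the polygon if its centre lies inside under the even-odd
#' (crossing-number) rule. Vertices are given in image coordinates
#' `(r, c)`, 1-based.
#'
#' @param vertices Numeric matrix with columns `r`, `c` (>= 3 rows).
#' @param height,width Output raster size.
#' @return Logical matrix `height x width`.
#' @export
rasterize_polygon <- function(vertices, height, width) {
  v <- as.matrix(vertices)
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3) stopf("polygon needs at least 3 distinct vertices")
  out <- matrix(FALSE, height, width)
  vr <- v[, 1]; vc <- v[, 2]
  n <- length(vr)
  jj <- c(n, seq_len(n - 1L))
  for (r in seq_len(height)) {
    # edges crossing the horizontal scanline at row r (pixel centres)
    y <- r
    cross <- (vr > y) != (vr[jj] > y)
    if (!any(cross)) next
    i <- which(cross); j <- jj[i]
    xs <- vc[i] + (y - vr[i]) / (vr[j] - vr[i]) * (vc[j] - vc[i])
    xs <- sort(xs)
    # even-odd fill between successive crossings
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      c0 <- ceiling(xs[k]); c1 <- floor(xs[k + 1])
      # half-open handling at exact pixel-centre crossings
      if (xs[k + 1] == floor(xs[k + 1])) c1 <- xs[k + 1] - 1
      c0 <- max(1L, c0); c1 <- min(width, c1)
      if (c0 <= c1) out[r, c0:c1] <- TRUE
    }
  }
  out
}

# Tight bounding rectangle [(c_min, r_min), (c_max, r_max)] of a binary mask.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stopf("mask is empty")
  c(c_min = min(idx[, 2]), r_min = min(idx[, 1]),
    c_max = max(idx[, 2]), r_max = max(idx[, 1]))
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))
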