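# Edge detection on the rough tapped-area segmentation.
#
# The gradient operators are 2x2 averaged differences evaluated on each
# 2x2 neighbourhood: with P(r, c) the gray value,
#
#   Gx(r, c) = (P(r, c+1) - P(r, c) + P(r+1, c+1) - P(r+1, c)) / 2
#   Gy(r, c) = (P(r, c)   - P(r+1, c) + P(r, c+1) - P(r+1, c+1)) / 2
#
# so Gx measures change along columns and Gy the (negated) change along
# rows; S = sqrt(Gx^2 + Gy^2), theta = atan2(Gy, Gx). The gradient grid has
# size (H-1) x (W-1); entry (r, c) sits at the top-left pixel of its
# neighbourhood.

#' Gaussian smoothing
#'
#' Separable Gaussian filter with replicate (edge-clamp) padding.
#'
#' @param image Numeric matrix.
#' @param size Odd kernel size (default 5).
#' @param sigma Standard deviation in pixels (default 1.4).
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(image, size = 5, sigma = 1.4) {
  if (size %% 2 != 1) stopf("`size` must be odd")
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(image); W <- ncol(image)
  ridx <- clamp(outer(seq_len(H), (-half):half, `+`), 1, H)
  out <- matrix(0, H, W)
  for (j in seq_len(size)) out <- out + image[ridx[, j], ] * k[j]
  cidx <- clamp(outer(seq_len(W), (-half):half, `+`), 1, W)
  out2 <- matrix(0, H, W)
  for (j in seq_len(size)) out2 <- out2 + out[, cidx[, j]] * k[j]
  out2
}

#' 2x2 averaged-difference gradient field
#'
#' @param P Grayscale matrix (at least 2x2).
#' @return Object of class `gradient_field`: list of `(H-1) x (W-1)` matrices
#'   `Gx`, `Gy`, `S` (magnitude) and `theta` (radians, `atan2(Gy, Gx)`,
#'   full -pi..pi range).
#' @export
gradient_2x2 <- function(P) {
  H <- nrow(P); W <- ncol(P)
  if (is.null(H) || H < 2 || W < 2) {
    stopf("gradient needs at least a 2x2 image")
  }
  tl <- P[-H, -W, drop = FALSE]; tr <- P[-H, -1, drop = FALSE]
  bl <- P[-1, -W, drop = FALSE]; br <- P[-1, -1, drop = FALSE]
  Gx <- (tr - tl + br - bl) / 2
  Gy <- (tl - bl + tr - br) / 2
  S <- sqrt(Gx^2 + Gy^2)
  structure(list(Gx = Gx, Gy = Gy, S = S, theta = atan2(Gy, Gx)),
            class = "gradient_field")
}

# Quantize gradient angles into 4 direction bins and return the (dr, dc)
# steps towards the two neighbours along the gradient. Gx points along +c,
# Gy along -r.
direction_bins <- function(theta) {
  a <- theta %% pi  # direction is sign-free
  bin <- integer(length(a))
  bin[a < pi / 8 | a >= 7 * pi / 8] <- 0L        # horizontal gradient
  bin[a >= pi / 8 & a < 3 * pi / 8] <- 1L        # 45 deg (up-right)
  bin[a >= 3 * pi / 8 & a < 5 * pi / 8] <- 2L    # vertical
  bin[a >= 5 * pi / 8 & a < 7 * pi / 8] <- 3L    # 135 deg (down-right)
  bin
}

#' Non-maximum suppression of a gradient field
#'
#' A pixel survives iff its magnitude is >= both neighbours along the
#' quantized gradient direction (4 bins of 45 degrees), with the tie on the
#' forward neighbour broken strictly (a plateau of equal magnitudes keeps
#' one pixel, not the whole plateau, so ridges thin to one pixel). Missing
#' neighbours at the border count as 0.
#'
#' @param field A [gradient_2x2()] result.
#' @return Matrix of suppressed magnitudes (0 where suppressed).
#' @export
nonmax_suppress <- function(field) {
  S <- field$S
  H <- nrow(S); W <- ncol(S)
  bin <- matrix(direction_bins(field$theta), H, W)
  # padded magnitude for cheap neighbour lookup
  Sp <- matrix(0, H + 2, W + 2)
  Sp[2:(H + 1), 2:(W + 1)] <- S
  nb <- function(dr, dc) Sp[(2:(H + 1)) + dr, (2:(W + 1)) + dc]
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  steps <- list(`0` = c(0L, 1L),   # horizontal gradient: left/right
                `1` = c(-1L, 1L),  # gradient up-right: anti-diagonal
                `2` = c(1L, 0L),   # vertical gradient: up/down
                `3` = c(1L, 1L))   # gradient down-right: main diagonal
  for (b in 0:3) {
    sel <- bin == b
    if (!any(sel)) next
    st <- steps[[as.character(b)]]
    a1 <- nb(st[1], st[2]); a2 <- nb(-st[1], -st[2])
    n1[sel] <- a1[sel]; n2[sel] <- a2[sel]
  }
  keep <- S > n1 & S >= n2 & S > 0
  out <- matrix(0, H, W)
  out[keep] <- S[keep]
  out
}

#' Double-threshold hysteresis edge linking
#'
#' Pixels >= `t_high` are strong and always kept; pixels in
#' `[t_low, t_high)` are weak and kept iff 8-connected (transitively) to a
#' strong pixel.
#'
#' @param thinned Suppressed magnitude matrix.
#' @param t_low,t_high Thresholds, `0 <= t_low <= t_high`.
#' @return Object of class `edge_map`: list with logical matrix `edges` and
#'   the thresholds used.
#' @export
hysteresis <- function(thinned, t_low, t_high) {
  if (t_low > t_high) stopf("`t_low` must be <= `t_high`")
  if (t_low < 0) stopf("thresholds must be non-negative")
  strong <- thinned >= t_high & thinned > 0
  cand <- thinned >= t_low & thinned > 0
  if (any(strong)) {
    lab <- label_components(cand, connectivity = 8)
    keep_labels <- unique(lab[strong])
    edges <- matrix(lab %in% keep_labels & cand, nrow(thinned), ncol(thinned))
  } else {
    edges <- matrix(FALSE, nrow(thinned), ncol(thinned))
  }
  structure(list(edges = edges, t_low = t_low, t_high = t_high),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %dx%d, %d edge pixels (t_low=%g, t_high=%g)\n",
              nrow(x$edges), ncol(x$edges), sum(x$edges), x$t_low, x$t_high))
  invisible(x)
}

# Luma grayscale conversion of an H x W x 3 array.
to_gray <- function(image) {
  if (length(dim(image)) == 2) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# Otsu threshold of positive values (used to scale hysteresis thresholds for
# grayscale inputs).
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  h <- hist(x, breaks = 64, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Remove redundant staircase pixels from an edge map
#'
#' Quantized-direction suppression leaves stair doublets on arcs near the
#' direction-bin boundaries. A pixel is redundant (a "simple point" of the
#' curve) when it has at least two edge neighbours and the edge pixels of
#' its 8-neighbourhood remain mutually 8-connected without it; removing such
#' pixels sequentially restores 1-px thinness while preserving connectivity
#' and endpoints. Applied until stable.
#'
#' @param edges Logical matrix.
#' @return Thinned logical matrix.
#' @export
thin_edges <- function(edges) {
  H <- nrow(edges); W <- ncol(edges)
  e <- matrix(FALSE, H + 2, W + 2)
  e[2:(H + 1), 2:(W + 1)] <- edges
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  neighbours_connected <- function(pos) {
    n <- nrow(pos)
    if (n < 2) return(TRUE)
    seen <- logical(n)
    stack <- 1L
    seen[1] <- TRUE
    while (length(stack)) {
      i <- stack[[1]]; stack <- stack[-1]
      adj <- which(!seen &
                     pmax(abs(pos[, 1] - pos[i, 1]),
                          abs(pos[, 2] - pos[i, 2])) <= 1)
      seen[adj] <- TRUE
      stack <- c(stack, adj)
    }
    all(seen)
  }
  repeat {
    changed <- FALSE
    idx <- which(e, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      if (!e[r, c]) next
      nb_pos <- offs + matrix(c(r, c), 8, 2, byrow = TRUE)
      on <- e[nb_pos]
      if (sum(on) < 2) next
      if (neighbours_connected(nb_pos[on, , drop = FALSE])) {
        e[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  e[2:(H + 1), 2:(W + 1)]
}

#' Edge map of a tapped-area mask
#'
#' Full composition of the edge stage: grayscale conversion, Gaussian
#' smoothing, 2x2 gradients, non-maximum suppression, hysteresis.
#'
#' @param mask Binary mask (0/255 or logical), or an RGB crop when
#'   `input = "gray"`.
#' @param t_low,t_high Hysteresis thresholds. Defaults 30/60 suit 0/255
#'   masks: Gaussian smoothing spreads the 255 step over several pixels, so
#'   the peak gradient magnitude is about 70, and any pair below that works.
#'   With `input = "gray"` thresholds default to Otsu-scaled values of the
#'   magnitude field.
#' @param input `"mask"` (default) treats the input as the binary rough
#'   segmentation; `"gray"` treats it as a grayscale/RGB image.
#' @param smooth_size,smooth_sigma Gaussian kernel parameters.
#' @return An `edge_map` whose `edges` matrix has size `(H-1) x (W-1)`.
#' @export
mask_to_edges <- function(mask, t_low = 30, t_high = 60,
                          input = c("mask", "gray"),
                          smooth_size = 5, smooth_sigma = 1.4) {
  input <- match.arg(input)
  if (input == "mask") {
    m <- if (length(dim(mask)) == 3) to_gray(mask) else mask
    if (sum(m != 0) == 0) stopf("no tapped area: mask is empty")
    g <- ifelse(m != 0, 255, 0)
  } else {
    g <- to_gray(mask)
  }
  sm <- gaussian_smooth(g, smooth_size, smooth_sigma)
  field <- gradient_2x2(sm)
  thin <- nonmax_suppress(field)
  if (input == "gray") {
    t0 <- otsu_threshold(thin[thin > 0])
    t_high <- t0
    t_low <- t0 / 2
  }
  em <- hysteresis(thin, t_low, t_high)
  em$edges <- thin_edges(em$edges)
  em$field <- field
  em
}
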