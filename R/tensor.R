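# Minimal feature-map operations on (C, H, W) arrays.
#
# These back the forward contracts of the architecture modules. Convolution
# uses im2col + BLAS matrix multiplication; weights are (C_out, C_in/groups,
# kh, kw) arrays. No batch axis: one image at a time.

# Zero-pad spatially.
pad_chw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * pad, d[3] + 2 * pad))
  out[, (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <- x
  out
}

#' 2-D convolution on a (C, H, W) feature map
#'
#' @param x Input array `(C_in, H, W)`.
#' @param w Weights `(C_out, C_in/groups, kh, kw)`.
#' @param b Bias vector of length `C_out` (default zeros).
#' @param stride,pad Stride and symmetric zero padding.
#' @param groups Grouped convolution: input and output channels are split
#'   into `groups` blocks convolved independently.
#' @return Array `(C_out, H_out, W_out)`.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, groups = 1) {
  dx <- dim(x); dw <- dim(w)
  cin <- dx[1]; cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  if (cin %% groups != 0 || cout %% groups != 0) {
    stopf("channels (%d in, %d out) not divisible by groups=%d",
          cin, cout, groups)
  }
  if (dw[2] != cin / groups) {
    stopf("weight expects %d input channels per group, got %d",
          dw[2], cin / groups)
  }
  xp <- pad_chw(x, pad)
  H <- dim(xp)[2]; W <- dim(xp)[3]
  Ho <- (H - kh) %/% stride + 1
  Wo <- (W - kw) %/% stride + 1
  if (Ho < 1 || Wo < 1) stopf("kernel larger than padded input")
  ri <- seq(1, by = stride, length.out = Ho)
  ci <- seq(1, by = stride, length.out = Wo)
  cg_in <- cin / groups; cg_out <- cout / groups
  if (is.null(b)) b <- rep(0, cout)
  out <- array(0, dim = c(cout, Ho, Wo))
  for (g in seq_len(groups)) {
    ch_in <- ((g - 1) * cg_in + 1):(g * cg_in)
    ch_out <- ((g - 1) * cg_out + 1):(g * cg_out)
    cols <- matrix(0, Ho * Wo, cg_in * kh * kw)
    q <- 0L
    for (ci_k in seq_len(cg_in)) {
      for (ki in seq_len(kh)) {
        for (kj in seq_len(kw)) {
          q <- q + 1L
          cols[, q] <- as.vector(xp[ch_in[ci_k], ri + ki - 1, ci + kj - 1])
        }
      }
    }
    wm <- matrix(0, cg_in * kh * kw, cg_out)
    for (oc in seq_len(cg_out)) {
      q <- 0L
      for (ci_k in seq_len(cg_in)) {
        for (ki in seq_len(kh)) {
          for (kj in seq_len(kw)) {
            q <- q + 1L
            wm[q, oc] <- w[ch_out[oc], ci_k, ki, kj]
          }
        }
      }
    }
    res <- cols %*% wm
    for (oc in seq_len(cg_out)) {
      out[ch_out[oc], , ] <- matrix(res[, oc], Ho, Wo) + b[ch_out[oc]]
    }
  }
  out
}

#' @rdname conv2d
#' @details `conv_transpose2` implements the 2x2, stride-2 transposed
#'   convolution used to upscale mask logits; `w` has shape
#'   `(C_in, C_out, 2, 2)`.
#' @export
conv_transpose2 <- function(x, w, b = NULL) {
  d <- dim(x); dw <- dim(w)
  cin <- d[1]; H <- d[2]; W <- d[3]; cout <- dw[2]
  if (dw[1] != cin) stopf("weight/input channel mismatch")
  if (is.null(b)) b <- rep(0, cout)
  X <- matrix(aperm(x, c(2, 3, 1)), H * W, cin)
  out <- array(0, dim = c(cout, 2 * H, 2 * W))
  for (a in 1:2) {
    for (bb in 1:2) {
      Wab <- matrix(w[, , a, bb], cin, cout)
      R <- X %*% Wab
      for (oc in seq_len(cout)) {
        out[oc, seq(a, 2 * H, by = 2), seq(bb, 2 * W, by = 2)] <-
          matrix(R[, oc], H, W)
      }
    }
  }
  if (any(b != 0)) out <- out + array(b, dim = dim(out))
  out
}

#' Max pooling with a k x k window
#' @param x `(C, H, W)` array.
#' @param k,stride Window size and stride (default 2/2).
#' @return Pooled array.
#' @export
maxpool2 <- function(x, k = 2, stride = 2) {
  d <- dim(x)
  Ho <- (d[2] - k) %/% stride + 1
  Wo <- (d[3] - k) %/% stride + 1
  out <- array(-Inf, dim = c(d[1], Ho, Wo))
  ri <- seq(1, by = stride, length.out = Ho)
  ci <- seq(1, by = stride, length.out = Wo)
  for (a in seq_len(k)) {
    for (bb in seq_len(k)) {
      out <- pmax(out, x[, ri + a - 1, ci + bb - 1, drop = FALSE])
    }
  }
  out
}

#' Nearest-neighbour 2x spatial upsampling
#' @param x `(C, H, W)` array.
#' @return `(C, 2H, 2W)` array.
#' @export
upsample_nearest2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), drop = FALSE]
}

relu <- function(x) pmax(x, 0)

# Global pools over the spatial axes -> length-C vectors.
global_maxpool <- function(x) apply(x, 1, max)
global_avgpool <- function(x) apply(x, 1, mean)

# Per-location max/mean over channels -> H x W matrices.
channel_max <- function(x) apply(x, c(2, 3), max)
channel_avg <- function(x) apply(x, c(2, 3), mean)

# Random weight array (uses the caller's RNG state).
rand_array <- function(..., sd = 0.05) {
  dims <- c(...)
  array(stats::rnorm(prod(dims), 0, sd), dim = dims)
}
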