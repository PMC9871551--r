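# Forward-contracted building blocks of the attention-augmented backbone:
# aggregated-residual (split-transform-merge) blocks, parallel channel +
# spatial attention, and feature-pyramid fusion. These are shape- and
# equation-contracted components, not a trained network.

#' Backbone configuration
#'
#' @param depth 50 or 101 (stage depths 3-4-6-3 vs 3-4-23-3).
#' @param cardinality Number of parallel transform branches per block
#'   (default 32).
#' @param cbam_enabled Attach the attention module after each enabled stage.
#' @param cbam_stages Stages carrying attention (subset of C2..C5).
#' @param fpn_channels Uniform pyramid channel width (default 256).
#' @param reduction Channel-attention MLP reduction ratio (default 16).
#' @param spatial_kernel Spatial-attention convolution kernel (default 7).
#' @return Object of class `backbone_config`.
#' @export
backbone_config <- function(depth = 50, cardinality = 32,
                            cbam_enabled = TRUE,
                            cbam_stages = c("C2", "C3", "C4", "C5"),
                            fpn_channels = 256, reduction = 16,
                            spatial_kernel = 7) {
  if (!depth %in% c(50, 101)) stopf("`depth` must be 50 or 101")
  if (cardinality < 1) stopf("`cardinality` must be >= 1")
  stopifnot(all(cbam_stages %in% c("C2", "C3", "C4", "C5")))
  structure(list(depth = depth, cardinality = cardinality,
                 cbam_enabled = cbam_enabled, cbam_stages = cbam_stages,
                 fpn_channels = fpn_channels, reduction = reduction,
                 spatial_kernel = spatial_kernel),
            class = "backbone_config")
}

#' Parameters for one aggregated-residual block
#'
#' Each of the `cardinality` branches is a 1x1 (reduce) - 3x3 - 1x1 (expand)
#' bottleneck of `branch_width` channels. The default branch width follows
#' the 32x4d family: total bottleneck width 128 * 2^(stage-1) split over the
#' branches, so 32 branches of width 4 at the first stage.
#'
#' @param in_channels Input (= output) channels of the block.
#' @param cardinality Branch count.
#' @param stage Stage index 1..4 (sets the default width).
#' @param branch_width Override the per-branch bottleneck width.
#' @param init `"zero"` or `"random"`.
#' @param seed Seed for random init.
#' @return List with `branches` (per-branch weight lists `w1`, `w3`, `w2`)
#'   and `branch_width`.
#' @export
resnext_block_params <- function(in_channels, cardinality = 32, stage = 1,
                                 branch_width = NULL,
                                 init = c("zero", "random"), seed = 1L) {
  init <- match.arg(init)
  if (is.null(branch_width)) {
    branch_width <- (128 * 2^(stage - 1)) %/% cardinality
    if (branch_width < 1) branch_width <- 1
  }
  make <- function() {
    if (init == "zero") {
      list(w1 = array(0, c(branch_width, in_channels, 1, 1)),
           w3 = array(0, c(branch_width, branch_width, 3, 3)),
           w2 = array(0, c(in_channels, branch_width, 1, 1)))
    } else {
      list(w1 = rand_array(branch_width, in_channels, 1, 1),
           w3 = rand_array(branch_width, branch_width, 3, 3),
           w2 = rand_array(in_channels, branch_width, 1, 1))
    }
  }
  with_seed(seed, list(branches = replicate(cardinality, make(),
                                            simplify = FALSE),
                       branch_width = branch_width,
                       in_channels = in_channels))
}

#' Aggregated-residual (split-transform-merge) block
#'
#' Computes `F_y = F_x + sum_i T_i(F_x)` over `cardinality` identical-shape
#' branches. `impl = "explicit"` evaluates every branch separately;
#' `impl = "grouped"` evaluates the equivalent grouped-convolution form
#' (concatenated 1x1 reduce, grouped 3x3, summing 1x1 expand). Both are exact
#' up to floating-point rounding.
#'
#' @param x Input `(C, H, W)` array.
#' @param params From [resnext_block_params()].
#' @param impl `"grouped"` or `"explicit"`.
#' @return Output array, same shape as `x`.
#' @export
resnext_block <- function(x, params, impl = c("grouped", "explicit")) {
  impl <- match.arg(impl)
  C <- dim(x)[1]
  if (C != params$in_channels) {
    stopf("block expects %d channels, got %d", params$in_channels, C)
  }
  br <- params$branches
  c_card <- length(br)
  bw <- params$branch_width
  if (impl == "explicit") {
    acc <- array(0, dim = dim(x))
    for (i in seq_len(c_card)) {
      t1 <- relu(conv2d(x, br[[i]]$w1))
      t3 <- relu(conv2d(t1, br[[i]]$w3, pad = 1))
      acc <- acc + conv2d(t3, br[[i]]$w2)
    }
    return(x + acc)
  }
  # grouped form: stack branch weights
  w1 <- array(0, c(c_card * bw, C, 1, 1))
  w3 <- array(0, c(c_card * bw, bw, 3, 3))
  w2 <- array(0, c(C, c_card * bw, 1, 1))
  for (i in seq_len(c_card)) {
    rows <- ((i - 1) * bw + 1):(i * bw)
    w1[rows, , , ] <- br[[i]]$w1
    w3[rows, , , ] <- br[[i]]$w3
    w2[, rows, , ] <- br[[i]]$w2
  }
  t1 <- relu(conv2d(x, w1))
  t3 <- relu(conv2d(t1, w3, pad = 1, groups = c_card))
  x + conv2d(t3, w2)
}

#' Parameters for the parallel attention module
#'
#' @param channels Input channels `C`.
#' @param reduction MLP reduction ratio (hidden width `C / reduction`,
#'   minimum 1).
#' @param spatial_kernel Odd spatial-attention kernel size.
#' @param init `"random"`, `"zero"`, or `"saturate"` (biases large so both
#'   gates are 1 within machine precision).
#' @param seed Seed for random init.
#' @return List of weights: shared MLP `W1`, `W2`, biases `b1`, `b2`,
#'   spatial conv `w_s`, `b_s`.
#' @export
cbam_params <- function(channels, reduction = 16, spatial_kernel = 7,
                        init = c("random", "zero", "saturate"), seed = 1L) {
  init <- match.arg(init)
  hidden <- max(1L, channels %/% reduction)
  k <- spatial_kernel
  with_seed(seed, {
    if (init == "random") {
      list(W1 = matrix(stats::rnorm(hidden * channels, 0, 0.1), hidden, channels),
           b1 = rep(0, hidden),
           W2 = matrix(stats::rnorm(channels * hidden, 0, 0.1), channels, hidden),
           b2 = rep(0, channels),
           w_s = rand_array(1, 2, k, k, sd = 0.1), b_s = 0)
    } else if (init == "zero") {
      list(W1 = matrix(0, hidden, channels), b1 = rep(0, hidden),
           W2 = matrix(0, channels, hidden), b2 = rep(0, channels),
           w_s = array(0, c(1, 2, k, k)), b_s = 0)
    } else {
      list(W1 = matrix(0, hidden, channels), b1 = rep(0, hidden),
           W2 = matrix(0, channels, hidden), b2 = rep(40, channels),
           w_s = array(0, c(1, 2, k, k)), b_s = 40)
    }
  })
}

#' Parallel channel + spatial attention
#'
#' `F''' = M_C(F) (x) F + M_S(F) (x) F`: the channel gate
#' `M_C = sigmoid(MLP(maxpool(F)) + MLP(avgpool(F)))` (shared one-hidden-layer
#' MLP over the two global poolings) and the spatial gate
#' `M_S = sigmoid(conv([channel-max; channel-avg]))` each multiply the input
#' element-wise, and the two attended maps are combined by element-wise sum
#' (parallel form; no module ordering).
#'
#' @param x Input `(C, H, W)` array.
#' @param params From [cbam_params()].
#' @return List with `out` (`F'''`), `M_C` (length-C gate) and `M_S`
#'   (`H x W` gate).
#' @export
cbam_parallel <- function(x, params) {
  C <- dim(x)[1]
  mlp <- function(v) params$W2 %*% relu(params$W1 %*% v + params$b1) + params$b2
  M_C <- sigmoid(drop(mlp(global_maxpool(x)) + mlp(global_avgpool(x))))
  sp_in <- array(0, c(2, dim(x)[2], dim(x)[3]))
  sp_in[1, , ] <- channel_max(x)
  sp_in[2, , ] <- channel_avg(x)
  k <- dim(params$w_s)[3]
  M_S <- sigmoid(conv2d(sp_in, params$w_s, b = params$b_s,
                        pad = (k - 1) %/% 2)[1, , ])
  attended_c <- x * M_C  # M_C recycles along the channel (first) axis
  ms_arr <- array(rep(as.vector(M_S), each = C), dim = dim(x))
  attended_s <- x * ms_arr
  out <- attended_c + attended_s
  list(out = out, M_C = M_C, M_S = M_S)
}

#' Feature-pyramid parameters
#'
#' @param in_channels Integer vector: channels of D2..D5.
#' @param fpn_channels Pyramid width (default 256).
#' @param init `"zero"` or `"random"`.
#' @param seed Seed.
#' @return List of lateral 1x1 and output 3x3 conv weights.
#' @export
fpn_params <- function(in_channels, fpn_channels = 256,
                       init = c("random", "zero"), seed = 1L) {
  init <- match.arg(init)
  mk <- function(co, ci, k) {
    if (init == "zero") array(0, c(co, ci, k, k)) else
      rand_array(co, ci, k, k, sd = 0.02)
  }
  with_seed(seed, list(
    lateral = lapply(in_channels, function(ci) mk(fpn_channels, ci, 1)),
    output = lapply(1:4, function(i) mk(fpn_channels, fpn_channels, 3)),
    fpn_channels = fpn_channels
  ))
}

#' Top-down feature-pyramid fusion
#'
#' Builds `P5 = conv3x3(conv1x1(D5))`, then
#' `P_k = conv3x3(upsample2(P_{k+1}) + conv1x1(D_k))` for k = 4, 3, 2, and
#' `P6 = maxpool(P5, stride 2)`. Upsampling is nearest-neighbour x2. All
#' outputs have `fpn_channels` channels; with an input image of side `s` the
#' levels have strides 4, 8, 16, 32 and 64.
#'
#' @param D List of 4 feature maps `D2..D5` with halving spatial sizes.
#' @param params From [fpn_params()].
#' @return Named list `P2..P6`.
#' @export
build_fpn <- function(D, params) {
  if (length(D) != 4) stopf("expected 4 input levels D2..D5")
  for (i in 1:3) {
    if (!all(dim(D[[i]])[2:3] == 2 * dim(D[[i + 1]])[2:3])) {
      stopf("input pyramid must halve spatially: level %d -> %d", i, i + 1)
    }
  }
  lat <- lapply(1:4, function(i) conv2d(D[[i]], params$lateral[[i]]))
  P5 <- conv2d(lat[[4]], params$output[[4]], pad = 1)
  P4 <- conv2d(upsample_nearest2(P5) + lat[[3]], params$output[[3]], pad = 1)
  P3 <- conv2d(upsample_nearest2(P4) + lat[[2]], params$output[[2]], pad = 1)
  P2 <- conv2d(upsample_nearest2(P3) + lat[[1]], params$output[[1]], pad = 1)
  P6 <- maxpool2(P5, k = 1, stride = 2)
  list(P2 = P2, P3 = P3, P4 = P4, P5 = P5, P6 = P6)
}

#' Analytic parameter count of the backbone
#'
#' Counts convolution/MLP weights of the stem, the four aggregated-residual
#' stages, the optional attention modules and the pyramid, so configurations
#' can be compared (attention adds parameters; depth 101 exceeds depth 50).
#' Batch-norm and bias terms are ignored.
#'
#' @param config A [backbone_config()].
#' @return Total parameter count (numeric).
#' @export
count_backbone_params <- function(config) {
  blocks <- if (config$depth == 50) c(3, 4, 6, 3) else c(3, 4, 23, 3)
  stage_out <- c(256, 512, 1024, 2048)
  stage_in <- c(64, 256, 512, 1024)
  widths <- 128 * 2^(0:3)
  total <- 7 * 7 * 3 * 64  # stem
  for (s in 1:4) {
    Wt <- widths[s]
    for (bk in seq_len(blocks[s])) {
      cin <- if (bk == 1) stage_in[s] else stage_out[s]
      total <- total + cin * Wt +                     # 1x1 reduce
        9 * Wt * (Wt / config$cardinality) +          # grouped 3x3
        Wt * stage_out[s]                             # 1x1 expand
      if (bk == 1) total <- total + cin * stage_out[s]  # projection shortcut
    }
    stage_name <- paste0("C", s + 1)
    if (config$cbam_enabled && stage_name %in% config$cbam_stages) {
      C <- stage_out[s]
      hidden <- max(1, C %/% config$reduction)
      total <- total + 2 * C * hidden +               # shared MLP
        config$spatial_kernel^2 * 2                   # spatial conv
    }
  }
  total + sum(stage_out * config$fpn_channels) +      # laterals
    4 * 9 * config$fpn_channels^2                     # output convs
}
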