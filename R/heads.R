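# Detection heads: anchor generation, the fused convolutional +
# fully-connected mask head, the composite loss, and a small trainable
# detector used for smoke training and end-to-end exercises.

#' Anchor configuration
#'
#' @param ratios Aspect ratios width/height (default `c(1, 1.5, 2)`, matched
#'   to tapped-area boxes which are mostly 1-2x wider than tall).
#' @param scales Named per-level anchor scales (box side at ratio 1).
#' @param strides Named per-level feature strides.
#' @return Object of class `anchor_config`.
#' @export
anchor_config <- function(ratios = c(1, 1.5, 2),
                          scales = c(P2 = 32, P3 = 64, P4 = 128, P5 = 256,
                                     P6 = 512),
                          strides = c(P2 = 4, P3 = 8, P4 = 16, P5 = 32,
                                      P6 = 64)) {
  if (any(ratios <= 0)) stopf("ratios must be positive")
  structure(list(ratios = ratios, scales = scales, strides = strides),
            class = "anchor_config")
}

#' Generate anchors for one pyramid level
#'
#' One anchor per ratio at every feature-map location. For ratio `rho` at
#' scale `s` the anchor is `s*sqrt(rho)` wide and `s/sqrt(rho)` tall, so all
#' ratios preserve the area `s^2`.
#'
#' @param config An [anchor_config()].
#' @param level Level name (e.g. `"P3"`).
#' @param feature_size `c(h, w)` of the level's feature map.
#' @return Matrix with columns `c_min`, `r_min`, `c_max`, `r_max`
#'   (`h * w * length(ratios)` rows).
#' @export
generate_anchors <- function(config, level, feature_size) {
  s <- config$scales[[level]]
  stride <- config$strides[[level]]
  h <- feature_size[1]; w <- feature_size[2]
  ctr_r <- (rep(seq_len(h), each = w) - 0.5) * stride
  ctr_c <- (rep(seq_len(w), times = h) - 0.5) * stride
  out <- vector("list", length(config$ratios))
  for (k in seq_along(config$ratios)) {
    rho <- config$ratios[k]
    aw <- s * sqrt(rho); ah <- s / sqrt(rho)
    out[[k]] <- cbind(c_min = ctr_c - aw / 2, r_min = ctr_r - ah / 2,
                      c_max = ctr_c + aw / 2, r_max = ctr_r + ah / 2)
  }
  do.call(rbind, out)
}

#' Parameters of the fused mask head
#'
#' @param in_channels Pooled feature channels (default 256).
#' @param pooled Pooled spatial size of the mask branch (default 14).
#' @param seed Seed for random init.
#' @param fc_zero Zero the fully-connected path (for the fusion-identity
#'   contract).
#' @return Weight list for [mask_head_fused()].
#' @export
mask_head_params <- function(in_channels = 256, pooled = 14, seed = 1L,
                             fc_zero = FALSE) {
  half <- in_channels %/% 2
  with_seed(seed, {
    p <- list(
      conv = lapply(1:4, function(i) {
        ci <- in_channels
        rand_array(in_channels, ci, 3, 3, sd = 0.02)
      }),
      deconv = rand_array(in_channels, in_channels, 2, 2, sd = 0.02),
      mask_logit = rand_array(1, in_channels, 1, 1, sd = 0.02),
      conv4_fc = rand_array(in_channels, in_channels, 3, 3, sd = 0.02),
      conv5_fc = rand_array(half, in_channels, 3, 3, sd = 0.02),
      fc_W = matrix(stats::rnorm((2 * pooled)^2 * (half * pooled^2), 0, 0.01),
                    (2 * pooled)^2, half * pooled^2),
      fc_b = rep(0, (2 * pooled)^2),
      in_channels = in_channels, pooled = pooled
    )
    if (fc_zero) {
      p$conv4_fc[] <- 0; p$conv5_fc[] <- 0; p$fc_W[] <- 0; p$fc_b[] <- 0
    }
    p
  })
}

#' Fused convolutional + fully-connected mask head
#'
#' The convolutional path applies four 3x3 convolutions, a 2x stride-2
#' transposed convolution and a 1x1 logit convolution. The fully-connected
#' path branches after the third convolution through two further 3x3
#' convolutions (the second with half the channels, to keep the flattened
#' vector small), flattens, and maps to a `(2*pooled)^2`-vector reshaped to
#' the output spatial size. The head output is the element-wise sum of the
#' two paths: `pooled = 14` gives 28 x 28 = 784 mask logits.
#'
#' @param roi Pooled feature `(in_channels, pooled, pooled)`.
#' @param params From [mask_head_params()].
#' @param path `"fused"` (default), `"fcn"` or `"fc"` to evaluate a single
#'   path.
#' @return Mask logits matrix `(2*pooled) x (2*pooled)`.
#' @export
mask_head_fused <- function(roi, params, path = c("fused", "fcn", "fc")) {
  path <- match.arg(path)
  d <- dim(roi)
  if (d[1] != params$in_channels || d[2] != params$pooled ||
      d[3] != params$pooled) {
    stopf("expected pooled feature (%d, %d, %d), got (%d, %d, %d)",
          params$in_channels, params$pooled, params$pooled, d[1], d[2], d[3])
  }
  x <- roi
  for (i in 1:3) x <- relu(conv2d(x, params$conv[[i]], pad = 1))
  x3 <- x  # branch point after conv3
  fcn <- function() {
    y <- relu(conv2d(x3, params$conv[[4]], pad = 1))
    y <- relu(conv_transpose2(y, params$deconv))
    conv2d(y, params$mask_logit)[1, , ]
  }
  fc <- function() {
    y <- relu(conv2d(x3, params$conv4_fc, pad = 1))
    y <- relu(conv2d(y, params$conv5_fc, pad = 1))
    v <- as.vector(y)
    out <- drop(params$fc_W %*% v + params$fc_b)
    matrix(out, 2 * params$pooled, 2 * params$pooled)
  }
  switch(path, fcn = fcn(), fc = fc(), fused = fcn() + fc())
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)

#' Composite detection loss
#'
#' `L = L_cls + L_box + L_mask` (unit weights): softmax cross-entropy over
#' classes, smooth-L1 box regression over matched (foreground) instances,
#' and per-pixel binary cross-entropy over matched masks. With no matched
#' targets (background-only batch) `L_box = L_mask = 0` and `L = L_cls`.
#'
#' @param cls_logits `n x K` matrix of class logits.
#' @param cls_target Integer class ids in `1..K` (class 1 = background).
#' @param box_pred,box_target `n x 4` matrices; only rows in `matched` enter
#'   the box loss.
#' @param mask_logits,mask_target Lists of same-size matrices (logits and
#'   0/1 targets) for matched instances; may be empty.
#' @param matched Indices (or logical) of foreground rows.
#' @return Object of class `loss_breakdown`: list `L`, `L_cls`, `L_box`,
#'   `L_mask` with `L` the exact sum.
#' @export
composite_loss <- function(cls_logits, cls_target, box_pred = NULL,
                           box_target = NULL, mask_logits = list(),
                           mask_target = list(), matched = integer(0)) {
  cls_logits <- as.matrix(cls_logits)
  n <- nrow(cls_logits)
  m <- cls_logits - apply(cls_logits, 1, max)
  logZ <- log(rowSums(exp(m)))
  L_cls <- mean(logZ - m[cbind(seq_len(n), cls_target)])
  if (is.logical(matched)) matched <- which(matched)
  if (length(matched) && !is.null(box_pred)) {
    diffs <- box_pred[matched, , drop = FALSE] -
      box_target[matched, , drop = FALSE]
    L_box <- mean(rowSums(smooth_l1(diffs)))
  } else L_box <- 0
  if (length(mask_logits)) {
    per <- vapply(seq_along(mask_logits), function(i) {
      z <- mask_logits[[i]]; t <- mask_target[[i]]
      # numerically stable BCE with logits
      mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    }, numeric(1))
    L_mask <- mean(per)
  } else L_mask <- 0
  structure(list(L = L_cls + L_box + L_mask, L_cls = L_cls, L_box = L_box,
                 L_mask = L_mask), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("L = %.6f (cls %.6f + box %.6f + mask %.6f)\n",
              x$L, x$L_cls, x$L_box, x$L_mask))
  invisible(x)
}

# ---- small trainable detector (smoke training) -----------------------------

# Per-pixel features on a block-averaged grid: intercept, RGB, gray.
pixel_features <- function(image, ds = 4) {
  H <- dim(image)[1]; W <- dim(image)[2]
  h <- H %/% ds; w <- W %/% ds
  down <- function(p) {
    p <- p[seq_len(h * ds), seq_len(w * ds), drop = FALSE] / 255
    rs <- rowsum(p, group = rep(seq_len(h), each = ds))          # h x (w*ds)
    t(rowsum(t(rs), group = rep(seq_len(w), each = ds))) / ds^2  # h x w
  }
  ch <- lapply(1:3, function(k) down(image[, , k]))
  gray <- 0.299 * ch[[1]] + 0.587 * ch[[2]] + 0.114 * ch[[3]]
  list(X = cbind(1, as.vector(ch[[1]]), as.vector(ch[[2]]),
                 as.vector(ch[[3]]), as.vector(gray)),
       h = h, w = w, ds = ds)
}

roi_features <- function(image, box) {
  r0 <- max(1, floor(box["r_min"])); r1 <- min(dim(image)[1], ceiling(box["r_max"]))
  c0 <- max(1, floor(box["c_min"])); c1 <- min(dim(image)[2], ceiling(box["c_max"]))
  sub <- image[r0:r1, c0:c1, , drop = FALSE] / 255
  g <- 0.299 * sub[, , 1] + 0.587 * sub[, , 2] + 0.114 * sub[, , 3]
  c(1, mean(sub[, , 1]), mean(sub[, , 2]), mean(sub[, , 3]), stats::sd(g))
}

#' Train the small detector on synthetic scenes
#'
#' A deliberately small differentiable detector used to exercise the
#' composite loss and the training/evaluation contracts end-to-end on a CPU:
#' a per-pixel logistic mask head over block-averaged colour features, a
#' logistic foreground/background classifier over region colour statistics
#' (positive region = true box, negative = a panel-free region), and a
#' linear box-refinement head. All three heads are trained jointly by
#' full-batch gradient descent on `L = L_cls + L_box + L_mask`.
#'
#' @param samples List of `synthetic_sample` objects.
#' @param epochs Number of epochs (full-batch passes; default 5).
#' @param steps_per_epoch Gradient steps per epoch (default 10).
#' @param lr Learning rate.
#' @param ds Feature downsampling factor.
#' @param seed Seed (negative-region draws).
#' @return Object of class `smoke_detector` with weights, the per-step
#'   `loss_log` (data.frame: step, L, L_cls, L_box, L_mask) and settings.
#' @export
train_smoke_detector <- function(samples, epochs = 5, steps_per_epoch = 10,
                                 lr = 1.0, ds = 4, seed = 1L) {
  if (epochs < 1) stopf("no training requested: epochs < 1")
  feats <- lapply(samples, function(s) pixel_features(s$image, ds))
  ys <- lapply(seq_along(samples), function(i) {
    f <- feats[[i]]
    m <- samples[[i]]$mask
    mh <- m[seq(1, f$h * ds, by = ds), seq(1, f$w * ds, by = ds)] != 0
    as.numeric(as.vector(mh))
  })
  X_mask <- do.call(rbind, lapply(feats, `[[`, "X"))
  y_mask <- unlist(ys)
  # classifier rois: the true box (label fg) and a panel-free strip (label bg)
  roi_X <- NULL; roi_y <- c()
  box_X <- NULL; box_t <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    H <- dim(s$image)[1]; W <- dim(s$image)[2]
    gt <- s$gt_box
    pos <- roi_features(s$image, gt)
    neg_box <- c(r_min = 1, c_min = 1, r_max = max(2, gt["r_min"] - 1),
                 c_max = W)
    if (neg_box["r_max"] < 4) {
      neg_box <- c(r_min = 1, c_min = 1, r_max = H,
                   c_max = max(4, gt["c_min"] - 1))
    }
    neg <- roi_features(s$image, neg_box)
    roi_X <- rbind(roi_X, pos, neg)
    roi_y <- c(roi_y, 1, 0)
    box_X <- rbind(box_X, pos)
    box_t <- rbind(box_t, as.numeric(gt[c("c_min", "r_min", "c_max", "r_max")]) /
                     c(W, H, W, H))
  }
  d_pix <- ncol(X_mask); d_roi <- ncol(roi_X)
  w_mask <- rep(0, d_pix)
  w_cls <- rep(0, d_roi)
  W_box <- matrix(0, d_roi, 4)
  n_steps <- epochs * steps_per_epoch
  log_rows <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    z_mask <- drop(X_mask %*% w_mask)
    p_mask <- sigmoid(z_mask)
    z_cls <- drop(roi_X %*% w_cls)
    p_cls <- sigmoid(z_cls)
    b_pred <- roi_X[roi_y == 1, , drop = FALSE] %*% W_box
    # losses through the shared composite-loss contract
    lb <- composite_loss(
      cls_logits = cbind(0, z_cls), cls_target = roi_y + 1L,
      box_pred = b_pred, box_target = box_t,
      matched = seq_len(nrow(b_pred)),
      mask_logits = list(matrix(z_mask, ncol = 1)),
      mask_target = list(matrix(y_mask, ncol = 1)))
    log_rows[[step]] <- data.frame(step = step, L = lb$L, L_cls = lb$L_cls,
                                   L_box = lb$L_box, L_mask = lb$L_mask)
    # analytic gradients
    g_mask <- drop(crossprod(X_mask, p_mask - y_mask)) / length(y_mask)
    g_cls <- drop(crossprod(roi_X, p_cls - roi_y)) / length(roi_y)
    db <- b_pred - box_t
    dhub <- ifelse(abs(db) < 1, db, sign(db))
    g_box <- crossprod(roi_X[roi_y == 1, , drop = FALSE], dhub) / nrow(db)
    w_mask <- w_mask - lr * g_mask
    w_cls <- w_cls - lr * g_cls
    W_box <- W_box - lr * g_box
  }
  structure(list(w_mask = w_mask, w_cls = w_cls, W_box = W_box,
                 ds = ds, lr = lr, epochs = epochs,
                 steps_per_epoch = steps_per_epoch,
                 loss_log = do.call(rbind, log_rows)),
            class = "smoke_detector")
}

#' Mock detector wrapping a known mask
#'
#' Pass-through harness: [run_detector()] returns exactly this mask with
#' score 1. Useful to run the geometric pipeline in "image mode" while
#' bypassing an actual model.
#'
#' @param mask Binary mask.
#' @return Object of class `mock_detector`.
#' @export
mock_detector <- function(mask) {
  structure(list(mask = mask), class = "mock_detector")
}

#' Run a detector on an image
#'
#' Returns tapped-area instances sorted by score (descending); each instance
#' has `box` (`c_min, r_min, c_max, r_max`), `class`, `score` and a binary
#' `mask` at image resolution.
#'
#' @param image H x W x 3 array (0-255).
#' @param model A `smoke_detector` or `mock_detector`.
#' @param score_threshold Minimum score to keep an instance (default 0.5).
#' @return List of instances (possibly empty).
#' @export
run_detector <- function(image, model, score_threshold = 0.5) {
  if (inherits(model, "mock_detector")) {
    inst <- list(box = mask_bbox(model$mask), class = "tapped_area",
                 score = 1, mask = ifelse(model$mask != 0, 255L, 0L))
    if (inst$score < score_threshold) return(list())
    return(list(inst))
  }
  if (!inherits(model, "smoke_detector")) stopf("unsupported model object")
  f <- pixel_features(image, model$ds)
  p <- matrix(sigmoid(drop(f$X %*% model$w_mask)), f$h, f$w)
  bin <- p > 0.5
  if (!any(bin)) return(list())
  lab <- label_components(bin, connectivity = 8)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  comp <- lab == biggest
  # upsample to image resolution
  mask <- matrix(0L, dim(image)[1], dim(image)[2])
  up_r <- rep(seq_len(f$h), each = model$ds)
  up_c <- rep(seq_len(f$w), each = model$ds)
  mask[seq_along(up_r), seq_along(up_c)] <- ifelse(comp[up_r, up_c], 255L, 0L)
  if (!any(mask != 0)) return(list())
  box <- mask_bbox(mask)
  score <- sigmoid(drop(roi_features(image, box) %*% model$w_cls))
  if (score < score_threshold) return(list())
  list(list(box = box, class = "tapped_area", score = as.numeric(score),
            mask = mask))
}
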