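# Detector heads: anchors, fused mask head, composite loss, smoke training
# and the detector assembly.

test_that("anchors preserve area across ratios and count locations x 3", {
  cfg <- anchor_config()
  sq <- generate_anchors(cfg, "P3", c(1, 1))
  expect_equal(nrow(sq), 3)
  first <- sq[1, ]  # ratio 1 at scale 64
  expect_equal(unname(first["c_max"] - first["c_min"]), 64)
  expect_equal(unname(first["r_max"] - first["r_min"]), 64)

  a <- generate_anchors(cfg, "P2", c(10, 10))
  expect_equal(nrow(a), 300)
  areas <- (a[, "c_max"] - a[, "c_min"]) * (a[, "r_max"] - a[, "r_min"])
  expect_lt(diff(range(areas)), 1)
  # ratio = width/height
  w <- a[, "c_max"] - a[, "c_min"]; h <- a[, "r_max"] - a[, "r_min"]
  expect_setequal(round(unique(w / h), 6), c(1, 1.5, 2))
})

test_that("fused mask head is 28x28 and reduces to the FCN path", {
  p <- mask_head_params(in_channels = 16, pooled = 14, seed = 2)
  set.seed(14)
  roi <- array(rnorm(16 * 14 * 14), dim = c(16, 14, 14))
  out <- mask_head_fused(roi, p)
  expect_equal(dim(out), c(28, 28))

  # two-path oracle: fused equals the independent sum
  fcn <- mask_head_fused(roi, p, path = "fcn")
  fc <- mask_head_fused(roi, p, path = "fc")
  expect_lt(max(abs(out - (fcn + fc))), 1e-6)

  pz <- mask_head_params(in_channels = 16, pooled = 14, seed = 2,
                         fc_zero = TRUE)
  expect_equal(mask_head_fused(roi, pz), mask_head_fused(roi, pz, "fcn"))
  expect_error(mask_head_fused(array(0, c(16, 7, 7)), p), "pooled")
})

test_that("composite loss is additive and handles degenerate batches", {
  # near-perfect predictions give near-zero loss
  lb <- composite_loss(
    cls_logits = rbind(c(-20, 20), c(20, -20)), cls_target = c(2L, 1L),
    box_pred = rbind(c(0.1, 0.1, 0.5, 0.5)),
    box_target = rbind(c(0.1, 0.1, 0.5, 0.5)), matched = 1L,
    mask_logits = list(matrix(c(-30, 30), 1)),
    mask_target = list(matrix(c(0, 1), 1)))
  expect_lt(lb$L, 1e-6)

  # background-only: L = L_cls exactly
  bg <- composite_loss(cls_logits = rbind(c(1, -1)), cls_target = 1L)
  expect_equal(bg$L_box, 0)
  expect_equal(bg$L_mask, 0)
  expect_identical(bg$L, bg$L_cls)

  # random batch: total equals independently computed components
  set.seed(3)
  logits <- matrix(rnorm(8), 4, 2)
  targ <- sample(1:2, 4, replace = TRUE)
  bp <- matrix(rnorm(16), 4, 4); bt <- matrix(rnorm(16), 4, 4)
  ml <- list(matrix(rnorm(9), 3), matrix(rnorm(9), 3))
  mt <- list(matrix(rbinom(9, 1, 0.5), 3), matrix(rbinom(9, 1, 0.5), 3))
  lb2 <- composite_loss(logits, targ, bp, bt, ml, mt, matched = c(2L, 4L))
  ce <- mean(vapply(1:4, function(i) {
    -log(exp(logits[i, targ[i]]) / sum(exp(logits[i, ])))
  }, numeric(1)))
  sl1 <- function(x) ifelse(abs(x) < 1, x^2 / 2, abs(x) - 0.5)
  lbox <- mean(rowSums(sl1(bp[c(2, 4), ] - bt[c(2, 4), ])))
  bce <- mean(vapply(1:2, function(i) {
    pr <- 1 / (1 + exp(-ml[[i]]))
    -mean(mt[[i]] * log(pr) + (1 - mt[[i]]) * log(1 - pr))
  }, numeric(1)))
  expect_equal(lb2$L_cls, ce, tolerance = 1e-10)
  expect_equal(lb2$L_box, lbox, tolerance = 1e-10)
  expect_equal(lb2$L_mask, bce, tolerance = 1e-10)
  expect_identical(lb2$L, lb2$L_cls + lb2$L_box + lb2$L_mask)
})

test_that("a few dozen gradient steps strictly decrease the total loss", {
  batch <- make_dataset(4, seed = 5, config = smoke_scene_config())$samples
  model <- train_smoke_detector(batch, epochs = 4, steps_per_epoch = 10,
                                seed = 5)
  L <- model$loss_log$L
  expect_length(L, 40)
  ma <- stats::filter(L, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) < 0))
})

test_that("detector assembly: mock pass-through and score thresholding", {
  s <- generate_sample(smoke_scene_config(seed = 31))
  inst <- run_detector(s$image, mock_detector(s$mask))
  expect_length(inst, 1)
  expect_equal(mask_iou(inst[[1]]$mask, s$mask)$iou, 100)
  expect_equal(unname(inst[[1]]$box), unname(s$gt_box))

  # untrained model on a blank image at threshold 1: nothing
  blank <- array(0, dim = c(64, 64, 3))
  untrained <- structure(list(w_mask = rep(0, 5), w_cls = rep(0, 5),
                              W_box = matrix(0, 5, 4), ds = 4),
                         class = "smoke_detector")
  expect_length(run_detector(blank, untrained, score_threshold = 1), 0)
})

test_that("smoke-trained detector segments a held-out scene", {
  train <- make_dataset(8, seed = 6, config = smoke_scene_config())$samples
  model <- train_smoke_detector(train, epochs = 5, steps_per_epoch = 10,
                                seed = 6)
  held <- generate_sample(smoke_scene_config(seed = 4242))
  inst <- run_detector(held$image, model)
  expect_gte(length(inst), 1)
  expect_gte(mask_iou(inst[[1]]$mask, held$mask)$iou, 50)
})
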