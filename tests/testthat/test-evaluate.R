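# Metrics: precision/recall/F1, average precision, mask IOU, success rate,
# pixel location error, run aggregation.

test_that("precision/recall/F1 reproduce hand-computed values", {
  m <- prf1(98, 2, 0)
  expect_equal(unname(m["P"]), 98)
  expect_equal(unname(m["R"]), 100)
  expect_equal(unname(m["F1"]), 2 * 98 * 100 / 198)

  perfect <- prf1(50, 0, 0)
  expect_true(all(perfect == 100))

  set.seed(4)
  for (i in 1:20) {
    tp <- sample(0:50, 1) + 1; fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    m <- prf1(tp, fp, fn)
    P <- tp / (tp + fp) * 100; R <- tp / (tp + fn) * 100
    expect_equal(unname(m), c(P, R, 2 * P * R / (P + R)), tolerance = 1e-12)
    expect_true(m["F1"] >= 0 && m["F1"] <= 100)
  }
  expect_warning(z <- prf1(0, 0, 5), "undefined")
  expect_true(all(z == 0))
})

test_that("average precision handles trivial and planted cases", {
  one <- average_precision(list(list(score = 0.9, iou = 0.9, gt_id = 1)),
                           n_gt = 1)
  expect_equal(one$AP50, 1)
  expect_equal(one$AP75, 1)

  wrong <- average_precision(list(list(score = 0.8, iou = 0.2, gt_id = 1)),
                             n_gt = 1)
  expect_equal(wrong$AP50, 0)
  expect_true(is.na(average_precision(list(), n_gt = 0)$AP50))
})

test_that("average precision equals a brute-force PR integration oracle", {
  set.seed(10)
  n_gt <- 8
  dets <- lapply(1:20, function(i) {
    list(score = runif(1), iou = runif(1, 0.2, 1),
         gt_id = sample(1:n_gt, 1))
  })
  got <- average_precision(dets, n_gt, iou_thresholds = 0.5)
  # oracle: walk detections by descending score, accumulate PR points,
  # integrate sum over recall steps of max precision at recall >= r
  ord <- order(vapply(dets, `[[`, numeric(1), "score"), decreasing = TRUE)
  used <- integer(0); tp <- 0; fp <- 0; pr <- NULL
  for (k in ord) {
    d <- dets[[k]]
    if (d$iou >= 0.5 && !(d$gt_id %in% used)) {
      tp <- tp + 1; used <- c(used, d$gt_id)
    } else fp <- fp + 1
    pr <- rbind(pr, c(p = tp / (tp + fp), r = tp / n_gt))
  }
  ap <- 0; r_prev <- 0
  for (i in seq_len(nrow(pr))) {
    r <- pr[i, "r"]
    if (r > r_prev) {
      ap <- ap + (r - r_prev) * max(pr[pr[, "r"] >= r, "p"])
      r_prev <- r
    }
  }
  expect_equal(unname(got$ap[["0.50"]]), unname(ap), tolerance = 1e-12)
  # monotone non-increasing in the IOU threshold
  full <- average_precision(dets, n_gt)
  expect_true(all(diff(unname(full$ap)) <= 1e-12))
})

test_that("mask IOU is exact and symmetric", {
  a <- rect_mask(20, 20, 5, 5, 10, 10)
  expect_equal(mask_iou(a, a)$iou, 100)
  b <- rect_mask(20, 20, 15, 15, 18, 18)
  expect_equal(mask_iou(a, b)$iou, 0)
  # planted counts: 9 TP, 1 FP, 0 FN -> 90%
  gt <- matrix(0, 5, 5); gt[1:3, 1:3] <- 1
  pred <- gt; pred[4, 4] <- 1
  got <- mask_iou(pred, gt)
  expect_equal(unname(got$counts), c(9, 1, 0))
  expect_equal(got$iou, 90)
  expect_equal(mask_iou(a, b)$iou, mask_iou(b, a)$iou)
  expect_error(mask_iou(a, matrix(0, 3, 3)), "mismatch")
})

test_that("success rate reproduces the printed worked examples", {
  expect_equal(success_rate(504, 560), 90)
  expect_equal(round(success_rate(70, 76), 2), 92.11)
  expect_equal(success_rate(0, 10), 0)
  expect_error(success_rate(1, 0), "positive")
  expect_error(success_rate(5, 4), "s_t")
})

test_that("location error follows the rectangle-corner formula", {
  same <- location_error(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(same$e, 0)
  expect_true(same$success)

  le <- location_error(c(0, 0, 10, 10), c(2, 2, 12, 14))
  expect_equal(le$e_x, 2)
  expect_equal(le$e_y, 3)
  expect_equal(le$e, sqrt(6.5))
  expect_true(le$success)

  far <- location_error(c(20, 20, 30, 30), c(0, 0, 10, 10))
  expect_equal(far$e, 20)
  expect_false(far$success)

  # swapping the axis roles of both rectangles leaves e unchanged
  sw <- location_error(c(0, 0, 10, 10)[c(2, 1, 4, 3)],
                       c(2, 2, 12, 14)[c(2, 1, 4, 3)])
  expect_equal(sw$e, le$e)
})

test_that("run evaluation aggregates per condition and overall", {
  manifest <- data.frame(
    id = sprintf("sample_%03d", 1:6),
    illumination_mode = rep(c("cloudy", "direct_sun"), each = 3),
    year = rep(1:2, 3),
    c_min = 10, r_min = 20, c_max = 110, r_max = 60,
    stringsAsFactors = FALSE)
  gt <- lapply(1:6, function(i) c(c_min = 10, r_min = 20, c_max = 110,
                                  r_max = 60))
  names(gt) <- manifest$id
  perfect <- lapply(gt, function(b) list(box_new = b))
  rep1 <- evaluate_run(manifest, perfect, gt)
  expect_equal(rep1$Y[rep1$condition == "overall"], 100)
  expect_true(all(rep1$mean_e[rep1$condition == "overall"] == 0))

  half <- perfect[1:3]
  rep2 <- evaluate_run(manifest, half, gt)
  expect_equal(rep2$Y[rep2$condition == "overall"], 50)

  # aggregate equals per-sample recomputation
  shifted <- lapply(gt, function(b) list(box_new = b + c(3, 0, 3, 0)))
  rep3 <- evaluate_run(manifest, shifted, gt)
  per_e <- location_error(c(13, 20, 113, 60), c(10, 20, 110, 60))$e
  expect_equal(rep3$mean_e[rep3$condition == "overall"], per_e)
})
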