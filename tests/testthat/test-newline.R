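# New-line location: side edges, centre line, m-pixel offset, cubic
# smoothing and the composed locator.

test_that("side edges sit on the panel sides", {
  e <- rect_outline(200, 150, 30, 40, 180, 120)
  se <- side_edges(e, C1 = c(180, 40), B1 = c(180, 120))
  # returned coordinates carry the half-pixel cell-centre offset
  expect_equal(unname(se$D1), c(150.5, 40.5))
  expect_equal(unname(se$D2), c(120.5, 40.5))
  expect_equal(unname(se$E1), c(150.5, 120.5))
  expect_equal(unname(se$E2), c(120.5, 120.5))

  s <- generate_sample(test_scene(seed = 77, tilt = 32))
  line <- extract_existing_line(s$mask)
  se2 <- side_edges(line$edges, line$C1, line$B1)
  g <- tapline:::scene_geometry(s$config_used)
  # left side: analytic leaning edge; right side: vertical at c_R
  for (p in list(se2$D1, se2$D2)) {
    expect_lte(abs(p["c"] - tapline:::left_edge_col(s$config_used, g,
                                                    p["r"])), 2)
  }
  expect_lte(abs(se2$E1["c"] - g$c_R), 2)
  expect_lte(abs(se2$E2["c"] - g$c_R), 2)

  short <- rect_outline(100, 80, 60, 20, 90, 60)
  expect_error(side_edges(short, c(90, 20), c(90, 60)), "panel too short")
})

test_that("centre line is the exact midpoint construction", {
  pts <- list(D1 = c(r = 100, c = 40), E1 = c(r = 100, c = 80),
              D2 = c(r = 70, c = 40), E2 = c(r = 70, c = 80))
  ctr <- center_line(pts)
  expect_equal(unname(ctr$F1), c(100, 60))
  expect_equal(unname(ctr$F2), c(70, 60))
  expect_equal(unname(ctr$direction), c(1, 0))  # straight down

  set.seed(5)
  for (i in 1:20) {
    pts <- list(D1 = c(r = runif(1, 50, 99), c = runif(1, 1, 50)),
                E1 = c(r = runif(1, 50, 99), c = runif(1, 51, 99)),
                D2 = c(r = runif(1, 1, 49), c = runif(1, 1, 50)),
                E2 = c(r = runif(1, 1, 49), c = runif(1, 51, 99)))
    ctr <- center_line(pts)
    expect_equal(unname(ctr$F1), unname((pts$D1 + pts$E1) / 2))
    expect_equal(unname(ctr$F2), unname((pts$D2 + pts$E2) / 2))
    expect_equal(sum(ctr$direction^2), 1, tolerance = 1e-12)
  }
  same <- list(D1 = c(r = 1, c = 1), E1 = c(r = 1, c = 3),
               D2 = c(r = 1, c = 1), E2 = c(r = 1, c = 3))
  expect_error(center_line(same), "degenerate")
})

test_that("offset moves every point exactly m along the centre direction", {
  Q <- cbind(r = seq(100, 60, by = -1), c = seq(200, 160, by = -1))
  vertical <- list(direction = c(dr = 1, dc = 0))
  Q1 <- offset_line(Q, vertical, m = 8)
  expect_equal(Q1[, "r"], Q[, "r"] + 8)
  expect_equal(Q1[, "c"], Q[, "c"])

  slanted <- list(direction = c(dr = 4, dc = 3) / 5)
  Q2 <- offset_line(Q, slanted, m = 8)
  expect_equal(unique(round(Q2[, "r"] - Q[, "r"], 9)), 6.4)
  expect_equal(unique(round(Q2[, "c"] - Q[, "c"], 9)), 4.8)

  expect_equal(offset_line(Q, vertical, m = 0)[, "r"], Q[, "r"])
  # upward direction is flipped to the downward root
  up <- list(direction = c(dr = -1, dc = 0))
  expect_equal(offset_line(Q, up, m = 5)[, "r"], Q[, "r"] + 5)
})

test_that("offset isometry holds on synthetic lines", {
  worst <- 0
  for (seed in 1:100) {
    with_seed <- tapline:::with_seed
    Q <- with_seed(seed, cbind(r = cumsum(runif(40, -1, 1)) + 100,
                               c = seq(50, 11)))
    dir <- with_seed(seed + 1000, {
      v <- c(runif(1, 0.5, 1), runif(1, -0.5, 0.5))
      v / sqrt(sum(v^2))
    })
    Q1 <- offset_line(Q, list(direction = dir), m = 8)
    d <- sqrt(rowSums((Q1 - Q)^2))
    worst <- max(worst, max(abs(d - 8)))
  }
  expect_lt(worst, 1e-9)
})

test_that("cubic fit recovers exact polynomials and matches the
           least-squares oracle", {
  cc <- 0:20
  rr <- 2 + 3 * cc
  fit <- fit_cubic(cbind(r = rr, c = cc), degree = 3)
  expect_equal(unname(fit$coefficients), c(2, 3, 0, 0), tolerance = 1e-8)

  a_true <- c(1, 0.5, -0.2, 0.01)
  cc <- seq(0, 10, length.out = 40)
  rr <- a_true[1] + a_true[2] * cc + a_true[3] * cc^2 + a_true[4] * cc^3
  fit2 <- fit_cubic(cbind(r = rr, c = cc))
  expect_equal(unname(fit2$coefficients), a_true, tolerance = 1e-6)

  # noisy data: coefficients equal lm()'s QR solution
  set.seed(8)
  rr_n <- rr + rnorm(length(rr), 0, 1)
  fit3 <- fit_cubic(cbind(r = rr_n, c = cc))
  oracle <- unname(coef(lm(rr_n ~ poly(cc, 3, raw = TRUE))))
  expect_equal(unname(fit3$coefficients), oracle, tolerance = 1e-6)
  # smoothed curve residual bounded by the oracle residual
  expect_lte(fit3$residual_rms,
             sqrt(mean(residuals(lm(rr_n ~ poly(cc, 3, raw = TRUE)))^2)) +
               1e-9)
  expect_error(fit_cubic(cbind(r = 1:3, c = c(1, 1, 2))), "distinct")
})

test_that("normal-equations solution agrees with the stable solver", {
  # the textbook normal-equations construction is the oracle here
  set.seed(12)
  cc <- seq(30, 90, length.out = 50)
  rr <- 120 + 0.8 * cc - 0.004 * cc^2 + rnorm(50, 0, 0.5)
  fit <- fit_cubic(cbind(r = rr, c = cc), degree = 3)
  V <- outer(cc, 0:3, `^`)
  a_ne <- solve(crossprod(V), crossprod(V, rr))
  expect_equal(unname(fit$coefficients), drop(a_ne), tolerance = 1e-6)
})

test_that("locate_new_line matches ground truth end to end", {
  s <- generate_sample(test_scene(seed = 303, tilt = 27))
  res <- locate_new_line(s$mask)
  expect_s3_class(res, "tapping_line_result")
  expect_lt(mean_line_dist(res$Q2, s$gt_new_line), 2)

  # m = 0 reproduces the fitted existing line
  res0 <- locate_new_line(s$mask, m = 0)
  d0 <- mean_line_dist(res0$Q2, s$gt_existing_line)
  expect_lt(d0, 2)

  # image mode with a mock detector equals mask mode
  res_img <- locate_new_line(s$image, model = mock_detector(s$mask))
  expect_equal(res_img$Q2, res$Q2)
  expect_equal(res_img$coefficients, res$coefficients)
  expect_error(locate_new_line(s$image), "model")
})

test_that("translation equivariance of the located line", {
  s <- generate_sample(test_scene(seed = 404, tilt = 22))
  res <- locate_new_line(s$mask)
  dr <- 7L; dc <- -9L
  H <- nrow(s$mask); W <- ncol(s$mask)
  shifted <- matrix(0L, H, W)
  shifted[(1 + dr):H, 1:(W + dc)] <- s$mask[1:(H - dr), (1 - dc):W]
  res_s <- locate_new_line(shifted)
  moved <- cbind(r = res$Q2[, "r"] + dr, c = res$Q2[, "c"] + dc)
  expect_lt(mean_line_dist(res_s$Q2, moved), 1)
})

test_that("smoothing does not hurt: raw RMS >= smoothed RMS on average", {
  set.seed(99)
  diff_rms <- replicate(50, {
    seed <- sample.int(1e6, 1)
    s <- generate_sample(test_scene(seed = seed,
                                    tilt = runif(1, 12, 45),
                                    mode = sample(c("cloudy", "direct_sun",
                                                    "backlight"), 1)))
    res <- locate_new_line(s$mask)
    gt <- s$gt_new_line
    raw <- sqrt(mean(line_dists(res$Q1, gt)^2))
    smooth <- sqrt(mean(line_dists(res$Q2, gt)^2))
    raw - smooth
  })
  expect_gt(mean(diff_rms), 0)
})
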