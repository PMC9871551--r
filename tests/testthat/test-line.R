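# Existing-line extraction: extremes, boundary trace, angle and distance
# filters, and recovery on synthetic ground truth.

test_that("extreme points follow the tie rules and match a full scan", {
  e <- rect_outline(50, 60, 10, 5, 20, 35)
  ex <- extreme_points(e)
  expect_equal(unname(ex$A1), c(10, 5))
  expect_equal(unname(ex$B1), c(20, 35))

  single <- matrix(FALSE, 5, 5); single[3, 4] <- TRUE
  ex1 <- extreme_points(single)
  expect_equal(unname(ex1$A1), c(3, 4))
  expect_equal(unname(ex1$B1), c(3, 4))
  expect_error(extreme_points(matrix(FALSE, 4, 4)), "empty")

  # full-scan oracle on random synthetic panel edge maps
  for (seed in 1:30) {
    s <- generate_sample(test_scene(seed = seed, tilt = 10 + (seed %% 5) * 9,
                                    h = 140 + 20 * (seed %% 3)))
    em <- mask_to_edges(s$mask)
    ex <- extreme_points(em)
    idx <- which(em$edges, arr.ind = TRUE)
    rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
    expect_equal(unname(ex$A1),
                 c(rmin, min(idx[idx[, 1] == rmin, 2])))
    expect_equal(unname(ex$B1),
                 c(rmax, max(idx[idx[, 1] == rmax, 2])))
  }
})

test_that("boundary trace picks the scanline extreme in both modes", {
  e <- rect_outline(50, 60, 10, 5, 20, 35)
  tr_row <- trace_lower_left(e, c(10, 5), c(20, 35), scan = "row")
  # interior rows: constant left-side column
  expect_true(all(tr_row[tr_row[, "r"] %in% 11:19, "c"] == 5))
  expect_equal(unname(tr_row[1, "c"]), 5)  # bottom row: bottom-left corner
  expect_equal(unname(tr_row[1, "r"]), 20)

  tr_col <- trace_lower_left(e, c(10, 5), c(20, 35), scan = "column")
  expect_true(all(tr_col[tr_col[, "c"] %in% 6:34, "r"] == 20))

  # 45-degree band: one column step per row along the diagonal
  d <- matrix(FALSE, 30, 30)
  for (i in 0:14) d[25 - i, 5 + i] <- TRUE
  tr <- trace_lower_left(d, c(11, 19), c(25, 5), scan = "row")
  expect_true(all(diff(tr[, "c"]) == 1))
  expect_true(all(diff(tr[, "r"]) == -1))

  one_row <- matrix(FALSE, 10, 10); one_row[4, 2:8] <- TRUE
  tr1 <- trace_lower_left(one_row, c(4, 2), c(4, 8), scan = "row")
  expect_equal(nrow(tr1), 1)
})

test_that("angle filter seeds, keeps forward chords and drops backtracks", {
  # straight 30-degree trace: all points kept
  n <- 80
  tr <- cbind(r = round(100 - (1:n) * tan(pi / 6)), c = 100 - (1:n))
  fa <- filter_angle(tr, anchor_index = 50)
  expect_equal(nrow(fa$N), n)
  expect_equal(unname(fa$anchor), unname(tr[50, ]))

  # tail that turns back right of the anchor: chords exceed pi/2, excluded
  tail_back <- rbind(tr, cbind(r = tr[n, "r"] - (1:10),
                               c = tr[50, "c"] + 5 + (1:10)))
  fa2 <- filter_angle(tail_back, anchor_index = 50)
  expect_equal(nrow(fa2$N), n)

  # trace of exactly anchor_index points: everything seeded, no filtering
  fa3 <- filter_angle(tr[1:50, ], anchor_index = 50)
  expect_equal(nrow(fa3$N), 50)
  expect_error(filter_angle(tr[1, , drop = FALSE]), "2 points")

  # signed convention excludes dips below the anchor, unsigned keeps them
  dip <- rbind(tr[1:50, ],
               cbind(r = tr[50, "r"] + 1, c = tr[50, "c"] - 1),
               cbind(r = tr[50, "r"] - 1, c = tr[50, "c"] - 2))
  expect_equal(nrow(filter_angle(dip, 50, convention = "unsigned")$N), 52)
  expect_equal(nrow(filter_angle(dip, 50, convention = "signed")$N), 51)
})

test_that("distance filter truncates at the first step over d_max", {
  # 8-connected chain fully accepted (max step sqrt(2) <= 1.5)
  n <- 70
  chain <- cbind(r = 200 - cumsum(rep(c(1, 0), n / 2)),
                 c = 300 - (1:n))
  line <- filter_distance(chain, anchor_index = 50)
  expect_equal(line$n_points, n)
  expect_equal(unname(line$B1), unname(chain[1, ]))

  # one 2-pixel jump: truncated exactly there
  jump <- chain
  jump[61:n, "c"] <- jump[61:n, "c"] - 2
  line2 <- filter_distance(jump, anchor_index = 50)
  expect_equal(line2$n_points, 60)
  expect_equal(unname(line2$C1), unname(jump[60, ]))
})

test_that("full extraction recovers the synthetic tapping line", {
  for (seed in 1:20) {
    tilt <- 10 + (seed - 1) * 2
    s <- generate_sample(test_scene(seed = seed, tilt = tilt,
                                    mode = c("cloudy", "direct_sun",
                                             "backlight")[1 + seed %% 3]))
    line <- extract_existing_line(s$mask)
    # line rises from end (B1) to start (C1)
    expect_lt(line$C1[1], line$B1[1])
    expect_true(all((line$points[, "r"] - 0.5) %in% line$trace[, "r"]))
    # mean distance of recovered points to the analytic line
    gt <- s$gt_existing_line
    d <- mean_line_dist(line$points, gt)
    expect_lt(d, 1.0)
    # C1 close to the analytic line start (within overhang + edge bias)
    d_start <- sqrt(sum((line$C1 - gt[nrow(gt), ])^2))
    expect_lt(d_start, s$config_used$corner_overhang_px + 2.5)
  }
  expect_error(extract_existing_line(matrix(0, 20, 20)), "no tapped area")
})

test_that("extraction is deterministic and subsets are nested", {
  s <- generate_sample(test_scene(seed = 202, tilt = 28))
  l1 <- extract_existing_line(s$mask)
  l2 <- extract_existing_line(s$mask)
  expect_identical(l1$points, l2$points)
  # Q subset of N subset of trace (points carry the half-pixel offset)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(l1$points - 0.5) %in% key(l1$N)))
  expect_true(all(key(l1$N) %in% key(l1$trace)))
})
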