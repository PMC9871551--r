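# Detection and location evaluation metrics.

#' Precision, recall and F1 from instance counts
#'
#' `P = TP/(TP+FP) * 100`, `R = TP/(TP+FN) * 100`, `F1 = 2PR/(P+R)`.
#' Undefined ratios (zero denominators) are reported as 0 with a warning.
#'
#' @param tp,fp,fn True positive, false positive and false negative counts.
#' @return Named vector `P`, `R`, `F1` in percent.
#' @export
prf1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  if (tp + fp == 0 || tp + fn == 0) {
    warning("undefined precision or recall; reporting 0", call. = FALSE)
    P <- if (tp + fp > 0) tp / (tp + fp) * 100 else 0
    R <- if (tp + fn > 0) tp / (tp + fn) * 100 else 0
  } else {
    P <- tp / (tp + fp) * 100
    R <- tp / (tp + fn) * 100
  }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

# IOU of two boxes given as c(c_min, r_min, c_max, r_max).
box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}

#' Average precision of scored detections
#'
#' Matches detections to ground truths greedily by descending score at each
#' IOU threshold, then integrates the precision-recall curve. Default
#' integration is all-point (area under the monotonized PR curve); the
#' 101-point interpolation used by COCO is available via `interpolation`.
#'
#' @param detections List of detections, each a list with `score` and either
#'   `iou` (pre-computed IOU against its candidate ground truth, with `gt_id`)
#'   or `box`/`mask`.
#' @param n_gt Number of ground-truth instances.
#' @param iou_thresholds IOU matching thresholds (default the 10 COCO
#'   thresholds 0.5 to 0.95).
#' @param interpolation `"all_point"` or `"101_point"`.
#' @return List with per-threshold `ap`, plus `AP50`, `AP75` and `AP5095`.
#' @export
average_precision <- function(detections, n_gt,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05),
                              interpolation = c("all_point", "101_point")) {
  interpolation <- match.arg(interpolation)
  thr_names <- sprintf("%.2f", iou_thresholds)
  if (n_gt <= 0) {
    return(list(ap = stats::setNames(rep(NA_real_, length(iou_thresholds)),
                                     thr_names),
                AP50 = NA_real_, AP75 = NA_real_, AP5095 = NA_real_))
  }
  scores <- vapply(detections, function(d) d$score, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  aps <- vapply(iou_thresholds, function(thr) {
    matched_gt <- integer(0)
    tp <- logical(length(ord))
    for (k in seq_along(ord)) {
      d <- detections[[ord[k]]]
      gid <- if (!is.null(d$gt_id)) d$gt_id else NA_integer_
      ok <- !is.null(d$iou) && d$iou >= thr && !is.na(gid) &&
        !(gid %in% matched_gt)
      if (ok) {
        tp[k] <- TRUE
        matched_gt <- c(matched_gt, gid)
      }
    }
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_along(tp)
    rec <- cum_tp / n_gt
    pr_integrate(prec, rec, interpolation)
  }, numeric(1))
  names(aps) <- thr_names
  pick <- function(nm) if (nm %in% thr_names) aps[[nm]] else NA_real_
  list(ap = aps,
       AP50 = pick("0.50"),
       AP75 = pick("0.75"),
       AP5095 = mean(aps))
}

# Area under the monotonized precision-recall curve.
pr_integrate <- function(prec, rec, interpolation = "all_point") {
  if (!length(prec)) return(0)
  # monotone non-increasing precision envelope from the right
  penv <- rev(cummax(rev(prec)))
  if (interpolation == "101_point") {
    rs <- seq(0, 1, by = 0.01)
    pv <- vapply(rs, function(r) {
      sel <- rec >= r
      if (any(sel)) max(penv[sel]) else 0
    }, numeric(1))
    return(mean(pv))
  }
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * penv)
}

#' Pixel-level mask IOU
#'
#' `IOU = M_TP / (M_TP + M_FP + M_FN) * 100` over pixels of two same-size
#' binary rasters.
#'
#' @param pred,gt Binary masks (0/255, 0/1 or logical), same dimensions.
#' @return List with `iou` (percent) and `counts` (`M_TP`, `M_FP`, `M_FN`).
#' @export
mask_iou <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stopf("mask size mismatch")
  p <- pred != 0; g <- gt != 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  iou <- if (tp + fp + fn == 0) 100 else tp / (tp + fp + fn) * 100
  list(iou = iou, counts = c(M_TP = tp, M_FP = fp, M_FN = fn))
}

#' Location success rate
#'
#' `Y = S_T / S * 100`, reported to full precision (print to 2 decimals).
#'
#' @param s_t Number of successful locations.
#' @param s Number attempted (> 0).
#' @return Percentage.
#' @export
success_rate <- function(s_t, s) {
  if (s <= 0) stopf("`s` must be positive")
  if (s_t < 0 || s_t > s) stopf("need 0 <= s_t <= s")
  s_t / s * 100
}

#' Pixel location error of a predicted rectangle
#'
#' `e_x = (|X_min - x_min| + |X_max - x_max|) / 2` and analogously `e_y`;
#' total error `e = sqrt((e_x^2 + e_y^2) / 2)`. A location succeeds when
#' `e <= tolerance` (default 10 px, the end-effector fault tolerance).
#'
#' @param pred,gt Rectangles `c(x_min, y_min, x_max, y_max)` with x = column,
#'   y = row.
#' @param tolerance Success tolerance in pixels.
#' @return Named list `e_x`, `e_y`, `e`, `success`, `tolerance`.
#' @export
location_error <- function(pred, gt, tolerance = 10) {
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  e_x <- (abs(gt[1] - pred[1]) + abs(gt[3] - pred[3])) / 2
  e_y <- (abs(gt[2] - pred[2]) + abs(gt[4] - pred[4])) / 2
  e <- sqrt((e_x^2 + e_y^2) / 2)
  list(e_x = e_x, e_y = e_y, e = e, success = e <= tolerance,
       tolerance = tolerance)
}

#' Evaluate a run of new-line predictions against a dataset manifest
#'
#' Groups samples by condition (illumination mode and, when present,
#' panel-age class), computes the location success tally and mean pixel
#' errors per group and overall, plus mask IOU when predicted masks are
#' supplied. Samples without a prediction count as location failures.
#'
#' @param manifest Data frame from [make_dataset()] (needs columns `id`,
#'   `illumination_mode`, `c_min`, `r_min`, `c_max`, `r_max`).
#' @param predictions Named list keyed by sample id; each element a list with
#'   `box_new` (`c_min, r_min, c_max, r_max` of the located new line),
#'   optional `mask` and `score`.
#' @param gt_boxes Named list keyed by sample id with the ground-truth
#'   new-line rectangles (`c_min, r_min, c_max, r_max`). Defaults to the
#'   tapped-area boxes in the manifest if absent.
#' @param tolerance Success tolerance in pixels (default 10).
#' @param out_csv,out_json Optional report paths.
#' @return Data frame, one row per condition group plus an `overall` row,
#'   with columns `condition`, `S`, `S_T`, `Y`, `mean_e_x`, `mean_e_y`,
#'   `mean_e`.
#' @export
evaluate_run <- function(manifest, predictions, gt_boxes = NULL,
                         tolerance = 10, out_csv = NULL, out_json = NULL) {
  ids <- manifest$id
  per <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    gt <- if (!is.null(gt_boxes)) gt_boxes[[id]] else
      c(manifest$c_min[i], manifest$r_min[i], manifest$c_max[i],
        manifest$r_max[i])
    pr <- predictions[[id]]
    if (is.null(pr) || is.null(pr$box_new)) {
      return(list(success = FALSE, e_x = NA_real_, e_y = NA_real_,
                  e = NA_real_))
    }
    b <- pr$box_new
    le <- location_error(c(b["c_min"], b["r_min"], b["c_max"], b["r_max"]),
                         c(gt["c_min"], gt["r_min"], gt["c_max"], gt["r_max"]),
                         tolerance)
    list(success = le$success, e_x = le$e_x, e_y = le$e_y, e = le$e)
  })
  succ <- vapply(per, `[[`, logical(1), "success")
  ex <- vapply(per, `[[`, numeric(1), "e_x")
  ey <- vapply(per, `[[`, numeric(1), "e_y")
  ee <- vapply(per, `[[`, numeric(1), "e")
  groups <- list()
  for (mode in unique(manifest$illumination_mode)) {
    groups[[mode]] <- which(manifest$illumination_mode == mode)
  }
  if ("year" %in% names(manifest) && !all(is.na(manifest$year))) {
    for (y in sort(unique(stats::na.omit(manifest$year)))) {
      groups[[sprintf("year_%d", y)]] <- which(manifest$year == y)
    }
  }
  groups[["overall"]] <- seq_along(ids)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(condition = g, S = length(i), S_T = sum(succ[i]),
               Y = success_rate(sum(succ[i]), length(i)),
               mean_e_x = mean(ex[i], na.rm = TRUE),
               mean_e_y = mean(ey[i], na.rm = TRUE),
               mean_e = mean(ee[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(report, out_csv, row.names = FALSE)
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, dataframe = "rows", digits = NA)
  }
  report
}
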