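# Detection evaluation: IoU, greedy TP/FP matching, precision/recall,
# AP by all-points precision-envelope integration of the PR curve, and
# mAP over classes and IoU thresholds.
#
# Detections are data frames with columns
#   image, class, conf, x1, y1, x2, y2
# ground truth with columns
#   image, class, x1, y1, x2, y2
# Boxes are half-open pixel rectangles (x2 > x1, y2 > y1); class ids are
# 0-based to match YOLO label files.

#' Intersection over union of two boxes
#'
#' @param a,b numeric length-4 vectors `(x1, y1, x2, y2)` with
#'   `x2 > x1`, `y2 > y1`
#' @return IoU in `[0, 1]`
#' @export
iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box")
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  inter / union
}

# vectorized IoU of one box against a matrix of boxes (rows)
iou_one_many <- function(a, m) {
  iw <- pmax(0, pmin(a[3], m[, 3]) - pmax(a[1], m[, 1]))
  ih <- pmax(0, pmin(a[4], m[, 4]) - pmax(a[2], m[, 2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter)
}

#' Greedy confidence-ordered detection/ground-truth matching
#'
#' Detections are visited in decreasing confidence; each is a true
#' positive iff its best-IoU, not-yet-matched, same-class ground truth in
#' the same image has IoU at or above the threshold (IoU ties broken by
#' ground-truth index). Each ground truth matches at most once.
#'
#' @param dets detection data frame (see module header)
#' @param gts ground-truth data frame
#' @param iou_thresh matching threshold
#' @return list: `tp` (logical per detection, in decreasing-confidence
#'   order), `order` (row indices of `dets` in that order), `fn`
#'   (unmatched ground-truth count)
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  ord <- order(-dets$conf)
  n <- length(ord)
  tp <- logical(n)
  matched <- rep(FALSE, nrow(gts))
  gbox <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
  if (n) {
    for (k in seq_len(n)) {
      d <- dets[ord[k], ]
      cand <- which(!matched & gts$image == d$image & gts$class == d$class)
      if (!length(cand)) next
      ious <- iou_one_many(c(d$x1, d$y1, d$x2, d$y2),
                           gbox[cand, , drop = FALSE])
      best <- which.max(ious) # first max = lowest GT index on ties
      if (ious[best] >= iou_thresh) {
        tp[k] <- TRUE
        matched[cand[best]] <- TRUE
      }
    }
  }
  list(tp = tp, order = ord, fn = sum(!matched))
}

#' Precision and recall from counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; both defined as 0 when
#' their denominator is 0.
#'
#' @param tp,fp,fn non-negative counts
#' @return named vector `c(precision, recall)`
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r)
}

#' Average precision of one class
#'
#' Ranks detections by confidence, accumulates TP/FP, and integrates the
#' precision envelope over recall (all-points interpolation, the
#' continuous realization of the area under the PR curve).
#'
#' @param dets detections of a single class
#' @param gts ground truths of the same class
#' @param iou_thresh matching threshold
#' @return object of class "cryolo_pr": list with `ap`, `precision`,
#'   `recall`, `tp_cum`, `fp_cum`, `n_gt`, `degenerate` (TRUE when
#'   detections exist but no ground truth does)
#' @export
average_precision <- function(dets, gts, iou_thresh = 0.5) {
  n_gt <- nrow(gts)
  if (nrow(dets) == 0) {
    return(structure(list(ap = 0, precision = numeric(0),
                          recall = numeric(0), tp_cum = integer(0),
                          fp_cum = integer(0), n_gt = n_gt,
                          degenerate = FALSE), class = "cryolo_pr"))
  }
  if (n_gt == 0) {
    return(structure(list(ap = 0, precision = rep(0, nrow(dets)),
                          recall = rep(0, nrow(dets)),
                          tp_cum = integer(nrow(dets)),
                          fp_cum = seq_len(nrow(dets)), n_gt = 0,
                          degenerate = TRUE), class = "cryolo_pr"))
  }
  mm <- match_detections(dets, gts, iou_thresh)
  tp_cum <- cumsum(mm$tp)
  fp_cum <- cumsum(!mm$tp)
  precision <- tp_cum / (tp_cum + fp_cum)
  recall <- tp_cum / n_gt
  # precision envelope: non-increasing hull from the right
  env <- rev(cummax(rev(precision)))
  # integrate over recall increments
  r_prev <- c(0, recall[-length(recall)])
  ap <- sum((recall - r_prev) * env)
  structure(list(ap = ap, precision = precision, recall = recall,
                 tp_cum = tp_cum, fp_cum = fp_cum, n_gt = n_gt,
                 degenerate = FALSE), class = "cryolo_pr")
}

#' Mean average precision over classes
#'
#' @param ap_values numeric vector of per-class APs
#' @return their unweighted mean
#' @export
mean_ap <- function(ap_values) {
  if (length(ap_values) < 1) stop("need at least one class AP")
  mean(ap_values)
}

#' Evaluate detections against a labelled dataset
#'
#' Computes per-class AP at IoU 0.5, mAP@0.5 and mAP@0.5:0.95 (the mean
#' over the 10-threshold grid 0.5, 0.55, ..., 0.95).
#'
#' @param dets detection data frame
#' @param gts ground-truth data frame
#' @param classes integer vector of class ids to evaluate; defaults to
#'   all classes present in the ground truth
#' @param iou_grid IoU thresholds for the averaged metric
#' @return list of class "cryolo_eval": `ap` (per class at 0.5), `map50`,
#'   `map50_95`, `precision`/`recall` at 0.5 (pooled over classes),
#'   `per_class` (data frame), `pr_curves` (list of "cryolo_pr")
#' @export
evaluate_detections <- function(dets, gts, classes = NULL,
                                iou_grid = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(gts) == 0) stop("empty ground truth")
  if (is.null(classes)) classes <- sort(unique(gts$class))
  per_thresh_map <- numeric(length(iou_grid))
  ap50 <- setNames(numeric(length(classes)), classes)
  pr_curves <- list()
  tp_tot <- fp_tot <- fn_tot <- 0
  for (ti in seq_along(iou_grid)) {
    aps <- numeric(length(classes))
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      dc <- dets[dets$class == cl, , drop = FALSE]
      gc <- gts[gts$class == cl, , drop = FALSE]
      pr <- average_precision(dc, gc, iou_grid[ti])
      aps[ci] <- pr$ap
      if (iou_grid[ti] == 0.5) {
        ap50[ci] <- pr$ap
        pr_curves[[as.character(cl)]] <- pr
        n <- length(pr$tp_cum)
        tp <- if (n) pr$tp_cum[n] else 0L
        tp_tot <- tp_tot + tp
        fp_tot <- fp_tot + (if (n) pr$fp_cum[n] else 0L)
        fn_tot <- fn_tot + pr$n_gt - tp
      }
    }
    per_thresh_map[ti] <- mean(aps)
  }
  pr50 <- precision_recall(tp_tot, fp_tot, fn_tot)
  structure(list(
    ap = ap50, map50 = mean(ap50), map50_95 = mean(per_thresh_map),
    precision = unname(pr50["precision"]), recall = unname(pr50["recall"]),
    per_class = data.frame(class = classes, ap50 = unname(ap50)),
    map_per_thresh = setNames(per_thresh_map, iou_grid),
    pr_curves = pr_curves), class = "cryolo_eval")
}

#' @export
print.cryolo_eval <- function(x, ...) {
  cat("detection evaluation\n")
  cat(sprintf("  mAP@0.5      %.4f\n", x$map50))
  cat(sprintf("  mAP@0.5:0.95 %.4f\n", x$map50_95))
  cat(sprintf("  P %.4f  R %.4f (pooled, IoU 0.5)\n", x$precision, x$recall))
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("  class %s AP@0.5 %.4f\n", x$per_class$class[i],
                x$per_class$ap50[i]))
  invisible(x)
}

#' Write an evaluation result to JSON and CSV
#'
#' @param ev a "cryolo_eval"
#' @param json_path,csv_path output paths (NULL = skip)
#' @param pr_csv_path optional CSV of the per-class PR points
#' @return invisibly, the list of written paths
#' @export
write_eval_report <- function(ev, json_path = NULL, csv_path = NULL,
                              pr_csv_path = NULL) {
  written <- character()
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(map50 = ev$map50, map50_95 = ev$map50_95,
           precision = ev$precision, recall = ev$recall,
           per_class = ev$per_class),
      json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(ev$per_class, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(pr_csv_path)) {
    rows <- do.call(rbind, lapply(names(ev$pr_curves), function(cl) {
      pr <- ev$pr_curves[[cl]]
      if (!length(pr$recall)) return(NULL)
      data.frame(class = cl, recall = pr$recall, precision = pr$precision)
    }))
    utils::write.csv(rows, pr_csv_path, row.names = FALSE)
    written <- c(written, pr_csv_path)
  }
  invisible(written)
}
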