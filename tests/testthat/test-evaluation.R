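# Detection metrics against arithmetic worked examples and a
# brute-force threshold-scanning evaluator.

test_that("IoU matches area arithmetic", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               iou(c(1, 1, 3, 3), c(0, 0, 2, 2))) # symmetry
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching assigns each ground truth at most once, in confidence order", {
  gt <- data.frame(image = 1, class = 0, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  d1 <- data.frame(image = 1, class = 0, conf = 0.9,
                   x1 = 0, y1 = 0, x2 = 10, y2 = 6) # IoU 0.6
  m <- match_detections(d1, gt, 0.5)
  expect_equal(sum(m$tp), 1); expect_equal(m$fn, 0)
  d2 <- data.frame(image = 1, class = 0, conf = 0.9,
                   x1 = 0, y1 = 0, x2 = 10, y2 = 4) # IoU 0.4
  m2 <- match_detections(d2, gt, 0.5)
  expect_equal(sum(m2$tp), 0); expect_equal(m2$fn, 1)
  # two detections over one GT: higher confidence wins, other is FP
  d3 <- rbind(transform(d1, conf = 0.8), transform(d1, conf = 0.9))
  m3 <- match_detections(d3, gt, 0.5)
  expect_equal(m3$tp[1], TRUE)  # first in confidence order (0.9)
  expect_equal(m3$tp[2], FALSE)
  expect_equal(m3$order, c(2L, 1L))
  # class mismatch never matches
  d4 <- transform(d1, class = 1)
  expect_equal(sum(match_detections(d4, gt, 0.5)$tp), 0)
})

test_that("precision and recall follow their defining ratios with a 0/0 -> 0 convention", {
  expect_equal(precision_recall(3, 1, 0), c(precision = 0.75, recall = 1))
  expect_equal(precision_recall(0, 0, 0), c(precision = 0, recall = 0))
  expect_equal(precision_recall(70, 30, 10),
               c(precision = 0.7, recall = 0.875))
  expect_error(precision_recall(-1, 0, 0))
})

test_that("AP integrates the precision envelope over recall", {
  gt2 <- data.frame(image = c(1, 1), class = 0,
                    x1 = c(0, 20), y1 = 0, x2 = c(10, 30), y2 = 10)
  # ranking [TP, FP, TP] over 2 GTs -> AP = 1*0.5 + 0.667*0.5 = 0.8333
  dets <- data.frame(
    image = 1, class = 0, conf = c(0.9, 0.8, 0.7),
    x1 = c(0, 50, 20), y1 = c(0, 50, 0),
    x2 = c(10, 60, 30), y2 = c(10, 60, 10))
  pr <- average_precision(dets, gt2, 0.5)
  expect_equal(pr$precision, c(1, 0.5, 2 / 3))
  expect_equal(pr$recall, c(0.5, 0.5, 1))
  expect_equal(pr$ap, 0.5 * 1 + 0.5 * 2 / 3)
  # all detections TP covering all GTs -> AP = 1
  d_all <- data.frame(image = 1, class = 0, conf = c(0.9, 0.8),
                      x1 = c(0, 20), y1 = 0, x2 = c(10, 30), y2 = 10)
  expect_equal(average_precision(d_all, gt2, 0.5)$ap, 1)
  # no detections -> AP 0; detections without GT -> AP 0, flagged
  none <- d_all[0, ]
  expect_equal(average_precision(none, gt2, 0.5)$ap, 0)
  deg <- average_precision(d_all, gt2[0, ], 0.5)
  expect_equal(deg$ap, 0)
  expect_true(deg$degenerate)
})

test_that("recall is non-decreasing, the envelope non-increasing, and a top TP never lowers AP", {
  set.seed(31)
  for (k in 1:10) {
    inst <- rand_instance()
    pr <- average_precision(inst$dets, inst$gts, 0.5)
    expect_true(all(diff(pr$recall) >= -1e-12))
    env <- rev(cummax(rev(pr$precision)))
    expect_true(all(diff(env) <= 1e-12))
    expect_gte(pr$ap, 0); expect_lte(pr$ap, 1)
    # prepending a perfect match for an otherwise-unmatched ground
    # truth never decreases AP: plant an extra, isolated GT first
    extra <- data.frame(image = 1, class = 0,
                        x1 = 500, y1 = 500, x2 = 520, y2 = 520)
    gts2 <- rbind(inst$gts, extra)
    pr1 <- average_precision(inst$dets, gts2, 0.5)
    boost <- data.frame(image = 1, class = 0, conf = 1,
                        x1 = 500, y1 = 500, x2 = 520, y2 = 520)
    pr2 <- average_precision(rbind(boost, inst$dets), gts2, 0.5)
    expect_gte(pr2$ap + 1e-12, pr1$ap)
  }
})

test_that("mean AP averages classes and is permutation invariant", {
  expect_equal(mean_ap(c(1, 0)), 0.5)
  expect_equal(mean_ap(0.73), 0.73)
  expect_error(mean_ap(numeric(0)))
  set.seed(32)
  inst <- rand_instance(n_gt = 10, n_det = 16)
  ev <- evaluate_detections(inst$dets, inst$gts)
  swap <- function(df) transform(df, class = 1 - class)
  ev2 <- evaluate_detections(swap(inst$dets), swap(inst$gts))
  expect_equal(ev$map50, ev2$map50)
  expect_equal(ev$map50_95, ev2$map50_95)
})

test_that("the evaluator agrees with a brute-force threshold-scanning oracle", {
  set.seed(33)
  for (k in 1:20) {
    inst <- rand_instance(n_img = sample(2:4, 1), n_gt = sample(4:8, 1),
                          n_det = sample(6:14, 1))
    for (th in c(0.5, 0.75)) {
      mine <- average_precision(inst$dets[inst$dets$class == 0, ],
                                inst$gts[inst$gts$class == 0, ], th)
      ref <- brute_ap(inst$dets[inst$dets$class == 0, ],
                      inst$gts[inst$gts$class == 0, ], th)
      expect_lt(abs(mine$ap - ref), 1e-6)
    }
  }
})

test_that("dataset evaluation reports a 10-threshold averaged mAP and a perfect echo scores 1", {
  set.seed(34)
  inst <- rand_instance(n_gt = 8, n_det = 12)
  ev <- evaluate_detections(inst$dets, inst$gts)
  expect_length(ev$map_per_thresh, 10)
  expect_equal(as.numeric(names(ev$map_per_thresh)),
               seq(0.5, 0.95, by = 0.05))
  echo <- transform(inst$gts, conf = 1)
  ev2 <- evaluate_detections(echo, inst$gts)
  expect_equal(ev2$map50, 1)
  expect_equal(ev2$map50_95, 1)
  expect_error(evaluate_detections(echo, inst$gts[0, ]), "empty")
})
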