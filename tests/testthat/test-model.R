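# Detector assembly, head-shape contracts, decoding/NMS and the loss.

count_module_types <- function(m) {
  counts <- c(repvgg = 0L, coord_att = 0L)
  walk <- function(v) {
    if (inherits(v, "repvgg")) counts["repvgg"] <<- counts["repvgg"] + 1L
    if (inherits(v, "coord_att"))
      counts["coord_att"] <<- counts["coord_att"] + 1L
    if (inherits(v, "cry_module"))
      for (nm in ls(v)) walk(v[[nm]])
    else if (is.list(v)) for (el in v) walk(el)
  }
  walk(m)
  counts
}

test_that("config validation rejects bad geometry and anchors", {
  expect_error(cryolo_config(img_size = 100), "img_size")
  expect_error(cryolo_config(nc = 0))
  expect_error(cryolo_config(anchors = list()), "anchors")
  expect_error(cryolo_config(anchors = rep(list(matrix(-1, 3, 2)), 3)),
               "anchors")
  cfg <- cryolo_config(img_size = 320)
  expect_equal(cfg$anchors[[1]][1, ], c(10, 13) / 2) # scaled to img_size
})

test_that("head emits 3*(5+nc) channels per scale at strides 8/16/32", {
  set.seed(41)
  m <- build_cr_yolov5s(tiny_cfg(img_size = 96, nc = 2))
  for (h in m$head) expect_equal(h$cout, 3 * (5 + 2))
  x <- array(runif(96 * 96 * 3 * 2), c(96, 96, 3, 2))
  raw <- forward_raw(m, x)
  expect_equal(dim(raw[[1]]), c(2, 3, 12, 12, 7))
  expect_equal(dim(raw[[2]]), c(2, 3, 6, 6, 7))
  expect_equal(dim(raw[[3]]), c(2, 3, 3, 3, 7))
  m5 <- build_cr_yolov5s(tiny_cfg(img_size = 96, nc = 5))
  expect_equal(m5$head[[1]]$cout, 30)
  expect_error(forward_raw(m, array(0, c(64, 64, 3, 1))), "letterboxed")
  # eval-mode forward is bitwise deterministic
  expect_identical(raw, forward_raw(m, x))
})

test_that("ablation baseline has no inserted blocks; the improved model has exactly the configured ones", {
  base <- build_cr_yolov5s(tiny_cfg(coordatt_sites = integer(0),
                                    repvgg_sites = integer(0)))
  expect_equal(unname(count_module_types(base)), c(0L, 0L))
  impr <- build_cr_yolov5s(tiny_cfg(coordatt_sites = c(3, 4),
                                    repvgg_sites = 1:4))
  expect_equal(unname(count_module_types(impr)), c(4L, 2L))
  one <- build_cr_yolov5s(tiny_cfg(coordatt_sites = 2, repvgg_sites = c(1, 3)))
  expect_equal(unname(count_module_types(one)), c(2L, 1L))
})

test_that("NMS suppresses by IoU and agrees with a brute-force oracle", {
  b <- matrix(c(0, 0, 10, 10), 1)
  two <- rbind(b, b)
  expect_equal(cryolo:::nms_boxes(two, c(0.9, 0.8), 0.45), 1L)
  disj <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30))
  expect_equal(sort(cryolo:::nms_boxes(disj, c(0.9, 0.8), 0.45)), c(1L, 2L))
  set.seed(42)
  for (k in 1:5) {
    n <- 50
    x1 <- runif(n, 0, 80); y1 <- runif(n, 0, 80)
    boxes <- cbind(x1, y1, x1 + runif(n, 5, 30), y1 + runif(n, 5, 30))
    scores <- sample(seq(0.01, 0.99, by = 1e-3), n)
    mine <- sort(cryolo:::nms_boxes(boxes, scores, 0.45))
    ref <- sort(brute_nms(boxes, scores, 0.45))
    expect_equal(mine, ref)
  }
})

test_that("decoding respects thresholds, ordering and determinism", {
  set.seed(43)
  m <- build_cr_yolov5s(tiny_cfg(img_size = 96))
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  raw <- cryolo:::forward_detector(m, x)
  dets <- decode_and_nms(m, raw, conf_thresh = 0.001, iou_thresh = 0.45)
  d <- dets[[1]]
  expect_true(all(diff(d$conf) <= 0))
  expect_true(all(d$x2 > d$x1 & d$y2 > d$y1))
  expect_lte(nrow(d), 300)
  expect_identical(dets, decode_and_nms(m, raw, 0.001, 0.45))
  high <- decode_and_nms(m, raw, conf_thresh = 0.99)[[1]]
  expect_equal(nrow(high), 0)
  expect_error(decode_and_nms(m, raw, conf_thresh = 2))
})

test_that("the loss vanishes on its box term for anchor-shaped, cell-centred targets", {
  cfg <- tiny_cfg(img_size = 96)
  cfg$hyp$anchor_t <- 1.5 # only the exact anchor matches
  m <- build_cr_yolov5s(cfg)
  nc <- 2
  raw <- lapply(c(12, 6, 3), function(g)
    array(0, c(g, g, 3 * (5 + nc), 1)))
  # target exactly the second anchor of the middle scale, centred in a cell
  aw <- m$cfg$anchors[[2]][2, 1]; ah <- m$cfg$anchors[[2]][2, 2]
  tgt <- data.frame(image = 1, class = 0L,
                    cx = (2 + 0.5) / 6, cy = (3 + 0.5) / 6,
                    w = aw / 96, h = ah / 96)
  l <- compute_loss(m, raw, tgt)
  expect_lt(abs(l$box), 1e-6) # bounded by the CIoU stabilizer epsilon
  expect_gt(l$obj, 0)
  expect_gt(l$cls, 0)
  # no targets: box and cls terms are exactly zero
  l0 <- compute_loss(m, raw, tgt[0, ])
  expect_identical(l0$box, 0)
  expect_identical(l0$cls, 0)
  expect_gt(l0$obj, 0)
  expect_equal(l0$total, l0$obj * m$cfg$hyp$obj)
  expect_error(compute_loss(m, raw, transform(tgt, class = 5L)),
               "class")
})

test_that("loss gradients match finite differences on a one-target toy", {
  set.seed(44)
  m <- build_cr_yolov5s(tiny_cfg(img_size = 96))
  raw <- lapply(c(12, 6, 3), function(g)
    array(rnorm(g * g * 21, sd = 0.5), c(g, g, 21, 1)))
  tgt <- data.frame(image = 1, class = 1L, cx = 0.4, cy = 0.55,
                    w = 0.3, h = 0.2)
  leaves <- lapply(raw, cryolo:::ag_leaf)
  l <- with_grad(compute_loss(m, leaves, tgt))
  ag_backward(l$total)
  for (s in 1:3) {
    g <- leaves[[s]]$grad
    idx <- order(-abs(g))[1:5]
    for (i in idx) {
      v0 <- leaves[[s]]$value[i]
      eps <- 1e-6
      leaves[[s]]$value[i] <- v0 + eps
      lp <- cryolo:::ag_value(compute_loss(m, leaves, tgt)$total)
      leaves[[s]]$value[i] <- v0 - eps
      lm <- cryolo:::ag_value(compute_loss(m, leaves, tgt)$total)
      leaves[[s]]$value[i] <- v0
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(fd - g[i]) / max(1e-8, abs(fd) + abs(g[i])), 1e-3)
    }
  }
})

test_that("checkpoints round-trip both model modes", {
  set.seed(45)
  m <- build_cr_yolov5s(tiny_cfg(img_size = 96))
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  r1 <- forward_raw(m, x)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_equal(forward_raw(m2, x), r1, tolerance = 1e-14)
  fused <- reparameterize_model(m)
  save_checkpoint(fused, p)
  m3 <- load_checkpoint(p)
  expect_identical(m3$mode, "fused")
  for (s in 1:3)
    expect_lt(max(abs(forward_raw(m3, x)[[s]] - r1[[s]])), 1e-10)
  unlink(p)
})
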