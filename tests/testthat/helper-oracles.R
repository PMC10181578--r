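# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately written as plain scalar loops / brute force,
# independent of the package's vectorized implementation paths.

# short aliases for internal engine entry points used by the tests
with_grad <- cryolo:::with_grad
ag_mean <- cryolo:::ag_mean
ag_backward <- cryolo:::ag_backward

tiny_cfg <- function(img_size = 96, nc = 2, ...) {
  cryolo_config(nc = nc, img_size = img_size, width_multiple = 0.125,
                depth_multiple = 0.33, ...)
}

rand_fmap <- function(h, w, c, b = 1) array(rnorm(h * w * c * b), c(h, w, c, b))

# scalar-loop 2-D convolution (cross-correlation), layout (H,W,C,B)
naive_conv <- function(x, w, bias, stride, pad, groups = 1) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  kh <- wd[1]; kw <- wd[2]; Cg <- wd[3]; Cout <- wd[4]
  Coutg <- Cout / groups
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  out <- array(0, c(Ho, Wo, Cout, B))
  for (b_ in 1:B) for (co in 1:Cout) {
    g <- (co - 1) %/% Coutg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      s <- if (length(bias)) bias[co] else 0
      for (c_ in 1:Cg) for (i in 1:kh) for (j in 1:kw) {
        hi <- (ho - 1) * stride - pad + i
        wi <- (wo - 1) * stride - pad + j
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          s <- s + x[hi, wi, g * Cg + c_, b_] * w[i, j, c_, co]
      }
      out[ho, wo, co, b_] <- s
    }
  }
  out
}

# scalar-loop transcription of the coordinate-attention equations,
# using the weights stored on a coord_att module (eval-mode BN)
coordatt_oracle <- function(m, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  mid <- m$mid
  conv1x1 <- function(v, wmat, bias) {
    # v: (len, channels); wmat: (1,1,cin,cout) kernel
    cin <- dim(wmat)[3]; cout <- dim(wmat)[4]
    out <- matrix(0, nrow(v), cout)
    for (o in 1:cout) {
      s <- if (length(bias)) bias[o] else 0
      acc <- rep(s, nrow(v))
      for (ci in 1:cin) acc <- acc + v[, ci] * wmat[1, 1, ci, o]
      out[, o] <- acc
    }
    out
  }
  out <- array(0, dim(x))
  for (b in 1:B) {
    zh <- matrix(0, H, C); zw <- matrix(0, W, C)
    for (c_ in 1:C) {
      for (h in 1:H) zh[h, c_] <- mean(x[h, , c_, b])
      for (w_ in 1:W) zw[w_, c_] <- mean(x[, w_, c_, b])
    }
    zcat <- rbind(zh, zw)                         # (H+W, C)
    f <- conv1x1(zcat, m$conv1$weight$value,
                 if (is.null(m$conv1$bias)) numeric(0)
                 else m$conv1$bias$value)
    if (!is.null(m$conv1$bn)) {
      bn <- m$conv1$bn
      for (o in 1:mid)
        f[, o] <- (f[, o] - bn$running_mean[o]) /
          sqrt(bn$running_var[o] + bn$eps) * bn$gamma$value[o] +
          bn$beta$value[o]
    }
    f <- f * plogis(f)                            # SiLU nonlinearity
    fh <- f[1:H, , drop = FALSE]
    fw <- f[H + (1:W), , drop = FALSE]
    gh <- plogis(conv1x1(fh, m$conv_h$weight$value, m$conv_h$bias$value))
    gw <- plogis(conv1x1(fw, m$conv_w$weight$value, m$conv_w$bias$value))
    for (c_ in 1:C) for (i in 1:H) for (j in 1:W)
      out[i, j, c_, b] <- x[i, j, c_, b] * gh[i, c_] * gw[j, c_]
  }
  out
}

# O(n^2) brute-force greedy NMS
brute_nms <- function(boxes, scores, thr) {
  alive <- rep(TRUE, length(scores))
  keep <- integer(0)
  while (any(alive)) {
    i <- which(alive)[which.max(scores[alive])]
    keep <- c(keep, i)
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (iou(boxes[i, ], boxes[j, ]) > thr) alive[j] <- FALSE
    }
  }
  keep
}

# independent AP evaluator: scans confidence thresholds, re-matches the
# kept subset from scratch each time, and integrates the precision
# envelope over recall increments
brute_ap <- function(dets, gts, iou_thresh = 0.5) {
  if (nrow(gts) == 0 || nrow(dets) == 0) return(0)
  match_subset <- function(sub) {
    used <- rep(FALSE, nrow(gts))
    tp <- 0L
    for (k in order(-sub$conf)) {
      best <- 0; best_g <- 0
      for (g in seq_len(nrow(gts))) {
        if (used[g] || gts$image[g] != sub$image[k] ||
            gts$class[g] != sub$class[k]) next
        i <- iou(c(sub$x1[k], sub$y1[k], sub$x2[k], sub$y2[k]),
                 c(gts$x1[g], gts$y1[g], gts$x2[g], gts$y2[g]))
        if (i > best) { best <- i; best_g <- g }
      }
      if (best_g > 0 && best >= iou_thresh) { tp <- tp + 1L; used[best_g] <- TRUE }
    }
    tp
  }
  ths <- sort(unique(dets$conf), decreasing = TRUE)
  pr <- t(vapply(ths, function(th) {
    sub <- dets[dets$conf >= th, , drop = FALSE]
    tp <- match_subset(sub)
    c(p = tp / nrow(sub), r = tp / nrow(gts))
  }, c(p = 0, r = 0)))
  ap <- 0
  r_prev <- 0
  for (k in seq_len(nrow(pr))) {
    if (pr[k, "r"] > r_prev) {
      env <- max(pr[k:nrow(pr), "p"])
      ap <- ap + (pr[k, "r"] - r_prev) * env
      r_prev <- pr[k, "r"]
    }
  }
  ap
}

# random small detection/GT instance on a few images
rand_instance <- function(n_img = 3, n_gt = 6, n_det = 10, nc = 2) {
  gts <- data.frame(
    image = sample.int(n_img, n_gt, replace = TRUE),
    class = sample.int(nc, n_gt, replace = TRUE) - 1L,
    x1 = runif(n_gt, 0, 60), y1 = runif(n_gt, 0, 60))
  gts$x2 <- gts$x1 + runif(n_gt, 8, 30)
  gts$y2 <- gts$y1 + runif(n_gt, 8, 30)
  base <- gts[sample.int(n_gt, n_det, replace = TRUE), ]
  jit <- function(v, s) v + rnorm(n_det, 0, s)
  dets <- data.frame(
    image = base$image,
    class = ifelse(runif(n_det) < 0.85, base$class,
                   sample.int(nc, n_det, replace = TRUE) - 1L),
    conf = sample(seq(0.01, 0.99, by = 1e-3), n_det), # distinct confidences
    x1 = jit(base$x1, 4), y1 = jit(base$y1, 4),
    x2 = jit(base$x2, 4), y2 = jit(base$y2, 4))
  sw <- dets$x2 <= dets$x1; dets$x2[sw] <- dets$x1[sw] + 1
  sh <- dets$y2 <= dets$y1; dets$y2[sh] <- dets$y1[sh] + 1
  list(dets = dets, gts = gts)
}

overfit_spec <- function(seed = 3) {
  scene_spec(canvas = 160, n_flowers = c(3, 6), bloom_radius = c(12, 22),
             bud_radius = c(5, 9), seed = seed)
}

# the desk-scale training profile used for CPU capacity checks
desk_hyp <- function(epochs = 50, batch_size = 4) {
  default_hyp(mosaic = FALSE, batch_size = batch_size, epochs = epochs,
              lr = 0.02, box = 0.5)
}
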