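# Seeded generator of chrysanthemum-like scenes with exact ground truth.
#
# The generator emulates the data regime of the greenhouse study the
# package is built around: top-down views of a bed of yellow
# chrysanthemums with two developmental classes — small green-yellow
# buds and larger radially-petalled open blooms (class imbalance about
# 939:326 bud:blooming) — partially covered by foliage, with optional
# low-light variants. Bounding boxes are recorded from the rendered
# flower support *before* occluders are drawn, mirroring how a human
# annotator labels a partially covered flower.

#' Synthetic scene specification
#'
#' @param canvas canvas side length in pixels
#' @param n_flowers integer range `c(min, max)` of flowers per scene
#' @param p_bud probability that a flower is a bud (default 939/1265,
#'   the target class imbalance)
#' @param bloom_radius,bud_radius pixel radius ranges
#' @param petals petal-count range for blooms
#' @param occluders range of foliage occluders per scene
#' @param occluder_opacity opacity of foliage over flowers
#' @param max_occlusion cap on the fraction of any flower covered by
#'   foliage (occluders that would exceed it are skipped)
#' @param brightness luminance multiplier range; `low_light = TRUE`
#'   switches to 0.3-0.6 (a weak-light regime)
#' @param low_light logical
#' @param noise_sd additive Gaussian pixel noise
#' @param clustering 0 for uniform flower placement; > 0 draws positions
#'   around a few cluster centers with this spread (pixels)
#' @param seed RNG seed used by [generate_dataset()]
#' @return list of class "scene_spec"
#' @export
scene_spec <- function(canvas = 320, n_flowers = c(4, 9),
                       p_bud = 939 / 1265,
                       bloom_radius = c(18, 34), bud_radius = c(6, 13),
                       petals = c(8, 13), occluders = c(2, 6),
                       occluder_opacity = 0.85, max_occlusion = 0.6,
                       brightness = c(0.9, 1.1), low_light = FALSE,
                       noise_sd = 0.02, clustering = 0, seed = 0) {
  if (low_light) brightness <- c(0.3, 0.6)
  stopifnot(all(bloom_radius > 0), all(bud_radius > 0), p_bud > 0,
            p_bud < 1, all(brightness > 0))
  if (canvas <= 2 * (max(bloom_radius) + 2))
    stop("canvas too small for radii")
  structure(list(canvas = canvas, n_flowers = n_flowers, p_bud = p_bud,
                 bloom_radius = bloom_radius, bud_radius = bud_radius,
                 petals = petals, occluders = occluders,
                 occluder_opacity = occluder_opacity,
                 max_occlusion = max_occlusion, brightness = brightness,
                 noise_sd = noise_sd, clustering = clustering, seed = seed),
            class = "scene_spec")
}

rrange <- function(r) if (length(r) == 2) runif(1, r[1], r[2]) else r
irange <- function(r) if (length(r) == 2) sample(r[1]:r[2], 1) else r

# radial petal-star mask and colouring around (cx, cy); returns the
# support mask (canvas-sized logical) and paints onto img in place
draw_flower <- function(img, cx, cy, radius, kind, petals = 10) {
  d <- dim(img)
  x1 <- max(1, floor(cx - radius)); x2 <- min(d[2], ceiling(cx + radius))
  y1 <- max(1, floor(cy - radius)); y2 <- min(d[1], ceiling(cy + radius))
  xs <- x1:x2; ys <- y1:y2
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  rr <- sqrt(dx^2 + dy^2)
  if (kind == "bud") {
    ecc <- runif(1, 0.85, 1.15)
    mask <- (dx / ecc)^2 + (dy * ecc)^2 <= radius^2
    base <- c(0.52, 0.62, 0.20) + runif(3, -0.05, 0.05)
    shade <- 1 - 0.35 * (rr / radius)^2
  } else {
    th <- atan2(dy, dx)
    rmax <- radius * (0.55 + 0.45 * abs(cos(petals * th / 2))^0.8)
    mask <- rr <= rmax
    base <- c(0.97, 0.80, 0.12) + c(runif(1, -0.05, 0.03),
                                    runif(1, -0.08, 0.05),
                                    runif(1, -0.04, 0.06))
    shade <- 1 - 0.25 * (rr / radius)
    core <- rr <= 0.28 * radius
  }
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    col <- pmin(pmax(base[ch] * shade, 0), 1)
    plane[mask] <- col[mask]
    if (kind == "bloom") {
      core_col <- c(0.85, 0.55, 0.08)[ch]
      plane[core] <- core_col * (1 - 0.3 * (rr[core] / (0.28 * radius)))
    }
    img[ys, xs, ch] <- plane
  }
  full <- matrix(FALSE, d[1], d[2])
  full[ys, xs] <- mask
  list(img = img, mask = full)
}

draw_leaf <- function(img, cx, cy, a, b, phi, opacity) {
  d <- dim(img)
  r <- max(a, b)
  x1 <- max(1, floor(cx - r)); x2 <- min(d[2], ceiling(cx + r))
  y1 <- max(1, floor(cy - r)); y2 <- min(d[1], ceiling(cy + r))
  xs <- x1:x2; ys <- y1:y2
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  col <- c(0.10, 0.34, 0.10) + runif(3, -0.04, 0.04)
  vein <- 1 - 0.3 * abs(v) / b
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    lc <- pmin(pmax(col[ch] * vein, 0), 1)
    plane[mask] <- (1 - opacity) * plane[mask] + opacity * lc[mask]
    img[ys, xs, ch] <- plane
  }
  full <- matrix(FALSE, d[1], d[2])
  full[ys, xs] <- mask
  list(img = img, mask = full)
}

#' Render one synthetic chrysanthemum scene
#'
#' Uses the current RNG state; see [generate_dataset()] for seeded
#' dataset generation.
#'
#' @param spec a [scene_spec()]
#' @return labelled image: `list(image, boxes)`; boxes are normalized
#'   `class, cx, cy, w, h` rows (class 0 = bud, 1 = blooming) recorded
#'   from the pre-occlusion pixel support of each flower
#' @export
render_scene <- function(spec) {
  s <- spec$canvas
  # mottled soil/foliage background
  img <- array(0, c(s, s, 3))
  base <- c(0.16, 0.22, 0.10)
  tex <- matrix(runif(s * s, -0.05, 0.05), s, s)
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + tex, 0), 1)
  for (k in seq_len(irange(c(6, 12)))) {
    lf <- draw_leaf(img, runif(1, 1, s), runif(1, 1, s),
                    runif(1, s / 10, s / 4), runif(1, s / 20, s / 8),
                    runif(1, 0, pi), 1)
    img <- lf$img
  }
  n <- irange(spec$n_flowers)
  boxes <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  masks <- list()
  centers <- NULL
  if (n > 0 && spec$clustering > 0) {
    k <- sample(1:3, 1)
    centers <- cbind(runif(k, 0.25 * s, 0.75 * s),
                     runif(k, 0.25 * s, 0.75 * s))
  }
  for (i in seq_len(n)) {
    is_bud <- runif(1) < spec$p_bud
    radius <- rrange(if (is_bud) spec$bud_radius else spec$bloom_radius)
    m <- radius + 2
    if (is.null(centers)) {
      cx <- runif(1, m, s - m); cy <- runif(1, m, s - m)
    } else {
      ct <- centers[sample(nrow(centers), 1), ]
      cx <- min(max(ct[1] + rnorm(1, 0, spec$clustering), m), s - m)
      cy <- min(max(ct[2] + rnorm(1, 0, spec$clustering), m), s - m)
    }
    fl <- draw_flower(img, cx, cy, radius,
                      if (is_bud) "bud" else "bloom",
                      petals = irange(spec$petals))
    img <- fl$img
    masks[[i]] <- fl$mask
    rows <- range(which(rowSums(fl$mask) > 0))
    cols <- range(which(colSums(fl$mask) > 0))
    boxes <- rbind(boxes, data.frame(
      class = if (is_bud) 0L else 1L,
      cx = mean(cols) / s, cy = mean(rows) / s,
      w = (cols[2] - cols[1] + 1) / s, h = (rows[2] - rows[1] + 1) / s))
  }
  # occluding foliage, drawn after the flowers; per-flower occlusion
  # capped so objects stay learnable
  occluded <- vapply(masks, function(m) 0, numeric(1))
  area <- vapply(masks, sum, numeric(1))
  for (k in seq_len(irange(spec$occluders))) {
    a <- runif(1, s / 12, s / 5); b <- runif(1, s / 24, s / 10)
    lcx <- runif(1, 1, s); lcy <- runif(1, 1, s)
    phi <- runif(1, 0, pi)
    lf <- draw_leaf(img, lcx, lcy, a, b, phi, spec$occluder_opacity)
    if (length(masks)) {
      add <- vapply(masks, function(m) sum(m & lf$mask), numeric(1))
      if (any((occluded + add) / pmax(area, 1) > spec$max_occlusion)) next
      occluded <- occluded + add
    }
    img <- lf$img
  }
  img <- img * rrange(spec$brightness)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  list(image = pmin(pmax(img, 0), 1), boxes = boxes)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `images/NNNN.png`, `labels/NNNN.txt` and a `data.yaml`
#' manifest in the YOLO layout. Fully determined by `spec$seed`.
#'
#' @param n_images number of scenes
#' @param spec a [scene_spec()]
#' @param out_dir output directory (created if missing)
#' @return list: `manifest` (path), `counts` (named per-class box
#'   counts), `n_images`
#' @export
generate_dataset <- function(n_images, spec, out_dir) {
  stopifnot(n_images >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(spec$seed)
  counts <- c(bud = 0L, blooming = 0L)
  for (i in seq_len(n_images)) {
    sc <- render_scene(spec)
    stem <- sprintf("%04d", i)
    write_image(sc$image, file.path(out_dir, "images",
                                    paste0(stem, ".png")))
    write_yolo_labels(file.path(out_dir, "labels", paste0(stem, ".txt")),
                      sc$boxes)
    counts["bud"] <- counts["bud"] + sum(sc$boxes$class == 0)
    counts["blooming"] <- counts["blooming"] + sum(sc$boxes$class == 1)
  }
  manifest <- file.path(out_dir, "data.yaml")
  yaml::write_yaml(list(names = c("bud", "blooming"),
                        nc = 2L, images = "images", labels = "labels"),
                   manifest)
  list(manifest = manifest, counts = counts, n_images = n_images)
}

#' Color-threshold baseline detector
#'
#' A deliberately simple non-learned detector used as a sanity floor for
#' the evaluation stack: thresholds warm (yellow-green) pixels,
#' extracts connected components, classifies each by its red/green
#' balance and scores by component size.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`
#' @param min_area smallest component kept, pixels
#' @return data frame `class, conf, x1, y1, x2, y2` (pixels)
#' @export
color_threshold_detector <- function(img, min_area = 20) {
  d <- dim(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mask <- (r > 0.42 & g > 0.35 & b < 0.5) & (r + g > 2.2 * b)
  lab <- label_components(mask)
  out <- list()
  for (k in seq_len(max(lab))) {
    pix <- which(lab == k, arr.ind = TRUE)
    if (nrow(pix) < min_area) next
    cls <- if (mean(r[pix]) >= mean(g[pix])) 1L else 0L
    out[[length(out) + 1L]] <- data.frame(
      class = cls, conf = min(1, nrow(pix) / 400),
      x1 = min(pix[, 2]) - 1, y1 = min(pix[, 1]) - 1,
      x2 = max(pix[, 2]), y2 = max(pix[, 1]))
  }
  if (!length(out)) {
    return(data.frame(class = integer(0), conf = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0)))
  }
  do.call(rbind, out)
}

# 4-connected component labelling (iterative flood fill)
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nextl <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextl <- nextl + 1L
    queue <- start
    lab[start] <- nextl
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% d[1] + 1L
      j <- (p - 1L) %/% d[1] + 1L
      nb <- c(if (i > 1) p - 1L, if (i < d[1]) p + 1L,
              if (j > 1) p - d[1], if (j < d[2]) p + d[1])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextl
      queue <- c(queue, nb)
    }
  }
  lab
}
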