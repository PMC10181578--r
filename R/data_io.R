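# Dataset handling: YOLO-format label I/O, deterministic 9:1/9:1
# splitting, aspect-preserving letterbox resize, and mosaic
# augmentation.
#
# A labelled image is list(image = path or (H,W,3) array,
# boxes = data.frame(class, cx, cy, w, h)) with normalized coordinates.

#' Read / write YOLO-format label files
#'
#' One `class cx cy w h` line per box, whitespace-separated, all
#' coordinates normalized to `[0, 1]`. A missing file means zero boxes.
#' Out-of-range coordinates are clipped with a warning; malformed lines
#' are an error naming the line.
#'
#' @param path label file path
#' @return `read_yolo_labels`: data frame with columns
#'   `class, cx, cy, w, h`
#' @export
read_yolo_labels <- function(path) {
  empty <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(tok) != 5 || anyNA(vals))
      stop("malformed label line ", i, " in ", path, ": '", lines[i], "'")
    vals
  })
  m <- do.call(rbind, rows)
  df <- data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                   w = m[, 4], h = m[, 5])
  coords <- as.matrix(df[, c("cx", "cy", "w", "h")])
  if (any(coords < 0) || any(coords > 1)) {
    warning("out-of-range label coordinates clipped in ", path)
    df[, c("cx", "cy", "w", "h")] <- pmin(pmax(coords, 0), 1)
  }
  df
}

#' @param boxes data frame or matrix with columns `class, cx, cy, w, h`
#' @rdname read_yolo_labels
#' @export
write_yolo_labels <- function(path, boxes) {
  boxes <- as.data.frame(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", as.integer(boxes$class),
                   boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic train/validation/test split
#'
#' Shuffles with the given seed, holds out floor(n/10) items as the test
#' set, then floor of a tenth of the remainder as validation; the rest is
#' training data (the 9:1 / 9:1 convention).
#'
#' @param items vector or list of dataset items
#' @param seed integer RNG seed
#' @param stratify_by optional factor (same length) to stratify the
#'   shuffle+split within groups
#' @return list with `train`, `val`, `test`
#' @export
split_dataset <- function(items, seed, stratify_by = NULL) {
  n <- length(items)
  if (n < 10) stop("need at least 10 items to split 9:1/9:1")
  pick <- function(idx) {
    n <- length(idx)
    n_test <- floor(n / 10)
    n_val <- floor((n - n_test) / 10)
    list(test = idx[seq_len(n_test)],
         val = idx[n_test + seq_len(n_val)],
         train = idx[-seq_len(n_test + n_val)])
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  if (is.null(stratify_by)) {
    parts <- pick(sample.int(n))
  } else {
    stopifnot(length(stratify_by) == n)
    parts <- list(test = integer(0), val = integer(0), train = integer(0))
    for (g in unique(stratify_by)) {
      idx <- which(stratify_by == g)
      p <- pick(idx[sample.int(length(idx))])
      parts <- Map(c, parts, p)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  sel <- function(idx) if (is.list(items)) items[idx] else items[idx]
  list(train = sel(sort(parts$train)), val = sel(sort(parts$val)),
       test = sel(sort(parts$test)))
}

#' Read an image file as a numeric (H, W, 3) array in [0, 1]
#' @param path PNG or JPEG file
#' @return numeric array
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = , jpeg = jpeg::readJPEG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a numeric (H, W, 3) array in [0, 1] as PNG
#' @param img array
#' @param path output path
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# separable bilinear resize of an (H, W, C) array
resize_bilinear <- function(img, nh, nw) {
  d <- dim(img)
  if (d[1] == nh && d[2] == nw) return(img)
  interp_axis <- function(n_src, n_dst) {
    src <- (seq_len(n_dst) - 0.5) * n_src / n_dst + 0.5
    src <- pmin(pmax(src, 1), n_src)
    lo <- pmin(floor(src), n_src - 1L)
    if (n_src == 1) lo <- rep(1, n_dst)
    list(lo = as.integer(lo), frac = src - lo)
  }
  ay <- interp_axis(d[1], nh)
  ax <- interp_axis(d[2], nw)
  out <- array(0, c(nh, nw, d[3]))
  hi_y <- pmin(ay$lo + 1L, d[1])
  hi_x <- pmin(ax$lo + 1L, d[2])
  for (c in seq_len(d[3])) {
    p <- img[, , c]
    top <- p[ay$lo, , drop = FALSE] * (1 - ay$frac) +
      p[hi_y, , drop = FALSE] * ay$frac
    out[, , c] <- top[, ax$lo, drop = FALSE] * rep(1 - ax$frac, each = nh) +
      top[, hi_x, drop = FALSE] * rep(ax$frac, each = nh)
  }
  out
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize followed by symmetric gray padding.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`
#' @param target output side length in pixels (divisible by 32)
#' @param fill pad value (YOLO convention 114/255 gray)
#' @return list: `image` (`(target, target, 3)`), `scale` (resize
#'   factor), `pad` (`c(top, left)` in pixels), `orig` (`c(H, W)`).
#'   A box maps into the letterboxed frame as `x * scale + pad[2]`
#'   (and back within 1 px).
#' @export
letterbox <- function(img, target, fill = 114 / 255) {
  stopifnot(target %% 32 == 0)
  d <- dim(img)
  scale <- min(target / d[1], target / d[2])
  nh <- round(d[1] * scale); nw <- round(d[2] * scale)
  resized <- resize_bilinear(img, nh, nw)
  out <- array(fill, c(target, target, 3))
  top <- floor((target - nh) / 2); left <- floor((target - nw) / 2)
  out[top + seq_len(nh), left + seq_len(nw), ] <- resized
  list(image = out, scale = scale, pad = c(top = top, left = left),
       orig = d[1:2])
}

#' Mosaic augmentation
#'
#' Combines four labelled images into one canvas: a random center point
#' splits the canvas into quadrants, each source image is scaled (with
#' jitter) to its quadrant and cropped at the canvas borders; boxes are
#' remapped, clipped, and dropped when a clipped side falls under
#' `min_side` pixels.
#'
#' @param items list of 4 labelled images (`list(image, boxes)`; `image`
#'   may be a path or array)
#' @param out_size canvas side length in pixels
#' @param center optional `c(x, y)` canvas center in pixels (random when
#'   NULL; drawn from the middle 40 percent of the canvas)
#' @param scale_jitter range of the per-image scale jitter factor
#' @param min_side minimum surviving box side after clipping, pixels
#' @return labelled image: `list(image, boxes)` with normalized boxes
#' @export
mosaic_augment <- function(items, out_size, center = NULL,
                           scale_jitter = c(0.6, 1.2), min_side = 2) {
  stopifnot(length(items) == 4)
  s <- out_size
  if (is.null(center)) {
    center <- round(runif(2, 0.3 * s, 0.7 * s))
  }
  cx <- center[1]; cy <- center[2]
  canvas <- array(114 / 255, c(s, s, 3))
  boxes <- list()
  # quadrant corner at the center: (x2,y2), (x1,y2), (x2,y1), (x1,y1)
  for (q in 1:4) {
    it <- items[[q]]
    img <- if (is.character(it$image)) read_image(it$image) else it$image
    d <- dim(img)
    f <- runif(1, scale_jitter[1], scale_jitter[2]) * s / max(d[1:2])
    nh <- max(1, round(d[1] * f)); nw <- max(1, round(d[2] * f))
    img <- resize_bilinear(img, nh, nw)
    # top-left placement of the scaled image on the (unbounded) canvas
    x1 <- switch(q, cx - nw, cx, cx - nw, cx)
    y1 <- switch(q, cy - nh, cy - nh, cy, cy)
    # visible region on the canvas
    vx1 <- max(x1, 0); vy1 <- max(y1, 0)
    vx2 <- min(x1 + nw, s); vy2 <- min(y1 + nh, s)
    if (vx2 > vx1 && vy2 > vy1) {
      canvas[(vy1 + 1):vy2, (vx1 + 1):vx2, ] <-
        img[(vy1 - y1 + 1):(vy2 - y1), (vx1 - x1 + 1):(vx2 - x1), ,
            drop = FALSE]
    }
    bx <- it$boxes
    if (!is.null(bx) && nrow(bx)) {
      px1 <- (bx$cx - bx$w / 2) * nw + x1
      px2 <- (bx$cx + bx$w / 2) * nw + x1
      py1 <- (bx$cy - bx$h / 2) * nh + y1
      py2 <- (bx$cy + bx$h / 2) * nh + y1
      px1 <- pmin(pmax(px1, 0), s); px2 <- pmin(pmax(px2, 0), s)
      py1 <- pmin(pmax(py1, 0), s); py2 <- pmin(pmax(py2, 0), s)
      keep <- (px2 - px1) >= min_side & (py2 - py1) >= min_side
      if (any(keep)) {
        boxes[[length(boxes) + 1L]] <- data.frame(
          class = bx$class[keep],
          cx = (px1[keep] + px2[keep]) / 2 / s,
          cy = (py1[keep] + py2[keep]) / 2 / s,
          w = (px2[keep] - px1[keep]) / s,
          h = (py2[keep] - py1[keep]) / s)
      }
    }
  }
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
               w = numeric(0), h = numeric(0))
  list(image = canvas, boxes = boxes)
}

#' Load a dataset manifest
#'
#' The manifest is a YAML file with fields `names` (class labels),
#' `images` and `labels` (directories, relative to the manifest).
#'
#' @param path manifest path
#' @return list with `names`, `nc`, and `items` (each
#'   `list(image, labels_path, boxes)`)
#' @export
load_dataset <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  img_dir <- file.path(base, man$images)
  lab_dir <- file.path(base, man$labels)
  imgs <- sort(list.files(img_dir, pattern = "\\.(png|jpe?g)$",
                          ignore.case = TRUE, full.names = TRUE))
  if (!length(imgs)) stop("no images found under ", img_dir)
  items <- lapply(imgs, function(p) {
    lp <- file.path(lab_dir,
                    paste0(tools::file_path_sans_ext(basename(p)), ".txt"))
    list(image = p, labels_path = lp, boxes = read_yolo_labels(lp))
  })
  list(names = unlist(man$names), nc = length(man$names), items = items)
}

# ground truth of a dataset in pixel xyxy coordinates (original frames)
dataset_ground_truth <- function(items) {
  rows <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    b <- it$boxes
    if (is.null(b) || !nrow(b)) return(NULL)
    d <- dim(if (is.character(it$image)) read_image(it$image) else it$image)
    data.frame(image = i, class = b$class,
               x1 = (b$cx - b$w / 2) * d[2], y1 = (b$cy - b$h / 2) * d[1],
               x2 = (b$cx + b$w / 2) * d[2], y2 = (b$cy + b$h / 2) * d[1])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("dataset has no ground-truth boxes")
  out
}
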