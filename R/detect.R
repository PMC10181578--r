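# Anchor decoding and non-maximum suppression.

# greedy NMS; boxes is a matrix with columns x1,y1,x2,y2
nms_boxes <- function(boxes, scores, iou_thresh) {
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (!length(ord)) break
    ious <- iou_one_many(boxes[i, ], boxes[ord, , drop = FALSE])
    ord <- ord[ious <= iou_thresh]
  }
  keep
}

#' Decode raw head outputs and apply per-class NMS
#'
#' Applies the logistic box/objectness/class decoding against the anchor
#' grid, keeps candidates with `objectness * class score >=
#' conf_thresh`, and runs greedy per-class NMS.
#'
#' @param m a "cryolo_model"
#' @param raw list of 3 head maps as produced internally (arrays
#'   `(Hg, Wg, 3*(5+nc), B)`); see [predict.cryolo_model()] for the
#'   user-level entry point
#' @param conf_thresh,iou_thresh confidence and NMS IoU thresholds in
#'   `[0, 1]`
#' @param max_det per-image detection cap
#' @return list (one per image) of data frames with columns
#'   `class, conf, x1, y1, x2, y2` (letterboxed-pixel coordinates),
#'   sorted by decreasing confidence
#' @export
decode_and_nms <- function(m, raw, conf_thresh = 0.25, iou_thresh = 0.45,
                           max_det = 300) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1,
            iou_thresh >= 0, iou_thresh <= 1)
  nc <- m$cfg$nc
  B <- dim(raw[[1]])[4]
  cand <- vector("list", 3L)
  for (s in 1:3) {
    arr <- raw[[s]]
    d <- dim(arr)
    Hg <- d[1]; Wg <- d[2]
    st <- m$strides[s]
    gx <- array(rep(0:(Wg - 1), each = Hg), c(Hg, Wg, 1, B))
    gy <- array(rep(0:(Hg - 1), times = Wg), c(Hg, Wg, 1, B))
    rows <- list()
    for (a in 1:3) {
      off <- (a - 1L) * (5L + nc)
      sx <- plogis(arr[, , off + 1L, , drop = FALSE])
      sy <- plogis(arr[, , off + 2L, , drop = FALSE])
      sw <- plogis(arr[, , off + 3L, , drop = FALSE])
      sh <- plogis(arr[, , off + 4L, , drop = FALSE])
      obj <- plogis(arr[, , off + 5L, , drop = FALSE])
      bx <- (2 * sx - 0.5 + gx) * st
      by <- (2 * sy - 0.5 + gy) * st
      bw <- (2 * sw)^2 * m$cfg$anchors[[s]][a, 1]
      bh <- (2 * sh)^2 * m$cfg$anchors[[s]][a, 2]
      cls <- array(plogis(arr[, , off + 5L + seq_len(nc), , drop = FALSE]),
                   c(Hg * Wg, nc, B))
      for (b in 1:B) {
        cm <- cls[, , b, drop = FALSE]
        dim(cm) <- c(Hg * Wg, nc)
        best <- max.col(cm, ties.method = "first")
        score <- as.vector(obj[, , 1, b]) * cm[cbind(seq_len(Hg * Wg), best)]
        keep <- which(score >= conf_thresh)
        if (!length(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          image = b, class = best[keep] - 1L, conf = score[keep],
          cx = as.vector(bx[, , 1, b])[keep],
          cy = as.vector(by[, , 1, b])[keep],
          w = as.vector(bw[, , 1, b])[keep],
          h = as.vector(bh[, , 1, b])[keep])
      }
    }
    cand[[s]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  all <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  out <- vector("list", B)
  empty <- data.frame(class = integer(0), conf = numeric(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0))
  for (b in 1:B) {
    db <- if (is.null(all)) NULL else all[all$image == b, , drop = FALSE]
    if (is.null(db) || !nrow(db)) { out[[b]] <- empty; next }
    boxes <- cbind(db$cx - db$w / 2, db$cy - db$h / 2,
                   db$cx + db$w / 2, db$cy + db$h / 2)
    keep <- unlist(lapply(sort(unique(db$class)), function(cl) {
      idx <- which(db$class == cl)
      idx[nms_boxes(boxes[idx, , drop = FALSE], db$conf[idx], iou_thresh)]
    }))
    keep <- keep[order(-db$conf[keep])]
    if (length(keep) > max_det) keep <- keep[seq_len(max_det)]
    out[[b]] <- data.frame(class = db$class[keep], conf = db$conf[keep],
                           x1 = boxes[keep, 1], y1 = boxes[keep, 2],
                           x2 = boxes[keep, 3], y2 = boxes[keep, 4])
  }
  out
}

#' Detect objects in images
#'
#' Letterboxes each image to the network input size, runs the eval-mode
#' forward pass, decodes with NMS and maps boxes back to original image
#' pixels.
#'
#' @param object a "cryolo_model"
#' @param images character vector of image paths, a single `(H, W, 3)`
#'   array, or a list of such arrays
#' @param conf_thresh,iou_thresh decoding thresholds
#' @param batch_size images per forward pass
#' @param ... unused
#' @return data frame with columns
#'   `image, class, conf, x1, y1, x2, y2` (original-image pixels)
#' @export
predict.cryolo_model <- function(object, images, conf_thresh = 0.25,
                                 iou_thresh = 0.45, batch_size = 4, ...) {
  imgs <- normalize_image_input(images)
  n <- length(imgs)
  res <- list()
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    lbs <- lapply(imgs[idx], function(im) {
      letterbox(if (is.character(im)) read_image(im) else im,
                object$cfg$img_size)
    })
    x <- array(0, c(object$cfg$img_size, object$cfg$img_size, 3,
                    length(idx)))
    for (k in seq_along(lbs)) x[, , , k] <- lbs[[k]]$image
    raw <- forward_detector(object, x, train = FALSE)
    dets <- decode_and_nms(object, raw, conf_thresh, iou_thresh)
    for (k in seq_along(idx)) {
      d <- dets[[k]]
      if (nrow(d)) {
        lb <- lbs[[k]]
        d$x1 <- pmax(0, (d$x1 - lb$pad[2]) / lb$scale)
        d$x2 <- pmin(lb$orig[2], (d$x2 - lb$pad[2]) / lb$scale)
        d$y1 <- pmax(0, (d$y1 - lb$pad[1]) / lb$scale)
        d$y2 <- pmin(lb$orig[1], (d$y2 - lb$pad[1]) / lb$scale)
      }
      d$image <- rep(idx[k], nrow(d))
      res[[length(res) + 1L]] <- d
    }
  }
  out <- do.call(rbind, res)
  out[, c("image", "class", "conf", "x1", "y1", "x2", "y2")]
}

normalize_image_input <- function(images) {
  if (is.character(images)) as.list(images)
  else if (is.array(images) && length(dim(images)) == 3) list(images)
  else if (is.list(images)) images
  else stop("images must be paths, an (H,W,3) array, or a list of arrays")
}
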