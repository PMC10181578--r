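# Training: seeded SGD with momentum, linear warmup + cosine decay,
# optional mosaic augmentation, per-epoch loss and mAP logging.

# load + letterbox an item once; remap its boxes into the square frame
prepare_item <- function(item, img_size) {
  img <- if (is.character(item$image)) read_image(item$image) else item$image
  d <- dim(img)
  lb <- letterbox(img, img_size)
  b <- item$boxes
  if (!is.null(b) && nrow(b)) {
    b$cx <- (b$cx * d[2] * lb$scale + lb$pad[2]) / img_size
    b$cy <- (b$cy * d[1] * lb$scale + lb$pad[1]) / img_size
    b$w <- b$w * d[2] * lb$scale / img_size
    b$h <- b$h * d[1] * lb$scale / img_size
  }
  list(image = lb$image, boxes = b, raw = img, raw_boxes = item$boxes)
}

#' Train a detector
#'
#' Seeded SGD-with-momentum training with linear warmup, cosine learning
#' rate decay and (optionally) mosaic augmentation. Identical seeds give
#' identical metric logs.
#'
#' @param model a "cryolo_model" (mutated in place and returned)
#' @param train_items list of labelled images (`list(image, boxes)` with
#'   normalized boxes; `image` may be a path or array), e.g.
#'   `load_dataset(...)$items`
#' @param val_items optional validation items for per-epoch mAP logging
#' @param epochs,batch_size schedule; defaults from the model's `hyp`
#' @param seed RNG seed controlling shuffling, mosaic and augmentation
#' @param mosaic override the `hyp` mosaic flag
#' @param eval_every evaluate mAP every this many epochs (and on the
#'   final epoch)
#' @param eval_conf confidence threshold used for the mAP evaluation
#' @param stop_at_map optionally stop once validation mAP@0.5 reaches
#'   this value
#' @param verbose print a line per epoch
#' @return object of class "cryolo_fit": list with `model` and `metrics`
#'   (one row per epoch: losses, learning rate, and mAP columns where
#'   evaluated)
#' @export
train_cryolo <- function(model, train_items, val_items = NULL,
                         epochs = NULL, batch_size = NULL, seed = 0,
                         mosaic = NULL, eval_every = 5, eval_conf = 0.05,
                         stop_at_map = NULL, verbose = TRUE) {
  stopifnot(inherits(model, "cryolo_model"))
  if (!length(train_items)) stop("empty training set")
  hyp <- model$cfg$hyp
  if (is.null(epochs)) epochs <- hyp$epochs
  if (is.null(batch_size)) batch_size <- hyp$batch_size
  if (is.null(mosaic)) mosaic <- hyp$mosaic
  img_size <- model$cfg$img_size
  set.seed(seed)
  items <- lapply(train_items, prepare_item, img_size = img_size)
  n <- length(items)
  params <- collect_params(model)
  vel <- lapply(params, function(p) 0)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- epochs * steps_per_epoch
  warmup_steps <- min(hyp$warmup_epochs * steps_per_epoch,
                      max(1, total_steps %/% 3))
  lrf <- 0.1
  step <- 0L
  logs <- list()
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- c(total = 0, box = 0, obj = 0, cls = 0)
    nb <- 0L
    lr_t <- NA_real_
    for (bs in seq(1, n, by = batch_size)) {
      step <- step + 1L
      sel <- ord[bs:min(n, bs + batch_size - 1)]
      B <- length(sel)
      x <- array(0, c(img_size, img_size, 3, B))
      tg <- list()
      for (k in seq_len(B)) {
        it <- items[[sel[k]]]
        if (mosaic) {
          others <- sample.int(n, 3, replace = n < 4)
          srcs <- lapply(c(sel[k], others), function(i)
            list(image = items[[i]]$raw, boxes = items[[i]]$raw_boxes))
          mo <- mosaic_augment(srcs, img_size)
          x[, , , k] <- mo$image
          bx <- mo$boxes
        } else {
          x[, , , k] <- it$image
          bx <- it$boxes
        }
        if (!is.null(bx) && nrow(bx)) {
          bx$image <- k
          tg[[length(tg) + 1L]] <- bx
        }
      }
      targets <- if (length(tg)) do.call(rbind, tg) else
        data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                   w = numeric(0), h = numeric(0), image = integer(0))
      loss <- with_grad({
        raw <- forward_detector(model, x, train = TRUE)
        compute_loss(model, raw, targets)
      })
      lt <- ag_value(loss$total)
      if (!is.finite(lt))
        stop("non-finite loss at epoch ", epoch, " step ", step,
             " (box=", signif(ag_value(loss$box), 4),
             " obj=", signif(ag_value(loss$obj), 4),
             " cls=", signif(ag_value(loss$cls), 4), ")")
      ag_backward(loss$total)
      # schedule: linear warmup then cosine decay to lrf * lr
      lr_t <- if (step <= warmup_steps) hyp$lr * step / warmup_steps
      else {
        prog <- (step - warmup_steps) / max(1, total_steps - warmup_steps)
        hyp$lr * (lrf + (1 - lrf) * 0.5 * (1 + cos(pi * prog)))
      }
      for (pi_ in seq_along(params)) {
        p <- params[[pi_]]
        if (is.null(p$grad)) next
        g <- p$grad
        if (hyp$weight_decay > 0 && length(dim(p$value)) == 4)
          g <- g + hyp$weight_decay * p$value
        vel[[pi_]] <- hyp$momentum * vel[[pi_]] + g
        p$value <- p$value - lr_t * vel[[pi_]]
      }
      zero_grads(params)
      ep_loss <- ep_loss + c(lt, ag_value(loss$box), ag_value(loss$obj),
                             ag_value(loss$cls))
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    row <- data.frame(epoch = epoch, loss = ep_loss["total"],
                      box = ep_loss["box"], obj = ep_loss["obj"],
                      cls = ep_loss["cls"], lr = lr_t,
                      map50 = NA_real_, map50_95 = NA_real_)
    do_eval <- !is.null(val_items) &&
      (epoch %% eval_every == 0 || epoch == epochs ||
         !is.null(stop_at_map))
    if (do_eval) {
      ev <- evaluate_dataset(model, val_items, conf_thresh = eval_conf)
      row$map50 <- ev$map50
      row$map50_95 <- ev$map50_95
    }
    logs[[epoch]] <- row
    if (verbose)
      cat(sprintf(
        "epoch %3d  loss %.4f (box %.4f obj %.4f cls %.4f)  lr %.4g%s\n",
        epoch, row$loss, row$box, row$obj, row$cls, lr_t,
        if (!is.na(row$map50))
          sprintf("  mAP@0.5 %.3f  mAP@0.5:0.95 %.3f",
                  row$map50, row$map50_95) else ""))
    if (!is.null(stop_at_map) && !is.na(row$map50) &&
        row$map50 >= stop_at_map) break
  }
  metrics <- do.call(rbind, logs)
  rownames(metrics) <- NULL
  structure(list(model = model, metrics = metrics, seed = seed,
                 epochs_run = nrow(metrics)),
            class = "cryolo_fit")
}

#' @export
print.cryolo_fit <- function(x, ...) {
  cat("cryolo fit:", x$epochs_run, "epochs (seed", x$seed, ")\n")
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("  final loss %.4f", last$loss))
  if (!is.na(last$map50))
    cat(sprintf("  mAP@0.5 %.3f  mAP@0.5:0.95 %.3f",
                last$map50, last$map50_95))
  cat("\n")
  invisible(x)
}

#' Evaluate a model (or precomputed detections) on a labelled dataset
#'
#' @param model_or_dets a "cryolo_model" (detections are computed with
#'   [predict.cryolo_model()]) or a detection data frame
#' @param items list of labelled images
#' @param conf_thresh,iou_thresh decoding thresholds when a model is
#'   given
#' @param iou_grid IoU thresholds of the averaged metric
#' @return a "cryolo_eval" (see [evaluate_detections()])
#' @export
evaluate_dataset <- function(model_or_dets, items, conf_thresh = 0.05,
                             iou_thresh = 0.45,
                             iou_grid = seq(0.5, 0.95, by = 0.05)) {
  if (!length(items)) stop("empty dataset")
  gts <- dataset_ground_truth(items)
  dets <- if (inherits(model_or_dets, "cryolo_model")) {
    predict(model_or_dets, lapply(items, `[[`, "image"),
            conf_thresh = conf_thresh, iou_thresh = iou_thresh)
  } else model_or_dets
  evaluate_detections(dets, gts, classes = sort(unique(gts$class)),
                      iou_grid = iou_grid)
}
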