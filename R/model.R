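# CR-YOLOv5s detector assembly: backbone with RepVGG down-sampling and
# coordinate attention, PAN-style neck, anchor-based 3-scale head.

make_div8 <- function(x) as.integer(pmax(8, round(x / 8) * 8))

# default anchor priors (pixels, defined at a 640 reference input)
default_anchors <- function(img_size) {
  base <- list(
    matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),
    matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),
    matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE))
  lapply(base, function(a) a * img_size / 640)
}

#' Detector configuration
#'
#' @param nc number of object classes
#' @param depth_multiple,width_multiple depth/width scaling knobs; the
#'   defaults are the "s"-scale convention (0.33, 0.50)
#' @param img_size network input size in pixels (divisible by 32)
#' @param anchors list of 3 matrices (3 x 2, anchor w/h in pixels, one
#'   matrix per output stride 8/16/32); default priors scale with
#'   `img_size`
#' @param coordatt_sites backbone stage indices (1-4) that receive a
#'   coordinate-attention block after their CSP stage; default: the last
#'   two stages (before SPPF). Empty vector = ablation baseline.
#' @param repvgg_sites down-sampling conv indices (1-4) replaced by
#'   RepVGG blocks; default: all four. Empty vector = ablation baseline.
#' @param reduction coordinate-attention channel reduction ratio
#' @param hyp named list of training hyperparameters; see
#'   [default_hyp()]
#' @return a config list of class "cryolo_config"
#' @export
cryolo_config <- function(nc = 2, depth_multiple = 0.33,
                          width_multiple = 0.50, img_size = 640,
                          anchors = default_anchors(img_size),
                          coordatt_sites = c(3, 4), repvgg_sites = 1:4,
                          reduction = 32, hyp = default_hyp()) {
  stopifnot(nc >= 1, img_size %% 32 == 0,
            depth_multiple > 0, width_multiple > 0)
  if (length(anchors) != 3 ||
      !all(vapply(anchors, function(a) all(dim(a) == c(3, 2)) && all(a > 0),
                  logical(1))))
    stop("anchors must be 3 positive 3x2 matrices")
  stopifnot(all(coordatt_sites %in% 1:4), all(repvgg_sites %in% 1:4))
  structure(list(nc = as.integer(nc), depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 img_size = as.integer(img_size), anchors = anchors,
                 coordatt_sites = as.integer(coordatt_sites),
                 repvgg_sites = as.integer(repvgg_sites),
                 reduction = reduction, hyp = hyp),
            class = "cryolo_config")
}

#' Default training hyperparameters
#'
#' @param lr initial learning rate (SGD, cosine-decayed)
#' @param momentum SGD momentum
#' @param weight_decay L2 penalty on convolution weights
#' @param warmup_epochs linear warmup duration
#' @param box,obj,cls loss-term gains
#' @param epochs,batch_size training schedule defaults
#' @param mosaic use 4-image mosaic augmentation
#' @param anchor_t anchor/target size-ratio matching threshold
#' @param neighbor_cells also assign each target to the nearest adjacent
#'   cell in x and in y (more positives per target; off by default)
#' @return named list
#' @export
default_hyp <- function(lr = 0.01, momentum = 0.937, weight_decay = 5e-4,
                        warmup_epochs = 3, box = 0.05, obj = 1.0, cls = 0.5,
                        epochs = 300, batch_size = 32, mosaic = TRUE,
                        anchor_t = 4.0, neighbor_cells = FALSE) {
  list(lr = lr, momentum = momentum, weight_decay = weight_decay,
       warmup_epochs = warmup_epochs, box = box, obj = obj, cls = cls,
       epochs = epochs, batch_size = batch_size, mosaic = mosaic,
       anchor_t = anchor_t, neighbor_cells = neighbor_cells)
}

#' Build the CR-YOLOv5s detector
#'
#' Backbone: 3x3 stride-2 stem, then four stages of (stride-2
#' down-sampling conv, CSP bottleneck); down-sampling convs listed in
#' `repvgg_sites` are multi-branch RepVGG blocks, stages listed in
#' `coordatt_sites` are followed by a coordinate-attention block; the
#' last stage feeds SPPF. Neck: PAN (top-down + bottom-up feature
#' fusion). Head: one 1x1 conv per scale emitting 3*(5+nc) channels at
#' strides 8/16/32. Building with empty `repvgg_sites` and
#' `coordatt_sites` reproduces the plain YOLOv5s ablation baseline.
#'
#' @param cfg a [cryolo_config()]
#' @return a detector of class "cryolo_model" in multi-branch ("train")
#'   mode
#' @export
build_cr_yolov5s <- function(cfg = cryolo_config()) {
  stopifnot(inherits(cfg, "cryolo_config"))
  wm <- cfg$width_multiple; dm <- cfg$depth_multiple
  ch <- make_div8(c(64, 128, 256, 512, 1024) * wm)
  depths <- pmax(1L, as.integer(round(c(3, 6, 9, 3) * dm)))
  n1 <- max(1L, as.integer(round(3 * dm)))
  no <- 3L * (5L + cfg$nc)
  down_of <- function(i) {
    if (i %in% cfg$repvgg_sites) repvgg_block(ch[i], ch[i + 1], stride = 2)
    else conv_bn(ch[i], ch[i + 1], 3, stride = 2)
  }
  ca_of <- function(i) {
    if (i %in% cfg$coordatt_sites)
      coord_att(ch[i + 1], reduction = cfg$reduction)
    else NULL
  }
  heads <- lapply(ch[3:5], function(c_in)
    conv_bn(c_in, no, 1, bn = FALSE, act = "none", bias = TRUE))
  # objectness/class prior bias initialisation (stabilises early training)
  strides <- c(8L, 16L, 32L)
  for (s in 1:3) {
    b <- heads[[s]]$bias$value
    for (a in 0:2) {
      off <- a * (5L + cfg$nc)
      b[off + 5L] <- log(8 / (cfg$img_size / strides[s])^2)
      b[off + 5L + seq_len(cfg$nc)] <- log(0.6 / (cfg$nc - 0.99 + 1e-9))
    }
    heads[[s]]$bias$value <- b
  }
  m <- new_module("cryolo_model", list(
    cfg = cfg, mode = "train", strides = strides, ch = ch,
    stem = conv_bn(3, ch[1], 3, stride = 2),
    down1 = down_of(1), stage1 = c3_block(ch[2], ch[2], depths[1]),
    down2 = down_of(2), stage2 = c3_block(ch[3], ch[3], depths[2]),
    down3 = down_of(3), stage3 = c3_block(ch[4], ch[4], depths[3]),
    down4 = down_of(4), stage4 = c3_block(ch[5], ch[5], depths[4]),
    ca1 = ca_of(1), ca2 = ca_of(2), ca3 = ca_of(3), ca4 = ca_of(4),
    spp = sppf(ch[5], ch[5]),
    lat5 = conv_bn(ch[5], ch[4], 1),
    c3_td4 = c3_block(2 * ch[4], ch[4], n1, shortcut = FALSE),
    lat4 = conv_bn(ch[4], ch[3], 1),
    c3_td3 = c3_block(2 * ch[3], ch[3], n1, shortcut = FALSE),
    dn3 = conv_bn(ch[3], ch[3], 3, stride = 2),
    c3_bu4 = c3_block(2 * ch[3], ch[4], n1, shortcut = FALSE),
    dn4 = conv_bn(ch[4], ch[4], 3, stride = 2),
    c3_bu5 = c3_block(2 * ch[4], ch[5], n1, shortcut = FALSE),
    head = heads))
  class(m) <- c("cryolo_model", "cry_module")
  m
}

# core forward pass: images (H, W, 3, B) -> list of 3 head maps
# (Hg, Wg, 3*(5+nc), B); nodes when recording is on
forward_detector <- function(m, x, train = FALSE) {
  d <- dim(ag_value(x))
  if (d[1] != m$cfg$img_size || d[2] != m$cfg$img_size || d[3] != 3)
    stop("input must be letterboxed to (img_size, img_size, 3, B)")
  y <- forward(m$stem, x, train)
  y <- forward(m$stage1, forward(m$down1, y, train), train)
  if (!is.null(m$ca1)) y <- forward(m$ca1, y, train)
  y <- forward(m$stage2, forward(m$down2, y, train), train)
  if (!is.null(m$ca2)) y <- forward(m$ca2, y, train)
  p3 <- y
  y <- forward(m$stage3, forward(m$down3, y, train), train)
  if (!is.null(m$ca3)) y <- forward(m$ca3, y, train)
  p4 <- y
  y <- forward(m$stage4, forward(m$down4, y, train), train)
  if (!is.null(m$ca4)) y <- forward(m$ca4, y, train)
  p5 <- forward(m$spp, y, train)
  t5 <- forward(m$lat5, p5, train)
  y <- forward(m$c3_td4, ag_cat(list(ag_upsample2(t5), p4), axis = 3), train)
  t4 <- forward(m$lat4, y, train)
  n3 <- forward(m$c3_td3, ag_cat(list(ag_upsample2(t4), p3), axis = 3), train)
  y <- forward(m$dn3, n3, train)
  n4 <- forward(m$c3_bu4, ag_cat(list(y, t4), axis = 3), train)
  y <- forward(m$dn4, n4, train)
  n5 <- forward(m$c3_bu5, ag_cat(list(y, t5), axis = 3), train)
  list(forward(m$head[[1]], n3, train),
       forward(m$head[[2]], n4, train),
       forward(m$head[[3]], n5, train))
}

#' Raw multi-scale head outputs
#'
#' Deterministic eval-mode forward pass returning the undecoded head
#' predictions.
#'
#' @param m a "cryolo_model"
#' @param images numeric array `(img_size, img_size, 3, B)` in `[0, 1]`
#' @return list of 3 arrays shaped `(B, 3, grid_h, grid_w, 5 + nc)`
#'   (strides 8, 16, 32)
#' @export
forward_raw <- function(m, images) {
  raw <- forward_detector(m, images, train = FALSE)
  nc <- m$cfg$nc
  lapply(raw, function(r) {
    d <- dim(r)
    aperm(array(r, c(d[1], d[2], 5L + nc, 3L, d[4])), c(5, 4, 1, 2, 3))
  })
}

#' @export
print.cryolo_model <- function(x, ...) {
  cfg <- x$cfg
  cat("CR-YOLOv5s detector (", x$mode, " mode)\n", sep = "")
  cat("  classes:", cfg$nc, " input:", cfg$img_size, "x", cfg$img_size, "\n")
  cat("  depth/width multiple:", cfg$depth_multiple, "/",
      cfg$width_multiple, "\n")
  cat("  RepVGG down-sampling sites:",
      if (length(cfg$repvgg_sites)) paste(cfg$repvgg_sites, collapse = ",")
      else "none (baseline)", "\n")
  cat("  coordinate-attention sites:",
      if (length(cfg$coordatt_sites)) paste(cfg$coordatt_sites, collapse = ",")
      else "none (baseline)", "\n")
  cat("  parameters:", format(count_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
summary.cryolo_model <- function(object, ...) {
  print(object)
  cat("  head strides: 8, 16, 32; anchors per scale: 3\n")
  grids <- object$cfg$img_size / object$strides
  cat("  grid sizes:", paste(grids, collapse = ", "), "\n")
  invisible(object)
}

# ---- checkpoints --------------------------------------------------------

state_dict <- function(m) {
  out <- list()
  walk <- function(v, path) {
    if (is_node(v)) {
      out[[path]] <<- v$value
    } else if (inherits(v, "cry_module")) {
      for (nm in ls(v, sorted = TRUE)) {
        if (nm %in% c("cfg", "mode", "strides", "ch")) next
        walk(v[[nm]], paste0(path, ".", nm))
      }
    } else if (is.list(v) && !is.null(v$running_mean)) { # BN state
      out[[paste0(path, ".gamma")]] <<- v$gamma$value
      out[[paste0(path, ".beta")]] <<- v$beta$value
      out[[paste0(path, ".running_mean")]] <<- v$running_mean
      out[[paste0(path, ".running_var")]] <<- v$running_var
    } else if (is.list(v) && length(v)) {
      for (k in seq_along(v)) walk(v[[k]], paste0(path, "[", k, "]"))
    }
  }
  walk(m, "model")
  out
}

load_state_dict <- function(m, state) {
  used <- new.env(parent = emptyenv())
  take <- function(key, ref) {
    s <- state[[key]]
    if (is.null(s)) stop("checkpoint missing value for ", key)
    if (length(s) != length(ref)) stop("shape mismatch at ", key)
    dim(s) <- dim(ref)
    used[[key]] <- TRUE
    s
  }
  skip <- c("cfg", "mode", "strides", "ch")
  walk_env <- function(env, path) {
    for (nm in ls(env, sorted = TRUE)) {
      if (nm %in% skip) next
      v <- env[[nm]]
      p <- paste0(path, ".", nm)
      if (is_node(v)) {
        v$value <- take(p, v$value)
      } else if (inherits(v, "cry_module")) {
        walk_env(v, p)
      } else if (is.list(v) && !is.null(v$running_mean)) {
        v$gamma$value <- take(paste0(p, ".gamma"), v$gamma$value)
        v$beta$value <- take(paste0(p, ".beta"), v$beta$value)
        v$running_mean <- take(paste0(p, ".running_mean"), v$running_mean)
        v$running_var <- take(paste0(p, ".running_var"), v$running_var)
        env[[nm]] <- v
      } else if (is.list(v) && length(v)) {
        for (k in seq_along(v)) {
          if (inherits(v[[k]], "cry_module"))
            walk_env(v[[k]], paste0(p, "[", k, "]"))
        }
      }
    }
  }
  walk_env(m, "model")
  miss <- setdiff(names(state), ls(used))
  if (length(miss)) stop("unused checkpoint entries: ",
                         paste(head(miss, 3), collapse = ", "))
  m
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is a plain R list (config, mode flag, named weight
#' arrays) serialized with `saveRDS()`.
#'
#' @param m a "cryolo_model"
#' @param path file path
#' @return `load_checkpoint` returns the rebuilt model
#' @export
save_checkpoint <- function(m, path) {
  saveRDS(list(cfg = m$cfg, mode = m$mode, state = state_dict(m),
               package = "cryolo", version = "1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$package, "cryolo")) stop("not a cryolo checkpoint")
  m <- build_cr_yolov5s(ck$cfg)
  if (identical(ck$mode, "fused")) m <- reparameterize_model(m)
  load_state_dict(m, ck$state)
  m
}

# deep copy of a module tree (fresh environments and parameter nodes)
clone_module <- function(m) {
  cp <- function(v) {
    if (is_node(v)) {
      ag_leaf(v$value)
    } else if (inherits(v, "cry_module")) {
      e <- new.env(parent = emptyenv())
      for (nm in ls(v, sorted = TRUE)) assign(nm, cp(v[[nm]]), envir = e)
      class(e) <- class(v)
      e
    } else if (is.list(v) && !inherits(v, "cryolo_config") && length(v)) {
      lapply(v, cp)
    } else v
  }
  cp(m)
}
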