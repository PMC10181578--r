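# Training loss: CIoU box regression + binary cross-entropy objectness
# and classification, with YOLO-style anchor/cell target assignment.

# elementwise binary cross-entropy on logits (autograd-aware)
bce_logits <- function(z, y) {
  p <- ag_sigmoid(z)
  ag_neg(ag_add(ag_mul(y, ag_log(ag_clamp(p, lo = 1e-9))),
                ag_mul(1 - y, ag_log(ag_clamp(ag_sub(1, p), lo = 1e-9)))))
}

# CIoU between predicted and target boxes given as center/size vectors
# (autograd-aware in the predictions; targets are constants)
ciou_vec <- function(px, py, pw, ph, tx, ty, tw, th, eps = 1e-9) {
  p_x1 <- ag_sub(px, ag_mul(pw, 0.5)); p_x2 <- ag_add(px, ag_mul(pw, 0.5))
  p_y1 <- ag_sub(py, ag_mul(ph, 0.5)); p_y2 <- ag_add(py, ag_mul(ph, 0.5))
  t_x1 <- tx - tw / 2; t_x2 <- tx + tw / 2
  t_y1 <- ty - th / 2; t_y2 <- ty + th / 2
  iw <- ag_clamp(ag_sub(ag_pmin2(p_x2, t_x2), ag_pmax2(p_x1, t_x1)), lo = 0)
  ih <- ag_clamp(ag_sub(ag_pmin2(p_y2, t_y2), ag_pmax2(p_y1, t_y1)), lo = 0)
  inter <- ag_mul(iw, ih)
  union <- ag_add(ag_sub(ag_add(ag_mul(pw, ph), tw * th), inter), eps)
  iou_v <- ag_div(inter, union)
  cw <- ag_sub(ag_pmax2(p_x2, t_x2), ag_pmin2(p_x1, t_x1))
  ch <- ag_sub(ag_pmax2(p_y2, t_y2), ag_pmin2(p_y1, t_y1))
  c2 <- ag_add(ag_add(ag_sq(cw), ag_sq(ch)), eps)
  rho2 <- ag_add(ag_sq(ag_sub(px, tx)), ag_sq(ag_sub(py, ty)))
  v <- ag_mul(ag_sq(ag_sub(atan(tw / th), ag_atan(ag_div(pw, ph)))),
              4 / pi^2)
  alpha <- ag_detach(ag_div(v, ag_add(ag_sub(v, iou_v), 1 + eps)))
  ag_sub(iou_v, ag_add(ag_div(rho2, c2), ag_mul(alpha, v)))
}

# Assign targets to (scale, anchor, cell) positions by wh-ratio matching;
# every target is guaranteed at least one assignment (its best-ratio
# anchor) even if no anchor passes the threshold.
build_targets <- function(m, targets) {
  nt <- nrow(targets)
  res <- vector("list", 3L)
  if (nt == 0) return(res)
  if (any(targets$class >= m$cfg$nc) || any(targets$class < 0))
    stop("target class id out of range")
  anchor_t <- m$cfg$hyp$anchor_t
  img <- m$cfg$img_size
  best <- data.frame(ratio = rep(Inf, nt), s = NA_integer_, a = NA_integer_)
  rows <- list()
  for (s in 1:3) {
    G <- img %/% m$strides[s]
    ag_ <- m$cfg$anchors[[s]] / m$strides[s] # anchors in grid units
    gx <- targets$cx * G; gy <- targets$cy * G
    gw <- targets$w * G; gh <- targets$h * G
    for (a in 1:3) {
      r <- pmax(gw / ag_[a, 1], ag_[a, 1] / gw,
                gh / ag_[a, 2], ag_[a, 2] / gh)
      upd <- r < best$ratio
      best$ratio[upd] <- r[upd]; best$s[upd] <- s; best$a[upd] <- a
      hit <- which(r < anchor_t)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          t = hit, s = s, a = a, forced = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  matched_t <- if (is.null(rows)) integer(0) else unique(rows$t)
  orphan <- setdiff(seq_len(nt), matched_t)
  if (length(orphan)) {
    rows <- rbind(rows, data.frame(t = orphan, s = best$s[orphan],
                                   a = best$a[orphan], forced = TRUE))
  }
  for (s in 1:3) {
    rs <- rows[rows$s == s, , drop = FALSE]
    if (!nrow(rs)) next # res[[s]] stays NULL
    G <- img %/% m$strides[s]
    t <- targets[rs$t, ]
    gx <- t$cx * G; gy <- t$cy * G
    gi <- pmin(pmax(floor(gx), 0), G - 1) # 0-based cell col
    gj <- pmin(pmax(floor(gy), 0), G - 1) # 0-based cell row
    base <- data.frame(
      b = t$image, a = rs$a, gi = gi, gj = gj,
      tx = gx - gi, ty = gy - gj,
      tw = t$w * G, th = t$h * G,
      aw = m$cfg$anchors[[s]][rs$a, 1] / m$strides[s],
      ah = m$cfg$anchors[[s]][rs$a, 2] / m$strides[s],
      cls = t$class)
    # optional neighbour-cell assignment: the adjacent cell on the
    # nearer side of the center, in x and in y (offsets stay inside the
    # (-0.5, 1.5) range the 2*sigmoid - 0.5 decode can express)
    out <- base
    if (isTRUE(m$cfg$hyp$neighbor_cells)) {
      fx <- gx - floor(gx); fy <- gy - floor(gy)
      nx <- base; nx$gi <- gi + ifelse(fx < 0.5, -1, 1); nx$tx <- gx - nx$gi
      ny <- base; ny$gj <- gj + ifelse(fy < 0.5, -1, 1); ny$ty <- gy - ny$gj
      nx <- nx[nx$gi >= 0 & nx$gi <= G - 1, , drop = FALSE]
      ny <- ny[ny$gj >= 0 & ny$gj <= G - 1, , drop = FALSE]
      out <- rbind(base, nx, ny)
    }
    res[[s]] <- out[!duplicated(out[, c("b", "a", "gi", "gj")]), ,
                    drop = FALSE]
  }
  res
}

#' Detection training loss
#'
#' Weighted sum of a CIoU box-regression term, a binary cross-entropy
#' objectness term over every anchor/cell (positives carry their
#' detached CIoU as target) and a binary cross-entropy classification
#' term at positives.
#'
#' @param m a "cryolo_model"
#' @param raw list of 3 head maps (internal layout; autograd nodes during
#'   training)
#' @param targets data frame with columns `image` (1-based index into
#'   the batch), `class` (0-based, `< nc`), `cx, cy, w, h` (normalized)
#' @return list with `total`, `box`, `obj`, `cls` (autograd nodes inside
#'   `with_grad()`, plain numbers otherwise)
#' @export
compute_loss <- function(m, raw, targets) {
  nc <- m$cfg$nc
  hyp <- m$cfg$hyp
  balance <- c(4.0, 1.0, 0.4)
  asn <- build_targets(m, targets)
  lbox <- 0; lobj <- 0; lcls <- 0
  for (s in 1:3) {
    r <- raw[[s]]
    d <- dim(ag_value(r))
    Hg <- d[1]; Wg <- d[2]; C <- d[3]; B <- d[4]
    fidx <- function(h, w, c, b) h + Hg * ((w - 1) + Wg * ((c - 1) + C * (b - 1)))
    ps <- asn[[s]]
    obj_t <- numeric(Hg * Wg * 3L * B)
    if (!is.null(ps) && nrow(ps)) {
      ch0 <- (ps$a - 1L) * (5L + nc)
      gx <- function(e) ag_gather(r, fidx(ps$gj + 1, ps$gi + 1, ch0 + e, ps$b))
      px <- ag_sub(ag_mul(ag_sigmoid(gx(1)), 2), 0.5)
      py <- ag_sub(ag_mul(ag_sigmoid(gx(2)), 2), 0.5)
      pw <- ag_mul(ag_sq(ag_mul(ag_sigmoid(gx(3)), 2)), ps$aw)
      ph <- ag_mul(ag_sq(ag_mul(ag_sigmoid(gx(4)), 2)), ps$ah)
      ci <- ciou_vec(px, py, pw, ph, ps$tx, ps$ty, ps$tw, ps$th)
      lbox <- ag_add(lbox, ag_mean(ag_sub(1, ci)))
      pos <- (ps$gj + 1) + Hg * (ps$gi + Wg * ((ps$a - 1) + 3 * (ps$b - 1)))
      obj_t[pos] <- pmin(pmax(ag_detach(ci), 0), 1)
      if (nc > 1) {
        np <- nrow(ps)
        cls_idx <- unlist(lapply(seq_len(nc), function(k)
          fidx(ps$gj + 1, ps$gi + 1, ch0 + 5L + k, ps$b)))
        y <- as.numeric(rep(seq_len(nc) - 1L, each = np) ==
                          rep(ps$cls, times = nc))
        lcls <- ag_add(lcls, ag_mean(bce_logits(ag_gather(r, cls_idx), y)))
      }
    }
    hh <- rep(seq_len(Hg), times = Wg * 3L * B)
    ww <- rep(rep(seq_len(Wg), each = Hg), times = 3L * B)
    aa <- rep(rep(1:3, each = Hg * Wg), times = B)
    bb <- rep(seq_len(B), each = Hg * Wg * 3L)
    idx_obj <- fidx(hh, ww, (aa - 1L) * (5L + nc) + 5L, bb)
    lobj <- ag_add(lobj,
                   ag_mul(ag_mean(bce_logits(ag_gather(r, idx_obj), obj_t)),
                          balance[s]))
  }
  total <- ag_add(ag_add(ag_mul(lbox, hyp$box), ag_mul(lobj, hyp$obj)),
                  ag_mul(lcls, hyp$cls))
  list(total = total, box = lbox, obj = lobj, cls = lcls)
}
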