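# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# Design: parameters and (optionally) inputs are leaf nodes; every op
# returns a new node carrying the value, its parent nodes and a backward
# closure. Recording only happens inside with_grad(); outside it, all ops
# operate on (and return) plain numeric arrays, so the same block code
# serves both training and inference.
#
# Nodes are environments so gradients accumulate in place.

.ag <- new.env(parent = emptyenv())
.ag$enabled <- FALSE
.ag$id <- 0L

ag_enabled <- function() .ag$enabled

#' Evaluate an expression with gradient recording enabled
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
with_grad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- TRUE
  on.exit(.ag$enabled <- old)
  expr
}

is_node <- function(x) inherits(x, "agnode")

#' @keywords internal
ag_value <- function(x) if (is_node(x)) x$value else x

new_node <- function(value, parents = list(), bfun = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$bfun <- bfun
  e$leaf <- leaf
  e$grad <- NULL
  .ag$id <- .ag$id + 1L
  e$id <- .ag$id
  class(e) <- "agnode"
  e
}

#' Create a leaf (parameter/input) node
#' @keywords internal
ag_leaf <- function(value) new_node(value, leaf = TRUE)

# Build an op result: records a tape node only when recording is on and at
# least one parent is a node; otherwise returns the plain value.
ag_op <- function(value, parents, bfun) {
  track <- vapply(parents, is_node, logical(1))
  if (.ag$enabled && any(track)) {
    new_node(value, parents = parents[track],
             bfun = function(g) bfun(g)[track])
  } else value
}

#' Backpropagate from a scalar (or seeded) node
#'
#' Accumulates gradients into `$grad` of every reachable node.
#' @param node terminal node (typically the scalar loss)
#' @param seed gradient seed; defaults to 1 for scalars
#' @keywords internal
ag_backward <- function(node, seed = NULL) {
  stopifnot(is_node(node))
  if (is.null(seed)) {
    if (length(node$value) != 1L) stop("seed required for non-scalar output")
    seed <- 1
  }
  # iterative topological sort (DFS, post-order)
  order <- vector("list", 256L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = node, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (is_node(p) && is.null(visited[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    }
  }
  node$grad <- seed
  for (i in seq(n_ord, 1L)) {
    nd <- order[[i]]
    if (is.null(nd$grad) || is.null(nd$bfun)) next
    gs <- nd$bfun(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      g <- gs[[k]]
      if (!is_node(p) || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!nd$leaf) nd$grad <- NULL # free memory on interior nodes
  }
  invisible(node)
}

# ---- elementwise ops ---------------------------------------------------

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av + bv, list(a, b), function(g) {
    list(sum_to_shape(g, av), sum_to_shape(g, bv))
  })
}

ag_sub <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av - bv, list(a, b), function(g) {
    list(sum_to_shape(g, av), sum_to_shape(-g, bv))
  })
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av * bv, list(a, b), function(g) {
    list(sum_to_shape(g * bv, av), sum_to_shape(g * av, bv))
  })
}

ag_div <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av / bv, list(a, b), function(g) {
    list(sum_to_shape(g / bv, av), sum_to_shape(-g * av / (bv * bv), bv))
  })
}

# handles the scalar-vs-array recycling used by the loss code
sum_to_shape <- function(g, ref) {
  if (length(ref) == 1L && length(g) > 1L) return(sum(g))
  if (length(g) == length(ref)) {
    if (!is.null(dim(ref))) dim(g) <- dim(ref)
    return(g)
  }
  stop("unsupported broadcast in backward pass")
}

ag_neg <- function(a) ag_mul(a, -1)

ag_sq <- function(a) ag_mul(a, a)

ag_sqrt <- function(a) {
  v <- sqrt(ag_value(a))
  ag_op(v, list(a), function(g) list(g * 0.5 / v))
}

ag_exp <- function(a) {
  v <- exp(ag_value(a))
  ag_op(v, list(a), function(g) list(g * v))
}

ag_log <- function(a) {
  av <- ag_value(a)
  ag_op(log(av), list(a), function(g) list(g / av))
}

ag_atan <- function(a) {
  av <- ag_value(a)
  ag_op(atan(av), list(a), function(g) list(g / (1 + av * av)))
}

ag_sigmoid <- function(a) {
  v <- plogis(ag_value(a))
  ag_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ag_silu <- function(a) {
  av <- ag_value(a)
  s <- plogis(av)
  ag_op(av * s, list(a), function(g) list(g * (s * (1 + av * (1 - s)))))
}

ag_clamp <- function(a, lo = -Inf, hi = Inf) {
  av <- ag_value(a)
  v <- pmin(pmax(av, lo), hi)
  if (!is.null(dim(av))) dim(v) <- dim(av)
  ag_op(v, list(a), function(g) {
    gm <- g * (av >= lo & av <= hi)
    if (!is.null(dim(av))) dim(gm) <- dim(av)
    list(gm)
  })
}

ag_pmax2 <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  take_a <- av >= bv
  ag_op(pmax(av, bv), list(a, b), function(g) {
    list(sum_to_shape(g * take_a, av), sum_to_shape(g * (!take_a), bv))
  })
}

ag_pmin2 <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  take_a <- av <= bv
  ag_op(pmin(av, bv), list(a, b), function(g) {
    list(sum_to_shape(g * take_a, av), sum_to_shape(g * (!take_a), bv))
  })
}

ag_sum <- function(a) {
  av <- ag_value(a)
  ag_op(sum(av), list(a), function(g) {
    gr <- array(g, dim = if (is.null(dim(av))) length(av) else dim(av))
    if (is.null(dim(av))) gr <- as.vector(gr)
    list(gr)
  })
}

ag_mean <- function(a) {
  n <- length(ag_value(a))
  ag_mul(ag_sum(a), 1 / n)
}

#' Stop gradient flow (treat the current value as a constant)
#' @keywords internal
ag_detach <- function(a) ag_value(a)

# gather with 1-based flat indices; backward scatter-adds
ag_gather <- function(a, idx) {
  av <- ag_value(a)
  ag_op(av[idx], list(a), function(g) {
    acc <- numeric(length(av))
    add <- rowsum(as.numeric(g), group = idx)
    acc[as.integer(rownames(add))] <- add
    dim(acc) <- dim(av)
    list(acc)
  })
}

# ---- shape ops on (H, W, C, B) arrays ----------------------------------

ag_cat <- function(xs, axis) {
  vals <- lapply(xs, ag_value)
  dims <- lapply(vals, dim)
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  outd <- dims[[1]]
  outd[axis] <- sum(sizes)
  out <- array(0, outd)
  off <- 0
  idx_all <- lapply(outd, seq_len)
  for (k in seq_along(vals)) {
    idx <- idx_all
    idx[[axis]] <- off + seq_len(sizes[k])
    out <- do.call(`[<-`, c(list(out), idx, list(vals[[k]])))
    off <- off + sizes[k]
  }
  ag_op(out, xs, function(g) {
    dim(g) <- outd
    res <- vector("list", length(xs))
    off <- 0
    for (k in seq_along(xs)) {
      idx <- idx_all
      idx[[axis]] <- off + seq_len(sizes[k])
      res[[k]] <- do.call(`[`, c(list(g), idx, list(drop = FALSE)))
      off <- off + sizes[k]
    }
    res
  })
}

ag_narrow <- function(a, axis, start, len) {
  av <- ag_value(a)
  d <- dim(av)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- start + seq_len(len) - 1L
  v <- do.call(`[`, c(list(av), idx, list(drop = FALSE)))
  ag_op(v, list(a), function(g) {
    acc <- array(0, d)
    dim(g) <- dim(v)
    acc <- do.call(`[<-`, c(list(acc), idx, list(g)))
    list(acc)
  })
}

# swap the two spatial axes of an (H, W, C, B) array
ag_permute_hw <- function(a) {
  av <- ag_value(a)
  ag_op(aperm(av, c(2, 1, 3, 4)), list(a),
        function(g) list(aperm(g, c(2, 1, 3, 4))))
}

# mean over width -> (H, 1, C, B); mean over height -> (1, W, C, B)
ag_pool_w <- function(a) {
  av <- ag_value(a)
  d <- dim(av)
  m <- array(0, c(d[1], 1, d[3], d[4]))
  # width is axis 2: average the W slabs
  m[] <- rowMeans(array(aperm(av, c(1, 3, 4, 2)), c(d[1] * d[3] * d[4], d[2])))
  ag_op(m, list(a), function(g) {
    gr <- array(rep(as.vector(g) / d[2], d[2]), c(d[1], d[3], d[4], d[2]))
    list(aperm(gr, c(1, 4, 2, 3)))
  })
}

ag_pool_h <- function(a) {
  av <- ag_value(a)
  d <- dim(av)
  m <- array(colMeans(array(av, c(d[1], d[2] * d[3] * d[4]))),
             c(1, d[2], d[3], d[4]))
  ag_op(m, list(a), function(g) {
    gr <- array(rep(as.vector(g) / d[1], each = d[1]), d)
    list(gr)
  })
}

# multiply x (H,W,C,B) by a gate broadcast along W (gate dim (H,1,C,B))
# or along H (gate dim (1,W,C,B))
ag_bmul <- function(x, gate) {
  xv <- ag_value(x); gv <- ag_value(gate)
  d <- dim(xv); gd <- dim(gv)
  if (gd[2] == 1L && gd[1] == d[1]) {
    gb <- array(aperm(array(gv, c(gd[1], gd[3], gd[4], d[2])),
                      c(1, 4, 2, 3)), d)
    axis <- 2L
  } else if (gd[1] == 1L && gd[2] == d[2]) {
    gb <- array(rep(as.vector(gv), each = d[1]), d)
    axis <- 1L
  } else stop("gate shape incompatible with input")
  ag_op(xv * gb, list(x, gate), function(g) {
    dim(g) <- d
    gx <- g * gb
    gg_full <- g * xv
    gg <- if (axis == 2L) {
      array(rowMeans(array(aperm(gg_full, c(1, 3, 4, 2)),
                           c(d[1] * d[3] * d[4], d[2]))) * d[2],
            c(d[1], 1, d[3], d[4]))
    } else {
      array(colSums(array(gg_full, c(d[1], d[2] * d[3] * d[4]))),
            c(1, d[2], d[3], d[4]))
    }
    list(gx, gg)
  })
}

# per-channel mean over (h, w, b) -> length-C vector
ag_cmean <- function(a) {
  av <- ag_value(a)
  d <- dim(av)
  n <- d[1] * d[2] * d[4]
  perm <- aperm(av, c(1, 2, 4, 3))
  v <- colMeans(matrix(perm, nrow = n, ncol = d[3]))
  ag_op(v, list(a), function(g) {
    gr <- array(rep(g, each = d[1] * d[2]), c(d[1], d[2], d[3], d[4])) / n
    list(gr)
  })
}

# per-channel affine y = x * scale[c] + shift[c]; scale/shift length-C
ag_caffine <- function(x, scale, shift) {
  xv <- ag_value(x); sv <- ag_value(scale); bv <- ag_value(shift)
  d <- dim(xv)
  sb <- array(rep(sv, each = d[1] * d[2]), d)
  bb <- array(rep(bv, each = d[1] * d[2]), d)
  ag_op(xv * sb + bb, list(x, scale, shift), function(g) {
    dim(g) <- d
    n <- d[1] * d[2]
    gs <- colSums(matrix(aperm(g * xv, c(1, 2, 4, 3)), nrow = n * d[4]))
    gb <- colSums(matrix(aperm(g, c(1, 2, 4, 3)), nrow = n * d[4]))
    list(g * sb, gs, gb)
  })
}

# ---- structured ops backed by compiled kernels -------------------------

ag_conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L, groups = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  bv <- if (is.null(bias)) numeric(0) else ag_value(bias)
  out <- cpp_conv2d(xv, wv, bv, as.integer(stride), as.integer(pad),
                    as.integer(groups))
  parents <- if (is.null(bias)) list(x, w) else list(x, w, bias)
  ag_op(out, parents, function(g) {
    dim(g) <- dim(out)
    need_dx <- is_node(x)
    bw <- cpp_conv2d_backward(xv, wv, g, as.integer(stride), as.integer(pad),
                              as.integer(groups), need_dx, !is.null(bias))
    res <- list(if (need_dx) bw$dx else NULL, bw$dw)
    if (!is.null(bias)) res <- c(res, list(as.numeric(bw$db)))
    res
  })
}

ag_maxpool <- function(x, k, pad = k %/% 2L) {
  xv <- ag_value(x)
  mp <- cpp_maxpool(xv, as.integer(k), as.integer(pad))
  ag_op(mp$out, list(x), function(g) {
    dx <- cpp_maxpool_backward(g, mp$argmax, length(xv))
    dim(dx) <- dim(xv)
    list(dx)
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  v <- xv[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
          drop = FALSE]
  ag_op(v, list(x), function(g) {
    dim(g) <- c(2L * d[1], 2L * d[2], d[3], d[4])
    s1 <- colSums(matrix(g, nrow = 2)) # fold h pairs
    m1 <- array(s1, c(d[1], 2L, d[2], d[3], d[4]))
    s2 <- colSums(matrix(aperm(m1, c(2, 1, 3, 4, 5)), nrow = 2))
    list(array(s2, d))
  })
}
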