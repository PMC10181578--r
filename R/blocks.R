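# Network building blocks.
#
# A module is an environment of class c(<type>, "cry_module") holding
# parameter nodes (agnode), batch-norm state lists and child modules.
# forward() dispatches on the module type and works both inside
# with_grad() (training) and outside it (plain-array inference).
#
# Feature maps are numeric arrays with dim = c(H, W, C, B).

new_module <- function(type, fields) {
  e <- list2env(fields, envir = new.env(parent = emptyenv()))
  class(e) <- c(type, "cry_module")
  e
}

#' Forward pass of a network module
#'
#' @param m a module created by [conv_bn()], [repvgg_block()],
#'   [coord_att()], [sppf()], [c3_block()] or the model builder
#' @param x feature map, a numeric array with `dim = c(H, W, C, B)`
#' @param train logical; use batch statistics in batch norm (and update
#'   the running statistics) instead of the running statistics
#' @return the transformed feature map
#' @export
forward <- function(m, x, train = FALSE) UseMethod("forward")

# conv weight init: uniform(-sqrt(k), sqrt(k)), k = groups/(cin*kh*kw)
init_conv_weight <- function(kh, kw, cin_g, cout) {
  bound <- sqrt(1 / (kh * kw * cin_g))
  array(runif(kh * kw * cin_g * cout, -bound, bound), c(kh, kw, cin_g, cout))
}

new_bn <- function(channels, eps = 1e-3, momentum = 0.03) {
  list(gamma = ag_leaf(rep(1, channels)), beta = ag_leaf(rep(0, channels)),
       running_mean = rep(0, channels), running_var = rep(1, channels),
       eps = eps, momentum = momentum, channels = channels)
}

# batch norm as per-channel affine; bn is a list created by new_bn and
# must live in a module environment field named in `slot` so running
# statistics can be updated in place.
bn_apply <- function(m, slot, x, train) {
  bn <- m[[slot]]
  if (train) {
    mu <- ag_cmean(x)
    ex2 <- ag_cmean(ag_mul(x, x))
    v <- ag_clamp(ag_sub(ex2, ag_mul(mu, mu)), lo = 0)
    scale <- ag_div(bn$gamma, ag_sqrt(ag_add(v, bn$eps)))
    shift <- ag_sub(bn$beta, ag_mul(mu, scale))
    out <- ag_caffine(x, scale, shift)
    d <- dim(ag_value(x))
    n <- d[1] * d[2] * d[4]
    mom <- bn$momentum
    bn$running_mean <- (1 - mom) * bn$running_mean + mom * ag_value(mu)
    unb <- if (n > 1) n / (n - 1) else 1
    bn$running_var <- (1 - mom) * bn$running_var + mom * ag_value(v) * unb
    m[[slot]] <- bn
    out
  } else {
    s0 <- 1 / sqrt(bn$running_var + bn$eps)
    scale <- ag_mul(bn$gamma, s0)
    shift <- ag_sub(bn$beta, ag_mul(scale, bn$running_mean))
    ag_caffine(x, scale, shift)
  }
}

apply_act <- function(x, act) {
  switch(act,
         silu = ag_silu(x),
         sigmoid = ag_sigmoid(x),
         relu = ag_clamp(x, lo = 0),
         none = x,
         stop("unknown activation: ", act))
}

#' SiLU activation
#'
#' The smooth, non-monotonic activation x * sigmoid(x) used throughout
#' the network.
#' @param x numeric vector or array
#' @return `x * plogis(x)`, same shape
#' @export
silu <- function(x) {
  stopifnot(all(is.finite(x)))
  ag_value(ag_silu(x))
}

#' Convolution + batch norm + activation block
#'
#' @param cin,cout input/output channel counts
#' @param k kernel size (1 or 3)
#' @param stride,pad,groups convolution geometry; `pad` defaults to
#'   `k %/% 2` (shape-preserving at stride 1)
#' @param bn include a batch-norm layer (convolution then has no bias)
#' @param act activation: "silu", "relu", "sigmoid" or "none"
#' @param bias include a convolution bias (default: only when `bn` is off)
#' @param eps,momentum batch-norm stabilizer and running-stat momentum
#' @return a module
#' @export
conv_bn <- function(cin, cout, k = 1, stride = 1, pad = k %/% 2, groups = 1,
                    bn = TRUE, act = "silu", bias = !bn,
                    eps = 1e-3, momentum = 0.03) {
  stopifnot(k %in% c(1L, 3L), cin %% groups == 0, cout %% groups == 0)
  new_module("conv_bn", list(
    weight = ag_leaf(init_conv_weight(k, k, cin %/% groups, cout)),
    bias = if (bias) ag_leaf(rep(0, cout)) else NULL,
    k = k, stride = stride, pad = pad, groups = groups,
    cin = cin, cout = cout, act = act,
    bn = if (bn) new_bn(cout, eps, momentum) else NULL))
}

#' @export
forward.conv_bn <- function(m, x, train = FALSE) {
  if (dim(ag_value(x))[3] != m$cin) stop("channel mismatch in conv_bn")
  y <- ag_conv2d(x, m$weight, m$bias, m$stride, m$pad, m$groups)
  if (!is.null(m$bn)) y <- bn_apply(m, "bn", y, train)
  apply_act(y, m$act)
}

#' Directional average pooling of the coordinate-attention block
#'
#' Pools a feature map along width and along height separately,
#' preserving the positional axis that 2-D global pooling would destroy.
#'
#' @param x feature map, `dim = c(H, W, C, B)`
#' @return list with `zh` (`dim = c(H, 1, C, B)`; mean over width) and
#'   `zw` (`dim = c(1, W, C, B)`; mean over height)
#' @export
coordatt_pool <- function(x) {
  list(zh = ag_value(ag_pool_w(x)), zw = ag_value(ag_pool_h(x)))
}

#' Coordinate attention block
#'
#' Factorizes channel attention into two 1-D, direction-aware gates:
#' features are averaged along each spatial axis, jointly squeezed by a
#' shared 1x1 convolution (with BN and a nonlinearity), re-expanded by
#' two 1x1 convolutions, passed through a logistic gate, and applied
#' multiplicatively to the input.
#'
#' @param cin channel count of the input
#' @param reduction channel reduction ratio r of the squeeze step
#' @param min_mid floor on the squeezed channel count
#' @param act nonlinearity after the squeeze convolution
#' @param squeeze_bn include BN inside the squeeze step
#' @return a module; its forward pass preserves the input shape
#' @export
coord_att <- function(cin, reduction = 32, min_mid = 8, act = "silu",
                      squeeze_bn = TRUE) {
  mid <- max(min_mid, ceiling(cin / reduction))
  new_module("coord_att", list(
    cin = cin, mid = mid,
    conv1 = conv_bn(cin, mid, 1, bn = squeeze_bn, act = act,
                    bias = !squeeze_bn),
    conv_h = conv_bn(mid, cin, 1, bn = FALSE, act = "none", bias = TRUE),
    conv_w = conv_bn(mid, cin, 1, bn = FALSE, act = "none", bias = TRUE)))
}

#' @export
forward.coord_att <- function(m, x, train = FALSE) {
  d <- dim(ag_value(x))
  if (d[3] != m$cin) stop("channel mismatch in coord_att")
  H <- d[1]; W <- d[2]
  zh <- ag_pool_w(x)                  # (H,1,C,B)
  zw <- ag_permute_hw(ag_pool_h(x))   # (W,1,C,B)
  f <- forward(m$conv1, ag_cat(list(zh, zw), axis = 1), train)
  fh <- ag_narrow(f, 1, 1, H)
  fw <- ag_narrow(f, 1, H + 1, W)
  gh <- ag_sigmoid(forward(m$conv_h, fh, train))                  # (H,1,C,B)
  gw <- ag_permute_hw(ag_sigmoid(forward(m$conv_w, fw, train)))   # (1,W,C,B)
  ag_bmul(ag_bmul(x, gh), gw)
}

#' RepVGG block (training-time multi-branch form)
#'
#' A 3x3 conv+BN branch in parallel with a 1x1 conv+BN branch and, when
#' stride is 1 and channel counts match, a BN-only identity branch; the
#' branch sum is passed through the post-activation. After training the
#' block collapses into a single 3x3 convolution, see
#' [reparameterize_block()].
#'
#' @param cin,cout channel counts
#' @param stride 1 or 2 (2 = the down-sampling placement in the backbone)
#' @param groups convolution groups shared by all branches
#' @param act post-activation
#' @param eps,momentum batch-norm settings shared by all branches
#' @return a module
#' @export
repvgg_block <- function(cin, cout, stride = 1, groups = 1, act = "silu",
                         eps = 1e-3, momentum = 0.03) {
  stopifnot(stride %in% c(1L, 2L))
  has_id <- stride == 1 && cin == cout
  new_module("repvgg", list(
    cin = cin, cout = cout, stride = stride, groups = groups, act = act,
    dense = conv_bn(cin, cout, 3, stride, pad = 1, groups = groups,
                    act = "none", eps = eps, momentum = momentum),
    compact = conv_bn(cin, cout, 1, stride, pad = 0, groups = groups,
                      act = "none", eps = eps, momentum = momentum),
    identity_bn = if (has_id) new_bn(cin, eps, momentum) else NULL))
}

#' @export
forward.repvgg <- function(m, x, train = FALSE) {
  y <- ag_add(forward(m$dense, x, train), forward(m$compact, x, train))
  if (!is.null(m$identity_bn)) {
    y <- ag_add(y, bn_apply(m, "identity_bn", x, train))
  }
  apply_act(y, m$act)
}

#' Spatial pyramid pooling - fast (SPPF)
#'
#' Three serial max-pools of one kernel size, concatenated with their
#' input and fused by a 1x1 conv; equivalent to parallel pyramid pooling
#' with kernels k, 2k-1, 3k-2 at lower cost.
#'
#' @param cin,cout channel counts
#' @param k pooling kernel size (odd)
#' @return a module; spatial size is preserved
#' @export
sppf <- function(cin, cout, k = 5) {
  if (k %% 2 != 1) stop("SPPF pooling kernel must be odd")
  c_ <- cin %/% 2
  new_module("sppf", list(
    cin = cin, cout = cout, k = k,
    cv1 = conv_bn(cin, c_, 1),
    cv2 = conv_bn(c_ * 4, cout, 1)))
}

#' @export
forward.sppf <- function(m, x, train = FALSE) {
  y <- forward(m$cv1, x, train)
  p1 <- ag_maxpool(y, m$k)
  p2 <- ag_maxpool(p1, m$k)
  p3 <- ag_maxpool(p2, m$k)
  forward(m$cv2, ag_cat(list(y, p1, p2, p3), axis = 3), train)
}

# residual bottleneck used inside C3
bottleneck <- function(c1, c2, shortcut = TRUE, e = 0.5) {
  c_ <- max(1L, round(c2 * e))
  new_module("bottleneck", list(
    shortcut = shortcut && c1 == c2,
    cv1 = conv_bn(c1, c_, 1),
    cv2 = conv_bn(c_, c2, 3)))
}

#' @export
forward.bottleneck <- function(m, x, train = FALSE) {
  y <- forward(m$cv2, forward(m$cv1, x, train), train)
  if (m$shortcut) ag_add(x, y) else y
}

#' CSP bottleneck stage (C3)
#'
#' Splits the input into a stack of residual bottlenecks and a 1x1
#' shortcut branch, concatenates the two and fuses with a 1x1 conv.
#'
#' @param c1,c2 channel counts
#' @param n number of inner bottlenecks (0 = split+concat+fuse only)
#' @param shortcut enable the residual connections inside the bottlenecks
#' @param e hidden-channel expansion ratio
#' @return a module
#' @export
c3_block <- function(c1, c2, n = 1, shortcut = TRUE, e = 0.5) {
  c_ <- max(1L, round(c2 * e))
  new_module("c3", list(
    cv1 = conv_bn(c1, c_, 1),
    cv2 = conv_bn(c1, c_, 1),
    cv3 = conv_bn(2 * c_, c2, 1),
    blocks = lapply(seq_len(n), function(i) bottleneck(c_, c_, shortcut, 1.0))))
}

#' @export
forward.c3 <- function(m, x, train = FALSE) {
  y1 <- forward(m$cv1, x, train)
  for (b in m$blocks) y1 <- forward(b, y1, train)
  y2 <- forward(m$cv2, x, train)
  forward(m$cv3, ag_cat(list(y1, y2), axis = 3), train)
}

# ---- parameter walking -------------------------------------------------

collect_params <- function(m) {
  out <- list()
  grab <- function(v) {
    if (is_node(v)) {
      out[[length(out) + 1L]] <<- v
    } else if (inherits(v, "cry_module")) {
      for (nm in ls(v, sorted = TRUE)) grab(v[[nm]])
    } else if (is.list(v) && !is.function(v)) {
      for (el in v) grab(el)
    }
  }
  grab(m)
  out
}

#' Number of learnable parameters in a module/model
#' @param m a module or model
#' @return integer parameter count (weights, biases, BN scale/shift)
#' @export
count_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$value), numeric(1)))
}

zero_grads <- function(params) for (p in params) p$grad <- NULL
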