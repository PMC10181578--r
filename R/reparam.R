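# Structural reparameterization: fold batch norm into convolutions, lift
# 1x1 and identity branches to 3x3, and merge parallel branches into one
# convolution with bias. All folds use eval-mode BN (running statistics),
# so the fused network reproduces the multi-branch eval-mode forward pass
# to floating-point accuracy.

#' Fold a batch-norm layer into its preceding convolution
#'
#' For per-channel BN statistics (mu, sigma^2) and learned (gamma, beta),
#' the conv-then-BN composite equals a plain convolution with
#' `W'_i = gamma_i / sqrt(sigma2_i + eps) * W_i` and
#' `b'_i = beta_i - mu_i * gamma_i / sqrt(sigma2_i + eps)`
#' (plus the rescaled original bias when the conv had one).
#'
#' @param cb a [conv_bn()] module with a BN layer
#' @return list with `kernel` (same shape as the conv kernel), `bias`
#'   (length = out channels), and the conv geometry (`stride`, `pad`,
#'   `groups`, `act`)
#' @export
fuse_conv_bn <- function(cb) {
  if (!inherits(cb, "conv_bn") || is.null(cb$bn))
    stop("fuse_conv_bn() needs a conv_bn module with BN statistics")
  bn <- cb$bn
  if (any(bn$running_var < 0)) stop("negative BN variance")
  s <- bn$gamma$value / sqrt(bn$running_var + bn$eps)
  w <- cb$weight$value
  kernel <- w * rep(s, each = prod(dim(w)[1:3]))
  dim(kernel) <- dim(w)
  bias <- bn$beta$value - bn$running_mean * s
  if (!is.null(cb$bias)) bias <- bias + s * cb$bias$value
  list(kernel = kernel, bias = bias, stride = cb$stride, pad = cb$pad,
       groups = cb$groups, act = cb$act)
}

#' Lift a 1x1 convolution kernel to an equivalent 3x3 kernel
#'
#' Surrounds each 1x1 weight with a border of zeros; run with padding 1,
#' the lifted kernel reproduces the original padding-0 convolution on any
#' input.
#'
#' @param kernel array with `dim = c(1, 1, cin_g, cout)`
#' @return array with `dim = c(3, 3, cin_g, cout)`
#' @export
pad_1x1_to_3x3 <- function(kernel) {
  d <- dim(kernel)
  if (length(d) != 4 || d[1] != 1 || d[2] != 1)
    stop("expected a 1x1 convolution kernel")
  out <- array(0, c(3, 3, d[3], d[4]))
  out[2, 2, , ] <- kernel[1, 1, , ]
  out
}

#' Express a BN-only identity branch as a 3x3 convolution + BN
#'
#' Builds the 3x3 kernel whose convolution (padding 1) is the identity
#' map — 1 at the center of each channel's own input position, 0
#' elsewhere, with per-group channel bookkeeping — and attaches the BN
#' statistics unchanged.
#'
#' @param bn a BN state list (as stored on a [repvgg_block()])
#' @param channels channel count of the branch
#' @param groups convolution groups of the surrounding block
#' @return a [conv_bn()] module (3x3, padding 1) equivalent to BN alone
#' @export
bn_identity_to_conv3x3 <- function(bn, channels, groups = 1) {
  if (bn$channels != channels) stop("BN channel count mismatch")
  if (channels %% groups != 0) stop("channels not divisible by groups")
  cg <- channels %/% groups
  kernel <- array(0, c(3, 3, cg, channels))
  for (co in seq_len(channels)) {
    kernel[2, 2, (co - 1) %% cg + 1, co] <- 1
  }
  m <- conv_bn(channels, channels, 3, stride = 1, pad = 1, groups = groups,
               bn = TRUE, act = "none", eps = bn$eps, momentum = bn$momentum)
  m$weight$value <- kernel
  m$bn$gamma$value <- bn$gamma$value
  m$bn$beta$value <- bn$beta$value
  m$bn$running_mean <- bn$running_mean
  m$bn$running_var <- bn$running_var
  m
}

#' Merge parallel same-geometry convolutions into one
#'
#' By linearity of convolution, parallel branches with kernels K_i and
#' biases B_i sum to a single convolution with kernel sum(K_i) and bias
#' sum(B_i).
#'
#' @param branches list of `list(kernel, bias)` with identical kernel
#'   shapes
#' @return `list(kernel, bias)`
#' @export
merge_parallel_convs <- function(branches) {
  stopifnot(length(branches) >= 1)
  d <- dim(branches[[1]]$kernel)
  for (b in branches) {
    if (!identical(dim(b$kernel), d)) stop("branch kernel shapes differ")
  }
  kernel <- Reduce(`+`, lapply(branches, `[[`, "kernel"))
  bias <- Reduce(`+`, lapply(branches, `[[`, "bias"))
  list(kernel = kernel, bias = bias)
}

#' Collapse a multi-branch RepVGG block into a single 3x3 convolution
#'
#' Stage 1 folds each branch's BN into its convolution
#' ([fuse_conv_bn()]), lifts the 1x1 branch to 3x3
#' ([pad_1x1_to_3x3()]) and converts the identity BN branch
#' ([bn_identity_to_conv3x3()]); stage 2 sums the now shape-identical
#' branches ([merge_parallel_convs()]). The post-activation is retained.
#'
#' @param blk a [repvgg_block()]
#' @return a plain convolution module (3x3, bias, no BN) whose eval-mode
#'   output equals the block's eval-mode output
#' @export
reparameterize_block <- function(blk) {
  if (!inherits(blk, "repvgg")) stop("expected a repvgg block")
  dense <- fuse_conv_bn(blk$dense)
  compact <- fuse_conv_bn(blk$compact)
  compact$kernel <- pad_1x1_to_3x3(compact$kernel)
  branches <- list(dense, compact)
  if (!is.null(blk$identity_bn)) {
    idc <- bn_identity_to_conv3x3(blk$identity_bn, blk$cin, blk$groups)
    branches <- c(branches, list(fuse_conv_bn(idc)))
  }
  merged <- merge_parallel_convs(branches)
  out <- conv_bn(blk$cin, blk$cout, 3, stride = blk$stride, pad = 1,
                 groups = blk$groups, bn = FALSE, act = blk$act, bias = TRUE)
  out$weight$value <- merged$kernel
  out$bias$value <- merged$bias
  out
}

# fold a conv_bn's BN into the conv, returning an equivalent plain conv
fold_conv_bn <- function(cb) {
  f <- fuse_conv_bn(cb)
  out <- conv_bn(cb$cin, cb$cout, cb$k, stride = cb$stride, pad = cb$pad,
                 groups = cb$groups, bn = FALSE, act = cb$act, bias = TRUE)
  out$weight$value <- f$kernel
  out$bias$value <- f$bias
  out
}

# recursively replace RepVGG blocks (and, optionally, conv+BN pairs) in a
# module tree; mutates module environments in place
reparam_walk <- function(m, fold_bn) {
  transform <- function(v) {
    if (inherits(v, "repvgg")) return(reparameterize_block(v))
    if (inherits(v, "conv_bn")) {
      return(if (fold_bn && !is.null(v$bn)) fold_conv_bn(v) else v)
    }
    if (inherits(v, "cry_module")) return(reparam_walk(v, fold_bn))
    if (is.list(v) && length(v) && all(vapply(v, inherits, logical(1),
                                              "cry_module"))) {
      return(lapply(v, transform))
    }
    v
  }
  for (nm in ls(m, sorted = TRUE)) m[[nm]] <- transform(m[[nm]])
  m
}

#' Convert a trained multi-branch detector to its single-path form
#'
#' Replaces every RepVGG block with its fused 3x3 convolution and (by
#' default) folds all remaining conv+BN pairs, producing the VGG-style
#' inference network. Eval-mode outputs are preserved to floating-point
#' accuracy and the parameter count strictly decreases. The operation is
#' idempotent.
#'
#' @param model a detector built by [build_cr_yolov5s()]
#' @param fold_bn also fold plain conv+BN pairs (default TRUE)
#' @return the fused model (class "cryolo_model", mode "fused")
#' @export
reparameterize_model <- function(model, fold_bn = TRUE) {
  if (!inherits(model, "cryolo_model")) stop("expected a cryolo_model")
  reparam_walk(model, fold_bn)
  model$mode <- "fused"
  model
}
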