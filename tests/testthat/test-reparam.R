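# Structural reparameterization: algebraic worked examples and
# train/inference equivalence oracles.

test_that("conv+BN folding reproduces the closed-form update", {
  # identity BN (gamma=1, beta=0, mu=0, var=1, eps=0) leaves the conv alone
  m <- conv_bn(2, 2, 3)
  m$bn$eps <- 0
  f <- fuse_conv_bn(m)
  expect_equal(f$kernel, m$weight$value, tolerance = 1e-14)
  expect_equal(f$bias, c(0, 0))
  # scalar case: W=3, mu=5, var=4, gamma=2, beta=1 -> W'=3, b'=-4
  s <- conv_bn(1, 1, 1)
  s$weight$value[] <- 3
  s$bn$eps <- 0
  s$bn$running_mean <- 5; s$bn$running_var <- 4
  s$bn$gamma$value <- 2; s$bn$beta$value <- 1
  fs <- fuse_conv_bn(s)
  expect_equal(as.vector(fs$kernel), 3)
  expect_equal(fs$bias, -4)
  expect_error(fuse_conv_bn(conv_bn(2, 2, 3, bn = FALSE)), "BN")
})

test_that("fused conv equals sequential conv-then-BN on random draws", {
  set.seed(21)
  for (k in 1:30) {
    cin <- sample(c(1, 3), 1); cout <- sample(c(2, 4), 1)
    ksz <- sample(c(1, 3), 1); stride <- sample(1:2, 1)
    m <- conv_bn(cin, cout, ksz, stride = stride, act = "none",
                 bias = sample(c(TRUE, FALSE), 1))
    m$bn$running_mean <- rnorm(cout)
    m$bn$running_var <- runif(cout, 0.1, 3)
    m$bn$gamma$value <- rnorm(cout)
    m$bn$beta$value <- rnorm(cout)
    x <- rand_fmap(6, 7, cin, 2)
    f <- fuse_conv_bn(m)
    fused <- cryolo:::cpp_conv2d(x, f$kernel, f$bias, stride, m$pad, 1L)
    expect_lt(max(abs(fused - forward(m, x))), 1e-5)
  }
})

test_that("1x1 kernels lift to 3x3 with an exact zero border", {
  k <- array(4, c(1, 1, 1, 1))
  p <- pad_1x1_to_3x3(k)
  expect_equal(p[, , 1, 1], matrix(c(0, 0, 0, 0, 4, 0, 0, 0, 0), 3))
  expect_true(all(pad_1x1_to_3x3(array(0, c(1, 1, 2, 3))) == 0))
  expect_error(pad_1x1_to_3x3(array(1, c(3, 3, 1, 1))), "1x1")
  set.seed(22)
  k1 <- array(rnorm(8 * 4), c(1, 1, 4, 8))
  x <- rand_fmap(6, 5, 4, 2)
  y1 <- cryolo:::cpp_conv2d(x, k1, numeric(0), 1L, 0L, 1L)
  y3 <- cryolo:::cpp_conv2d(x, pad_1x1_to_3x3(k1), numeric(0), 1L, 1L, 1L)
  expect_lt(max(abs(y1 - y3)), 1e-12)
})

test_that("a BN-only branch converts to an identity 3x3 conv + BN", {
  bn <- cryolo:::new_bn(2)
  m <- bn_identity_to_conv3x3(bn, 2, 1)
  expect_equal(m$weight$value[2, 2, 1, 1], 1)
  expect_equal(m$weight$value[2, 2, 2, 2], 1)
  expect_equal(sum(m$weight$value), 2)
  set.seed(23)
  bn2 <- cryolo:::new_bn(4)
  bn2$running_mean <- rnorm(4); bn2$running_var <- runif(4, 0.2, 2)
  bn2$gamma$value <- rnorm(4); bn2$beta$value <- rnorm(4)
  m2 <- bn_identity_to_conv3x3(bn2, 4, 1)
  holder <- cryolo:::new_module("x", list(bn = bn2))
  x <- rand_fmap(5, 6, 4, 2)
  expect_lt(max(abs(forward(m2, x) -
                      cryolo:::bn_apply(holder, "bn", x, FALSE))), 1e-6)
  # depthwise bookkeeping: each group sees only its own channel
  md <- bn_identity_to_conv3x3(bn2, 4, 4)
  for (co in 1:4) expect_equal(md$weight$value[2, 2, 1, co], 1)
  expect_error(bn_identity_to_conv3x3(bn2, 6, 1), "mismatch")
})

test_that("parallel branches merge by kernel and bias summation", {
  k1 <- array(1, c(3, 3, 1, 1))
  k2 <- array(0, c(3, 3, 1, 1)); k2[2, 2, 1, 1] <- 2
  m <- merge_parallel_convs(list(list(kernel = k1, bias = 0.5),
                                 list(kernel = k2, bias = -0.5)))
  expect_equal(m$kernel[2, 2, 1, 1], 3)
  expect_equal(m$kernel[1, 1, 1, 1], 1)
  expect_equal(m$bias, 0)
  one <- list(kernel = k1, bias = 0.25)
  expect_equal(merge_parallel_convs(list(one)), list(kernel = k1, bias = 0.25))
  expect_error(merge_parallel_convs(list(
    one, list(kernel = array(1, c(3, 3, 2, 1)), bias = 0))), "shapes")
  set.seed(24)
  br <- lapply(1:3, function(i)
    list(kernel = array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4)),
         bias = rnorm(4)))
  x <- rand_fmap(6, 6, 2, 1)
  run <- function(b) cryolo:::cpp_conv2d(x, b$kernel, b$bias, 1L, 1L, 1L)
  mm <- merge_parallel_convs(br)
  expect_lt(max(abs(run(mm) - (run(br[[1]]) + run(br[[2]]) + run(br[[3]])))),
            1e-5)
  # merging commutes with branch permutation
  mp <- merge_parallel_convs(br[c(3, 1, 2)])
  expect_equal(mm$kernel, mp$kernel)
  expect_equal(mm$bias, mp$bias)
})

test_that("fused RepVGG blocks reproduce the multi-branch output over 100 draws", {
  set.seed(25)
  worst <- 0
  for (k in 1:100) {
    cin <- sample(c(2, 4), 1)
    stride <- sample(1:2, 1)
    cout <- if (k %% 2 == 0) cin else sample(c(2, 4), 1)
    if (stride == 2) cout <- sample(c(2, 4), 1)
    groups <- if (cin == 4 && cout == 4 && k %% 3 == 0) 2 else 1
    blk <- repvgg_block(cin, cout, stride, groups = groups)
    for (p in cryolo:::collect_params(blk)) p$value[] <- rnorm(length(p$value))
    blk$dense$bn$running_mean <- rnorm(cout)
    blk$dense$bn$running_var <- runif(cout, 0.1, 2)
    blk$compact$bn$running_mean <- rnorm(cout)
    blk$compact$bn$running_var <- runif(cout, 0.1, 2)
    if (!is.null(blk$identity_bn)) {
      blk$identity_bn$running_mean <- rnorm(cout)
      blk$identity_bn$running_var <- runif(cout, 0.1, 2)
    }
    x <- rand_fmap(sample(4:7, 1), sample(4:7, 1), cin, 1)
    fused <- reparameterize_block(blk)
    worst <- max(worst, max(abs(forward(fused, x) - forward(blk, x))))
  }
  expect_lt(worst, 1e-10)
})

test_that("all-zero-gamma blocks fuse to a zero kernel with summed betas", {
  blk <- repvgg_block(2, 2, 1)
  betas <- list(rnorm(2), rnorm(2), rnorm(2))
  blk$dense$bn$gamma$value[] <- 0; blk$dense$bn$beta$value <- betas[[1]]
  blk$compact$bn$gamma$value[] <- 0; blk$compact$bn$beta$value <- betas[[2]]
  blk$identity_bn$gamma$value[] <- 0; blk$identity_bn$beta$value <- betas[[3]]
  fused <- reparameterize_block(blk)
  expect_true(all(fused$weight$value == 0))
  expect_equal(fused$bias$value, betas[[1]] + betas[[2]] + betas[[3]])
})

test_that("whole-model reparameterization preserves outputs, shrinks the model and is idempotent", {
  set.seed(26)
  m <- build_cr_yolov5s(tiny_cfg(img_size = 96))
  x <- array(runif(96 * 96 * 3 * 2), c(96, 96, 3, 2))
  r1 <- forward_raw(m, x)
  n_train <- count_params(m)
  fused <- reparameterize_model(cryolo:::clone_module(m))
  expect_identical(fused$mode, "fused")
  r2 <- forward_raw(fused, x)
  for (s in 1:3) expect_lt(max(abs(r1[[s]] - r2[[s]])), 1e-10)
  expect_lt(count_params(fused), n_train)
  twice <- reparameterize_model(cryolo:::clone_module(fused))
  expect_equal(cryolo:::state_dict(twice), cryolo:::state_dict(fused))
})
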