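# Building-block forward passes against closed forms and scalar-loop
# oracles.

test_that("SiLU matches x * sigmoid(x) at reference points", {
  expect_identical(silu(0), 0)
  expect_lt(abs(silu(30) - 30), 1e-9)
  expect_equal(silu(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(silu(1), 0.731059, tolerance = 1e-6)
  # non-monotonic with a minimum near -1.278
  xs <- seq(-3, 0, by = 0.001)
  expect_equal(xs[which.min(silu(xs))], -1.278, tolerance = 1e-2)
  expect_error(silu(NaN))
})

test_that("directional pooling averages along the intended axes", {
  x <- array(5, c(4, 6, 2, 1))
  p <- coordatt_pool(x)
  expect_true(all(p$zh == 5) && all(p$zw == 5))
  expect_equal(dim(p$zh), c(4, 1, 2, 1))
  expect_equal(dim(p$zw), c(1, 6, 2, 1))
  x1 <- array(7.5, c(1, 1, 3, 1))
  p1 <- coordatt_pool(x1)
  expect_equal(as.vector(p1$zh), rep(7.5, 3))
  expect_equal(as.vector(p1$zw), rep(7.5, 3))
  xr <- array(0, c(2, 3, 1, 1))
  xr[1, , 1, 1] <- c(1, 2, 3)
  expect_equal(coordatt_pool(xr)$zh[1, 1, 1, 1], 2)
})

test_that("coordinate attention with zeroed transforms scales the input by exactly 1/4", {
  set.seed(11)
  m <- coord_att(4, reduction = 2, min_mid = 2)
  m$conv1$weight$value[] <- 0
  m$conv1$bn$gamma$value[] <- 0
  m$conv1$bn$beta$value[] <- 0
  m$conv_h$weight$value[] <- 0; m$conv_h$bias$value[] <- 0
  m$conv_w$weight$value[] <- 0; m$conv_w$bias$value[] <- 0
  x <- rand_fmap(5, 7, 4, 2)
  expect_equal(forward(m, x), 0.25 * x, tolerance = 1e-14)
})

test_that("coordinate attention matches a scalar-loop transcription and preserves shape", {
  set.seed(12)
  for (rep_ in 1:3) {
    h <- sample(3:8, 1); w <- sample(3:8, 1); c_ <- sample(c(2, 4), 1)
    m <- coord_att(c_, reduction = 2, min_mid = 2)
    x <- rand_fmap(h, w, c_, 2)
    y <- forward(m, x)
    expect_equal(dim(y), dim(x))
    expect_lt(max(abs(y - coordatt_oracle(m, x))), 1e-6)
    gates <- y / x
    expect_true(all(gates > 0 & gates < 1)) # logistic gates stay in (0,1)
  }
})

test_that("RepVGG training forward is the activated sum of its branches", {
  set.seed(13)
  # zeroed 1x1 and identity branches reduce to the dense branch
  m <- repvgg_block(3, 3, 1)
  m$compact$bn$gamma$value[] <- 0; m$compact$bn$beta$value[] <- 0
  m$identity_bn$gamma$value[] <- 0; m$identity_bn$beta$value[] <- 0
  x <- rand_fmap(6, 6, 3, 1)
  expect_equal(forward(m, x), silu(forward(m$dense, x)), tolerance = 1e-12)
  # stride-2 blocks have no identity branch
  expect_null(repvgg_block(3, 5, 2)$identity_bn)
  expect_null(repvgg_block(3, 5, 1)$identity_bn) # cin != cout
  # sum-of-branches oracle over random draws, both strides
  for (k in 1:100) {
    cin <- sample(c(2, 4), 1)
    stride <- sample(1:2, 1)
    cout <- if (stride == 1) cin else sample(c(2, 4), 1)
    blk <- repvgg_block(cin, cout, stride)
    for (p in cryolo:::collect_params(blk)) p$value[] <- rnorm(length(p$value))
    for (nm in c("dense", "compact")) {
      blk[[nm]]$bn$running_mean <- rnorm(cout)
      blk[[nm]]$bn$running_var <- runif(cout, 0.2, 2)
    }
    x <- rand_fmap(5, 5, cin, 1)
    manual <- forward(blk$dense, x) + forward(blk$compact, x)
    if (!is.null(blk$identity_bn)) {
      blk$identity_bn$running_mean <- rnorm(cout)
      blk$identity_bn$running_var <- runif(cout, 0.2, 2)
      manual <- manual + cryolo:::bn_apply(blk, "identity_bn", x, FALSE)
    }
    expect_lt(max(abs(forward(blk, x) - silu(manual))), 1e-6)
  }
})

test_that("SPPF pools serially and preserves spatial size and channel contract", {
  set.seed(14)
  expect_error(sppf(4, 8, k = 4), "odd")
  m <- sppf(4, 8, 5)
  x <- rand_fmap(9, 9, 4, 2)
  y <- forward(m, x)
  expect_equal(dim(y), c(9, 9, 8, 2))
  m2 <- sppf(4, 6, 3)
  expect_equal(dim(forward(m2, x))[3], 6)
  # max of a constant map is constant (pre-fusion pooling)
  cp <- cryolo:::cpp_maxpool(array(2.5, c(6, 6, 1, 1)), 5L, 2L)
  expect_true(all(cp$out == 2.5))
  # two serial k=5 pools (stride 1) equal one k=9 pool
  xa <- rand_fmap(11, 13, 3, 2)
  p5 <- cryolo:::ag_maxpool(cryolo:::ag_maxpool(xa, 5), 5)
  p9 <- cryolo:::ag_maxpool(xa, 9)
  expect_identical(p5, p9)
})

test_that("CSP bottleneck composes as split + bottlenecks + concat + fuse", {
  set.seed(15)
  x <- rand_fmap(6, 8, 4, 2)
  # n = 0: pure split/concat/fuse
  m0 <- c3_block(4, 8, n = 0)
  manual0 <- forward(m0$cv3, cryolo:::ag_cat(
    list(forward(m0$cv1, x), forward(m0$cv2, x)), axis = 3))
  expect_equal(forward(m0, x), manual0, tolerance = 1e-12)
  # zeroed inner bottleneck with shortcut is the identity on its branch
  mb <- cryolo:::bottleneck(4, 4, shortcut = TRUE, e = 1)
  mb$cv2$weight$value[] <- 0
  mb$cv2$bn$beta$value[] <- 0
  expect_equal(forward(mb, x), x, tolerance = 1e-12)
  # full block equals explicit branch-by-branch composition
  m <- c3_block(4, 8, n = 2)
  y1 <- forward(m$cv1, x)
  for (b in m$blocks) y1 <- forward(b, y1)
  manual <- forward(m$cv3, cryolo:::ag_cat(list(y1, forward(m$cv2, x)),
                                           axis = 3))
  expect_lt(max(abs(forward(m, x) - manual)), 1e-6)
  expect_error(forward(m, rand_fmap(6, 8, 3, 1)), "channel")
})

test_that("attention output shape equals input shape over random draws", {
  set.seed(16)
  for (k in 1:10) {
    h <- sample(2:9, 1); w <- sample(2:9, 1)
    c_ <- sample(c(2, 3, 5), 1); b <- sample(1:2, 1)
    m <- coord_att(c_, reduction = sample(c(2, 32), 1), min_mid = 2)
    x <- rand_fmap(h, w, c_, b)
    expect_equal(dim(forward(m, x)), c(h, w, c_, b))
  }
})
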