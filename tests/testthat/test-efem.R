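test_that("convolution windows span the intended durations and lengths", {
  expect_equal(convWindowSeconds(64, 100), 0.64)
  expect_equal(convWindowSeconds(512, 100), 5.12)
  # valid-padding output length of the first small-branch conv
  expect_identical(sleepExit:::conv_out_len(3000, 64, 8), 368L)
  x <- array(rnorm(3000), dim = c(1, 3000, 1))
  W <- matrix(rnorm(64), 1, 64)
  out <- sleepExit:::conv1d_fwd(x, W, 0, 8L)
  expect_identical(dim(out$y), c(1L, 368L, 1L))
})

test_that("channel attention obeys its algebra", {
  set.seed(1)
  F <- matrix(rnorm(8), 2, 4)
  zero_w <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
                 W2 = matrix(0, 2, 2), b2 = c(0, 0))
  expect_equal(as.vector(channelAttention(F, zero_w)), c(0.5, 0.5))

  w <- list(W1 = matrix(rnorm(4), 2, 2), b1 = rnorm(2),
            W2 = matrix(rnorm(4), 2, 2), b2 = rnorm(2))
  Mc <- channelAttention(F, w)
  expect_true(all(Mc > 0 & Mc < 1))
  expect_equal(as.vector(Mc),
               oracle_channel_attention(F, w$W1, w$b1, w$W2, w$b2),
               tolerance = 1e-12)

  # a constant-zero channel with identity MLP (r = 1) pools to 0: weight 0.5
  Fz <- rbind(0, rnorm(4))
  idw <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  expect_equal(channelAttention(Fz, idw)[1], 0.5)
})

test_that("channel rescaling is row-wise with shape preservation", {
  F <- matrix(1:6, 2, 3)
  expect_equal(applyChannelAttention(F, c(1, 1)), F)
  expect_equal(applyChannelAttention(F, c(0, 0)), F * 0)
  half <- applyChannelAttention(F, c(0.5, 1))
  expect_equal(half[1, ], F[1, ] / 2)
  expect_equal(half[2, ], F[2, ])
  expect_error(applyChannelAttention(F, c(1, 1, 1)), "channels")
})

test_that("spatial attention obeys its algebra", {
  set.seed(2)
  F <- matrix(rnorm(16), 2, 8)
  zw <- list(W = matrix(0, 1, 14), b = 0)
  expect_equal(as.vector(spatialAttention(F, zw)), rep(0.5, 8))

  w <- list(W = matrix(rnorm(14), 1, 14), b = rnorm(1))
  Ms <- spatialAttention(F, w)
  expect_identical(dim(Ms), c(1L, 8L))         # same-padding keeps length d
  expect_true(all(Ms > 0 & Ms < 1))
  expect_equal(as.vector(Ms),
               oracle_spatial_attention(F, as.vector(w$W), w$b),
               tolerance = 1e-12)

  Fc <- matrix(3, 2, 8)   # constant grid: avg = max profile, constant interior
  Msc <- as.vector(spatialAttention(Fc, w))
  expect_equal(Msc[4], Msc[5])  # interior positions see identical windows
})

test_that("spatial rescaling is column-wise", {
  F <- matrix(1:6, 2, 3)
  expect_equal(applySpatialAttention(F, c(1, 1, 1)), F)
  expect_equal(applySpatialAttention(F, c(0, 0, 0)), F * 0)
  alt <- applySpatialAttention(F, c(1, 0, 1))
  expect_equal(alt[, 2], c(0, 0))
  expect_equal(alt[, c(1, 3)], F[, c(1, 3)])
})

test_that("vectorized CBAM matches the straight-from-the-definitions oracle", {
  set.seed(3)
  for (rep in 1:5) {
    F <- matrix(rnorm(30), 3, 10)
    W1 <- matrix(rnorm(9) * 0.5, 3, 3); b1 <- rnorm(3) * 0.1
    W2 <- matrix(rnorm(9) * 0.5, 3, 3); b2 <- rnorm(3) * 0.1
    Wsp <- rnorm(14) * 0.5; bsp <- rnorm(1) * 0.1
    expected <- oracle_cbam(F, W1, b1, W2, b2, Wsp, bsp)

    Fb <- array(F, dim = c(3, 10, 1))
    ch <- sleepExit:::cbam_channel_fwd(Fb, list(W1 = W1, b1 = b1,
                                                W2 = W2, b2 = b2))
    sp <- sleepExit:::cbam_spatial_fwd(ch$y, list(Wsp = matrix(Wsp, 1, 14),
                                                  bsp = bsp), 7)
    expect_equal(matrix(sp$y, 3, 10), expected, tolerance = 1e-6)
  }
})

test_that("the extractor applies channel attention before spatial attention", {
  m <- sleepNet(tiny_config(), seed = 5)
  sig <- rnorm(3000)
  F0 <- multiScaleConv(sig, m, "eeg")
  cb <- m@params$efem$eeg$cbam
  Mc <- channelAttention(F0, list(W1 = cb$W1, b1 = cb$b1,
                                  W2 = cb$W2, b2 = cb$b2))
  F1 <- applyChannelAttention(F0, Mc)
  Ms <- spatialAttention(F1, list(W = cb$Wsp, b = cb$bsp))
  composed <- applySpatialAttention(F1, Ms)
  expect_equal(efemForward(sig, m, "eeg"), composed, tolerance = 1e-10)
  # the reversed order disagrees (wiring is order-sensitive)
  Ms0 <- spatialAttention(F0, list(W = cb$Wsp, b = cb$bsp))
  reversed <- applyChannelAttention(applySpatialAttention(F0, Ms0), Mc)
  expect_false(isTRUE(all.equal(efemForward(sig, m, "eeg"), reversed,
                                tolerance = 1e-6)))
})

test_that("extractor output shape is fixed by config, not input values", {
  m <- sleepNet(tiny_config(), seed = 6)
  a <- efemForward(rnorm(3000), m, "eeg")
  b <- efemForward(rnorm(3000) * 50 + 3, m, "eeg")
  expect_identical(dim(a), dim(b))
  expect_identical(dim(a), c(4L, 8L))   # C = 2*f3, d_out
  expect_error(multiScaleConv(rnorm(400), m), "large")
})
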