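test_that("SE recalibration is a gated residual with exact shape preservation", {
  set.seed(4)
  F <- array(rnorm(2 * 3 * 4), dim = c(2, 3, 4))
  zw <- list(c1 = list(W = matrix(0, 2, 2), b = c(0, 0)),
             c2 = list(W = matrix(0, 2, 2), b = c(0, 0)),
             g1 = list(W = matrix(0, 2, 2), b = c(0, 0)),
             g2 = list(W = matrix(0, 2, 2), b = c(0, 0)))
  # zero convs: F' = 0, gate = 0.5, output = F + 0.5 * 0 = F
  expect_equal(seRecalibrate(F, zw), F)
  rw <- list(c1 = list(W = matrix(rnorm(4), 2, 2), b = rnorm(2)),
             c2 = list(W = matrix(rnorm(4), 2, 2), b = rnorm(2)),
             g1 = list(W = matrix(rnorm(4), 2, 2), b = rnorm(2)),
             g2 = list(W = matrix(rnorm(4), 2, 2), b = rnorm(2)))
  expect_identical(dim(seRecalibrate(F, rw)), dim(F))
})

test_that("SE block with L = 1 reduces to a hand-computable scalar gate", {
  F <- array(c(1, 2, 3, 4, 5, 6), dim = c(1, 2, 3))
  idw <- list(c1 = list(W = matrix(1, 1, 1), b = 0),
              c2 = list(W = matrix(1, 1, 1), b = 0),
              g1 = list(W = matrix(1, 1, 1), b = 0),
              g2 = list(W = matrix(1, 1, 1), b = 0))
  # identity 1x1 convs: F' = F; z = mean(F) = 3.5; gate = sigmoid(3.5)
  g <- 1 / (1 + exp(-3.5))
  expect_equal(seRecalibrate(F, idw), F + g * F, tolerance = 1e-12)
})

test_that("multi-head self-attention matches the double-loop oracle", {
  set.seed(5)
  # fixed small-integer toy: 2 tokens, d = 2, one head
  X <- matrix(c(1, 2, 0, -1), 2, 2)
  Wq <- matrix(c(1, 0, 1, 1), 2, 2)
  Wk <- matrix(c(0, 1, 1, 0), 2, 2)
  Wv <- matrix(c(1, 1, 0, 1), 2, 2)
  got <- multiHeadSelfAttention(X, list(Wq = Wq, Wk = Wk, Wv = Wv), H = 1)
  expect_equal(got, oracle_mhsa(X, Wq, Wk, Wv, 1), tolerance = 1e-6)

  # all toy instances with <= 4 tokens, d <= 4, every valid head count
  for (Tn in 2:4) for (d in c(2, 4)) for (H in c(1, 2)) {
    if (d %% H != 0) next
    X <- matrix(rnorm(Tn * d), Tn, d)
    Wq <- matrix(rnorm(d * d), d, d)
    Wk <- matrix(rnorm(d * d), d, d)
    Wv <- matrix(rnorm(d * d), d, d)
    expect_equal(
      multiHeadSelfAttention(X, list(Wq = Wq, Wk = Wk, Wv = Wv), H = H),
      oracle_mhsa(X, Wq, Wk, Wv, H), tolerance = 1e-6,
      label = sprintf("T=%d d=%d H=%d", Tn, d, H))
  }
})

test_that("attention over identical tokens with identity projections is identity", {
  X <- matrix(rep(c(1.5, -0.5), each = 2), 2, 2)
  id <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2))
  expect_equal(multiHeadSelfAttention(X, id, H = 1), X, tolerance = 1e-12)
  expect_error(multiHeadSelfAttention(matrix(0, 2, 3), id, H = 2),
               "divisible")
})

test_that("encoder block preserves shape and wires residuals as configured", {
  set.seed(6)
  d <- 4; Tn <- 2
  X <- matrix(rnorm(Tn * d), Tn, d)
  zeroW <- matrix(0, d, d)
  w <- list(Wq = zeroW, Wk = zeroW, Wv = zeroW,
            ln1 = list(gamma = rep(1, d), beta = rep(0, d)),
            ff1 = list(W = matrix(0, 3, d), b = rep(0, 3)),
            ff2 = list(W = matrix(0, d, 3), b = rep(0, d)),
            ln2 = list(gamma = rep(1, d), beta = rep(0, d)))
  ln <- function(M) t(apply(M, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
  }))
  # zero attention/FF weights: MHSA = 0, IO1 = LN(X), IO2 = IO1,
  # as-printed wiring closes with LN(IO1 + X)
  got_x <- encoderBlock(X, w, H = 1, wiring = "x")
  expect_equal(got_x, ln(ln(X) + X), tolerance = 1e-10)
  got_io2 <- encoderBlock(X, w, H = 1, wiring = "io2")
  expect_equal(got_io2, ln(ln(X)), tolerance = 1e-10)
  expect_identical(dim(got_x), dim(X))
})

test_that("layer norm standardizes each token before the affine map", {
  set.seed(7)
  X <- array(rnorm(5 * 3 * 2), dim = c(5, 3, 2))
  out <- sleepExit:::ln_fwd(X, gamma = rep(1, 5), beta = rep(0, 5))
  m <- matrix(out$y, nrow = 5)
  expect_equal(colMeans(m), rep(0, 6), tolerance = 1e-10)
  expect_equal(apply(m, 2, function(v) mean(v^2)), rep(1, 6),
               tolerance = 1e-4)
})

test_that("head probabilities are a proper softmax with shift invariance", {
  cfg <- tiny_config()
  m <- sleepNet(cfg, seed = 8)
  set.seed(8)
  st <- array(rnorm(3 * 4 * 8), dim = c(3, 4, 8))
  p <- predictProbs(st, m@params$head[[3]], cfg)
  expect_equal(colSums(p), 1, tolerance = 1e-9)
  expect_true(all(p > 0))
  shifted <- m@params$head[[3]]
  shifted$cls$l2$b <- shifted$cls$l2$b + 7.3
  expect_equal(predictProbs(st, shifted, cfg), p, tolerance = 1e-9)
  # an untrained head is near-agnostic: high normalized entropy
  expect_gt(normalizedEntropy(p[, 1]), 0.8)
})

test_that("exit k consumes exactly the first k modalities", {
  cfg <- tiny_config()
  m <- sleepNet(cfg, seed = 9)
  es <- synthesizeDataset(syntheticConfig(n_epochs = 6, seed = 10))
  base <- exitProbabilities(m, es)
  set.seed(101)
  perturbed <- es
  SummarizedExperiment::assay(perturbed, "emg") <-
    matrix(rnorm(3000 * 6), 3000, 6)
  pe <- exitProbabilities(m, perturbed)
  expect_equal(pe$p1, base$p1, tolerance = 1e-12)   # EEG exit blind to EMG
  expect_equal(pe$p2, base$p2, tolerance = 1e-12)   # EOG exit blind to EMG
  expect_false(isTRUE(all.equal(pe$p3, base$p3, tolerance = 1e-6)))
  perturbed2 <- es
  SummarizedExperiment::assay(perturbed2, "eog") <-
    matrix(rnorm(3000 * 6), 3000, 6)
  pe2 <- exitProbabilities(m, perturbed2)
  expect_equal(pe2$p1, base$p1, tolerance = 1e-12)  # EEG exit blind to EOG
  expect_false(isTRUE(all.equal(pe2$p2, base$p2, tolerance = 1e-6)))
})

test_that("the three heads are structurally near-identical up to depth L", {
  cfg <- tiny_config()
  m <- sleepNet(cfg, seed = 10)
  hs <- m@params$head
  # identical block structure at every level
  for (h in hs) expect_identical(names(h), c("se", "enc", "cls"))
  for (h in hs) expect_identical(names(h$enc), names(hs[[1]]$enc))
  # encoder blocks are size-identical across exits (d-dependent only)
  for (h in hs[-1]) {
    expect_identical(dim(h$enc$Wq), dim(hs[[1]]$enc$Wq))
    expect_identical(dim(h$cls$l2$W), dim(hs[[1]]$cls$l2$W))
  }
  # the classifier input width grows linearly with the modality depth L
  in_w <- vapply(hs, function(h) ncol(h$cls$l1$W), numeric(1))
  expect_equal(in_w / in_w[1], c(1, 2, 3))
})
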