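test_that("KL divergence satisfies its identities", {
  p <- c(0.2, 0.3, 0.1, 0.25, 0.15)
  expect_equal(klDivergence(p, p), 0)
  expect_equal(klDivergence(c(1, 0, 0, 0, 0), rep(0.2, 5)), log(5),
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:200) {
    a <- stats::runif(5); a <- a / sum(a)
    b <- stats::runif(5) + 1e-3; b <- b / sum(b)
    expect_gte(klDivergence(a, b), 0)
  }
  expect_error(klDivergence(c(0.5, 0.6), c(0.5, 0.5)), "distribution")
})

test_that("the distillation loss is the sum of the two student divergences", {
  set.seed(24)
  for (i in 1:20) {
    ps1 <- stats::runif(5); ps1 <- ps1 / sum(ps1)
    ps2 <- stats::runif(5); ps2 <- ps2 / sum(ps2)
    pt <- stats::runif(5) + 0.01; pt <- pt / sum(pt)
    expect_equal(selfDistillLoss(ps1, ps2, pt),
                 klDivergence(ps1, pt) + klDivergence(ps2, pt))
  }
  u <- rep(0.2, 5)
  expect_equal(selfDistillLoss(u, u, u), 0)
})

test_that("stage 1 trains only the backbone and final exit, reproducibly", {
  cfg <- tiny_config()
  es <- synthesizeDataset(syntheticConfig(n_epochs = 30, seed = 25))
  m0 <- sleepNet(cfg, seed = 2)
  tc <- trainConfig(epochs = 2, batch_size = 10, seed = 3)
  m1 <- trainSingleExit(m0, es, tc)
  expect_identical(m1@trainedStage, 1L)
  # early-exit parameters bit-identical to initialization
  expect_identical(m1@params$head[[1]], m0@params$head[[1]])
  expect_identical(m1@params$head[[2]], m0@params$head[[2]])
  expect_false(identical(m1@params$head[[3]], m0@params$head[[3]]))
  expect_false(identical(m1@params$efem, m0@params$efem))
  # seeded determinism
  m1b <- trainSingleExit(m0, es, tc)
  expect_identical(m1@params, m1b@params)
  expect_identical(m1@history$stage1, m1b@history$stage1)
  expect_identical(nrow(m1@history$stage1), 2L)
})

test_that("the final exit learns separable synthetic data", {
  cfg <- reducedSleepNetConfig()
  es <- synthesizeDataset(syntheticConfig(
    n_epochs = 300,
    tier_proportions = c(eeg_separable = 1, eog_required = 0,
                         emg_required = 0),
    seed = 26))
  m <- sleepNet(cfg, seed = 4)
  m1 <- trainSingleExit(m, es, trainConfig(epochs = 30, batch_size = 64,
                                           lr = 3e-3, seed = 5))
  expect_true(all(is.finite(m1@history$stage1$loss)))
  expect_gte(utils::tail(m1@history$stage1$acc, 1), 0.9)
  # loss decreases overall
  expect_lt(utils::tail(m1@history$stage1$loss, 1),
            m1@history$stage1$loss[1])
})

test_that("stage 2 freezes the backbone and teacher and trains the students", {
  cfg <- tiny_config()
  es <- synthesizeDataset(syntheticConfig(n_epochs = 30, seed = 27))
  m0 <- sleepNet(cfg, seed = 6)
  expect_error(trainMultiExit(m0, es), "stage-1")
  m1 <- trainSingleExit(m0, es, trainConfig(epochs = 2, batch_size = 10,
                                            seed = 7))
  m2 <- trainMultiExit(m1, es, trainConfig(epochs = 5, batch_size = 10,
                                           seed = 8))
  expect_identical(m2@trainedStage, 2L)
  # frozen parts bit-identical
  expect_identical(m2@params$efem, m1@params$efem)
  expect_identical(m2@params$head[[3]], m1@params$head[[3]])
  expect_identical(m2@state, m1@state)
  expect_false(identical(m2@params$head[[1]], m1@params$head[[1]]))
  expect_false(identical(m2@params$head[[2]], m1@params$head[[2]]))
  # zero loss weights leave even the students untouched
  m2z <- trainMultiExit(m1, es, trainConfig(epochs = 2, batch_size = 10,
                                            kd_weight = 0, ce_weight = 0,
                                            seed = 9))
  expect_identical(m2z@params, m1@params)
  # determinism
  m2b <- trainMultiExit(m1, es, trainConfig(epochs = 5, batch_size = 10,
                                            seed = 8))
  expect_identical(m2@params, m2b@params)
})

test_that("distillation moves the students toward the teacher", {
  cfg <- tiny_config()
  es <- synthesizeDataset(syntheticConfig(n_epochs = 60, seed = 28))
  m1 <- trainSingleExit(sleepNet(cfg, seed = 10), es,
                        trainConfig(epochs = 4, batch_size = 20, lr = 2e-3,
                                    seed = 11))
  pt <- exitProbabilities(m1, es)$p3
  kl_of <- function(m) {
    ps <- exitProbabilities(m, es)$p1
    mean(vapply(seq_len(ncol(ps)), function(i)
      klDivergence(ps[, i], pt[, i]), numeric(1)))
  }
  before <- kl_of(m1)
  m2 <- trainMultiExit(m1, es, trainConfig(epochs = 10, batch_size = 20,
                                           lr = 2e-3, seed = 12))
  expect_lt(kl_of(m2), before)
  expect_true(all(is.finite(m2@history$stage2$loss)))
})
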