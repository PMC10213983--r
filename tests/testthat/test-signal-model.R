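test_that("stage templates encode the canonical band structure", {
  n3 <- stageTemplate("N3")
  expect_identical(names(which.max(n3$band_weights)), "delta")
  expect_true(n3$band_weights["delta"] > max(n3$band_weights[-1]))
  w <- stageTemplate("W")
  expect_gt(w$band_weights["alpha"], w$band_weights["delta"])
  for (s in SLEEP_STAGES) {
    tpl <- stageTemplate(s)
    expect_gt(sum(tpl$band_weights), 0)
    expect_gte(tpl$eog_event_rate, 0)
    expect_gte(tpl$emg_tone, 0)
    expect_identical(tpl, stageTemplate(s))  # deterministic
  }
  expect_error(stageTemplate("N5"), "N5")
})

test_that("synthesized epochs have the right length, spectrum and determinism", {
  cfg <- syntheticConfig(seed = 7)
  rec <- synthesizeEpoch("N3", "eeg_separable", cfg, seed = 7)
  expect_length(rec$signals$eeg, 3000)   # 30 s x 100 Hz
  expect_length(rec$signals$emg, 3000)

  # dominant slow-wave content: > 50% of total power in 0.5-4 Hz, checked
  # against an independent periodogram (spec.pgram) integration
  x <- rec$signals$eeg
  sp <- stats::spec.pgram(stats::ts(x, frequency = 100), plot = FALSE,
                          taper = 0, detrend = TRUE)
  frac_indep <- sum(sp$spec[sp$freq >= 0.5 & sp$freq < 4]) / sum(sp$spec)
  expect_gt(frac_indep, 0.5)
  expect_gt(bandPower(x, 100, 0.5, 4) / bandPower(x, 100, 0, 50), 0.5)

  rec2 <- synthesizeEpoch("N3", "eeg_separable", cfg, seed = 7)
  expect_identical(rec, rec2)
  rec3 <- synthesizeEpoch("N3", "eeg_separable", cfg, seed = 8)
  expect_false(identical(rec$signals$eeg, rec3$signals$eeg))

  bad <- cfg; bad$sampling_rates["eeg"] <- -1
  expect_error(synthesizeEpoch("N3", "eeg_separable", bad, 1), "positive")
})

test_that("dataset class counts follow largest-remainder apportionment", {
  p <- c(0.193, 0.069, 0.414, 0.142, 0.182)
  expect_identical(apportionCounts(100, p), oracle_apportion(100, p))
  expect_identical(apportionCounts(100, p), c(19L, 7L, 42L, 14L, 18L))

  set.seed(1)
  for (i in 1:20) {
    pr <- stats::runif(5); pr <- pr / sum(pr)
    n <- sample(5:500, 1)
    a <- apportionCounts(n, pr)
    expect_identical(sum(a), as.integer(n))
    expect_true(all(abs(a - n * pr) <= 1))
  }

  es <- synthesizeDataset(syntheticConfig(n_epochs = 100,
                                          class_proportions = p, seed = 3))
  expect_identical(unname(c(table(stages(es)))), c(19L, 7L, 42L, 14L, 18L))

  es5 <- synthesizeDataset(syntheticConfig(n_epochs = 5,
    class_proportions = rep(0.2, 5), seed = 1))
  expect_identical(unname(c(table(stages(es5)))), rep(1L, 5))

  esA <- synthesizeDataset(syntheticConfig(n_epochs = 40, seed = 11))
  esB <- synthesizeDataset(syntheticConfig(n_epochs = 40, seed = 11))
  expect_identical(as.character(stages(esA)), as.character(stages(esB)))
  expect_identical(SummarizedExperiment::assay(esA, "eeg"),
                   SummarizedExperiment::assay(esB, "eeg"))

  expect_error(synthesizeDataset(syntheticConfig(n_epochs = 3)), "nonzero")
})

test_that("every stage's dominant band matches its template on average", {
  cfg <- syntheticConfig(seed = 5)
  bands <- EEG_BANDS
  for (s in SLEEP_STAGES) {
    tpl <- stageTemplate(s)
    pw <- matrix(0, 50, length(bands))
    for (i in 1:50) {
      rec <- synthesizeEpoch(s, "eeg_separable", cfg, seed = 1000 + i)
      for (b in seq_along(bands))
        pw[i, b] <- bandPower(rec$signals$eeg, 100,
                              bands[[b]][1], bands[[b]][2])
    }
    expect_identical(which.max(colMeans(pw)),
                     unname(which.max(tpl$band_weights)),
                     label = paste("stage", s))
  }
})

test_that("difficulty tiers control EEG separability (stump on delta power)", {
  cfg <- syntheticConfig(seed = 2)
  gen <- function(tier) {
    stage <- rep(c("N3", "W"), each = 100)
    x <- vapply(seq_along(stage), function(i) {
      rec <- synthesizeEpoch(stage[i], tier, cfg, seed = 5000 + i)
      bandPower(rec$signals$eeg, 100, 0.5, 4)
    }, numeric(1))
    stump_accuracy(x, stage == "N3")
  }
  expect_gte(gen("eeg_separable"), 0.95)
  expect_lte(gen("emg_required"), 0.70)
})

test_that("class fraction bookkeeping reproduces published stage fractions", {
  f78 <- classFractions(psgClassCounts[["sleep-edf-78"]])
  expect_equal(round(unname(f78["W"]), 1), 33.7)
  f20 <- classFractions(psgClassCounts[["sleep-edf-20"]])
  expect_equal(round(unname(f20["N2"]), 1), 41.4)
  # the same counting code applied to a realized label vector
  labs <- rep(SLEEP_STAGES, c(20, 10, 40, 10, 20))
  expect_equal(unname(classFractions(labs)["N2"]), 40)
})
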