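# One shared end-to-end training run (reduced-width configuration, 1500
# synthetic epochs, both stages), memoized across test files.  Several
# acceptance checks interrogate the same trained model.

.trained_cache <- new.env(parent = emptyenv())

trained_pipeline <- function() {
  if (!is.null(.trained_cache$fit)) return(.trained_cache$fit)
  tiers <- c(eeg_separable = 0.5, eog_required = 0.3, emg_required = 0.2)
  train_es <- synthesizeDataset(syntheticConfig(
    n_epochs = 1500, tier_proportions = tiers, seed = 101))
  cfg <- reducedSleepNetConfig()
  m0 <- sleepNet(cfg, seed = 1)
  m1 <- trainSingleExit(m0, train_es,
                        trainConfig(epochs = 22, batch_size = 64, lr = 3e-3,
                                    seed = 1))
  m2 <- trainMultiExit(m1, train_es,
                       trainConfig(epochs = 25, batch_size = 64, lr = 2e-3,
                                   seed = 1))
  .trained_cache$fit <- list(config = cfg, data = train_es,
                             stage0 = m0, stage1 = m1, stage2 = m2)
  .trained_cache$fit
}
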