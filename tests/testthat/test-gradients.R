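# Finite-difference verification of the hand-derived backward passes on a
# narrow configuration.  Coordinates whose analytic gradient is ~0 (conv
# biases immediately followed by batch norm) are excluded from the relative
# comparison since central differences are noise-dominated there.

test_that("backbone and final-head gradients match finite differences", {
  cfg <- tiny_config()
  m <- sleepNet(cfg, seed = 11)
  es <- synthesizeDataset(syntheticConfig(n_epochs = 6, seed = 9))
  labels <- as.integer(stages(es))[1:3]
  xs <- lapply(cfg$modalities, function(md)
    sleepExit:::modality_batch(es, md, 1:3, TRUE))

  loss_grad <- function(params, want_grad = TRUE) {
    st <- sleepExit:::init_state(cfg)
    fw <- sleepExit:::features_fwd(params, st, cfg, xs, 3, training = TRUE)
    hc <- sleepExit:::head_fwd(sleepExit:::stack_features(fw$feats),
                               params$head[[3]], cfg)
    Y <- sleepExit:::onehot(labels, 5)
    loss <- -mean(log(pmax(colSums(hc$probs * Y), 1e-12)))
    if (!want_grad) return(loss)
    hb <- sleepExit:::head_bwd((hc$probs - Y) / 3, hc)
    ge <- list()
    for (j in 1:3) {
      md <- cfg$modalities[j]
      dfeat <- hb$dstack[j, , , , drop = TRUE]
      if (length(dim(dfeat)) == 2)
        dfeat <- array(dfeat, dim = c(dim(dfeat), 1))
      ge[[md]] <- sleepExit:::efem_bwd(dfeat, fw$caches[[j]], cfg$efem$f3)
    }
    list(loss = loss, grad = list(efem = ge, head3 = hb$g))
  }

  p0 <- m@params
  r <- loss_grad(p0)
  expect_true(is.finite(r$loss))

  set.seed(31)
  # backbone block
  pv <- sleepExit:::param_flatten(p0$efem)
  gv <- sleepExit:::param_flatten(r$grad$efem)
  idx <- sample(length(pv), 25)
  for (i in idx) {
    f <- function(d) {
      v <- pv; v[i] <- v[i] + d
      pp <- p0; pp$efem <- sleepExit:::param_unflatten(p0$efem, v)
      loss_grad(pp, want_grad = FALSE)
    }
    num <- (f(1e-5) - f(-1e-5)) / 2e-5
    if (abs(num) + abs(gv[i]) < 1e-6) next  # BN-cancelled direction
    expect_lt(abs(num - gv[i]) / (abs(num) + abs(gv[i])), 1e-3)
  }
  # final head block (includes SE, attention, encoder, classifier)
  pv <- sleepExit:::param_flatten(p0$head[[3]])
  gv <- sleepExit:::param_flatten(r$grad$head3)
  idx <- sample(length(pv), 20)
  for (i in idx) {
    f <- function(d) {
      v <- pv; v[i] <- v[i] + d
      pp <- p0; pp$head[[3]] <- sleepExit:::param_unflatten(p0$head[[3]], v)
      loss_grad(pp, want_grad = FALSE)
    }
    num <- (f(1e-5) - f(-1e-5)) / 2e-5
    if (abs(num) + abs(gv[i]) < 1e-6) next
    expect_lt(abs(num - gv[i]) / (abs(num) + abs(gv[i])), 1e-3)
  }
})

test_that("distillation gradients through a student head match finite differences", {
  cfg <- tiny_config()
  m <- sleepNet(cfg, seed = 12)
  es <- synthesizeDataset(syntheticConfig(n_epochs = 6, seed = 13))
  xs <- lapply(cfg$modalities, function(md)
    sleepExit:::modality_batch(es, md, 1:3, TRUE))
  st0 <- sleepExit:::init_state(cfg)
  fw <- sleepExit:::features_fwd(m@params, st0, cfg, xs, 3, training = FALSE)
  pt <- sleepExit:::head_fwd(sleepExit:::stack_features(fw$feats),
                             m@params$head[[3]], cfg)$probs
  log_pt <- log(pmax(pt, 1e-12))

  loss_grad <- function(hp, want_grad = TRUE) {
    hc <- sleepExit:::head_fwd(sleepExit:::stack_features(fw$feats[1:2]),
                               hp, cfg)
    ps <- hc$probs
    log_ps <- log(pmax(ps, 1e-12))
    loss <- sum(ps * (log_ps - log_pt)) / 3
    if (!want_grad) return(loss)
    g <- log_ps - log_pt
    dl <- ps * sweep(g, 2, colSums(ps * g), "-") / 3
    list(loss = loss, grad = sleepExit:::head_bwd(dl, hc)$g)
  }
  hp0 <- m@params$head[[2]]
  r <- loss_grad(hp0)
  expect_gte(r$loss, 0)
  pv <- sleepExit:::param_flatten(hp0)
  gv <- sleepExit:::param_flatten(r$grad)
  set.seed(32)
  for (i in sample(length(pv), 20)) {
    f <- function(d) {
      v <- pv; v[i] <- v[i] + d
      loss_grad(sleepExit:::param_unflatten(hp0, v), want_grad = FALSE)
    }
    num <- (f(1e-6) - f(-1e-6)) / 2e-6
    if (abs(num) + abs(gv[i]) < 1e-6) next
    expect_lt(abs(num - gv[i]) / (abs(num) + abs(gv[i])), 1e-3)
  }
})
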