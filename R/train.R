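# Two-stage training: (1) backbone + final exit with cross-entropy;
# (2) backbone and final exit frozen, early exits trained by
# self-distillation against the final exit's output distribution.

#' Kullback-Leibler divergence between two class distributions
#'
#' `sum(ps * log(ps / pt))` in nats, with the `0 * log 0 = 0` convention and
#' probabilities clamped at `clamp` before the logarithm (the divergence is
#' undefined at exact zeros of `pt`).  Nonnegative; zero iff the
#' distributions coincide.
#'
#' @param ps,pt Nonnegative vectors summing to 1 (student, teacher).
#' @param clamp Lower clamp applied before taking logs.
#' @return Nonnegative scalar (nats).
#' @examples
#' klDivergence(c(1, 0, 0, 0, 0), rep(0.2, 5))  # log(5)
#' @export
klDivergence <- function(ps, pt, clamp = 1e-12) {
  check_dist <- function(p, nm) {
    if (any(!is.finite(p)) || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
      stop(nm, " is not a probability distribution")
  }
  check_dist(ps, "ps"); check_dist(pt, "pt")
  if (length(ps) != length(pt)) stop("distributions differ in length")
  ps <- pmax(ps, 0)
  ptc <- pmax(pt, clamp)
  nz <- ps > 0
  sum(ps[nz] * (log(ps[nz]) - log(ptc[nz])))
}

#' Self-distillation loss of the two student exits
#'
#' Sum of the student-vs-teacher KL divergences; the teacher distribution is
#' treated as a constant (no gradient flows into it during training).
#'
#' @param ps1,ps2 Student exit distributions.
#' @param pt Teacher (final exit) distribution.
#' @return Nonnegative scalar.
#' @export
selfDistillLoss <- function(ps1, ps2, pt) {
  klDivergence(ps1, pt) + klDivergence(ps2, pt)
}

## ---- Adam ------------------------------------------------------------------

adam_new <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g^2
      list(p = p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps), m = m2, v = v2)
    }
  }
  r <- upd(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

## ---- batching --------------------------------------------------------------

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

onehot <- function(labels, n_classes) {
  Y <- matrix(0, n_classes, length(labels))
  Y[cbind(as.integer(labels), seq_along(labels))] <- 1
  Y
}

#' Training configuration
#'
#' @param epochs Passes over the data.
#' @param batch_size Samples per optimizer step.
#' @param lr Adam learning rate.
#' @param kd_weight Weight of the distillation (KL) term in stage 2.
#' @param ce_weight Weight of an optional hard-label cross-entropy term in
#'   stage 2 (0 = pure distillation, the default regimen).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 10, batch_size = 64, lr = 1e-3,
                        kd_weight = 1, ce_weight = 0, seed = 1L,
                        verbose = FALSE) {
  stopifnot(batch_size >= 1, kd_weight >= 0, ce_weight >= 0)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 kd_weight = kd_weight, ce_weight = ce_weight,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "TrainConfig")
}

## ---- stage 1: backbone + final exit ----------------------------------------

#' Stage-1 training: backbone and final exit
#'
#' Trains the three modality feature extractors and the deepest (final) exit
#' with cross-entropy on the five stage classes; the two early exits are not
#' enabled and their parameters are left bit-identical to initialization.
#'
#' @param model An untrained or stage-1 [SleepNet-class].
#' @param data An [EpochSet-class] with stage labels.
#' @param config A [trainConfig()].
#' @return The trained model (`trainedStage = 1`) with a `stage1` history
#'   data frame of per-epoch loss and training accuracy.
#' @export
trainSingleExit <- function(model, data, config = trainConfig()) {
  cfg <- model@config
  params <- model@params
  state <- model@state
  n <- ncol(data)
  labels <- as.integer(stages(data))
  depth <- length(cfg$modalities)
  final <- depth
  opt_e <- adam_new(params$efem)
  opt_h <- adam_new(params$head[[final]])
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  Xall <- lapply(cfg$modalities, function(m)
    modality_batch(data, m, seq_len(n), cfg$normalize))

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (idx in batch_indices(n, config$batch_size)) {
        ii <- ord[idx]
        B <- length(ii)
        xs <- lapply(Xall, function(X) X[, , ii, drop = FALSE])
        fw <- features_fwd(params, state, cfg, xs, depth, training = TRUE)
        st <- stack_features(fw$feats)
        hc <- head_fwd(st, params$head[[final]], cfg)
        Y <- onehot(labels[ii], cfg$n_classes)
        p_true <- pmax(colSums(hc$probs * Y), 1e-12)
        loss <- -mean(log(p_true))
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", ep, "; lower the learning rate")
        tot_loss <- tot_loss + loss * B
        tot_correct <- tot_correct +
          sum(max.col(t(hc$probs)) == labels[ii])
        dlogits <- (hc$probs - Y) / B
        hb <- head_bwd(dlogits, hc)
        ge <- list()
        for (j in seq_len(depth)) {
          m <- cfg$modalities[j]
          dfeat <- hb$dstack[j, , , , drop = TRUE]
          if (length(dim(dfeat)) == 2) dfeat <- array(dfeat, dim = c(dim(dfeat), 1))
          ge[[m]] <- efem_bwd(dfeat, fw$caches[[j]], cfg$efem$f3)
          state$efem[[m]] <- list(
            small = branch_state_update(fw$caches[[j]]$small),
            large = branch_state_update(fw$caches[[j]]$large))
        }
        r <- adam_step(params$efem, ge, opt_e, config$lr)
        params$efem <- r$params; opt_e <- r$opt
        r <- adam_step(params$head[[final]], hb$g, opt_h, config$lr)
        params$head[[final]] <- r$params; opt_h <- r$opt
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n,
                                     acc = tot_correct / n))
      if (config$verbose)
        message(sprintf("stage1 epoch %d  loss %.4f  acc %.3f",
                        ep, tot_loss / n, tot_correct / n))
    }
  })
  model@params <- params
  model@state <- state
  model@trainedStage <- 1L
  model@history$stage1 <- hist
  model
}

## ---- stage 2: early exits by self-distillation -----------------------------

#' Stage-2 training: early exits by self-distillation
#'
#' Freezes every feature-extractor and final-exit parameter (and batch-norm
#' statistics), then trains the two early exits to match the frozen final
#' exit's output distribution by KL divergence (optionally plus a hard-label
#' cross-entropy term).  The teacher receives no gradient.
#'
#' @inheritParams trainSingleExit
#' @return The trained model (`trainedStage = 2`) with a `stage2` history.
#' @export
trainMultiExit <- function(model, data, config = trainConfig()) {
  if (model@trainedStage < 1L)
    stop("stage-2 training requires a stage-1 trained model ",
         "(run trainSingleExit first)")
  cfg <- model@config
  params <- model@params
  state <- model@state
  n <- ncol(data)
  labels <- as.integer(stages(data))
  depth <- length(cfg$modalities)
  final <- depth
  students <- seq_len(depth - 1)
  opts <- lapply(students, function(L) adam_new(params$head[[L]]))
  hist <- data.frame(epoch = integer(), loss = numeric())

  # backbone and teacher are frozen: features and teacher distributions are
  # fixed for the whole stage and computed once
  feats_all <- vector("list", depth)
  pt_all <- matrix(0, cfg$n_classes, n)
  for (idx in batch_indices(n, config$batch_size)) {
    xs <- lapply(cfg$modalities, function(m)
      modality_batch(data, m, idx, cfg$normalize))
    fw <- features_fwd(params, state, cfg, xs, depth, training = FALSE)
    for (j in seq_len(depth)) {
      if (is.null(feats_all[[j]])) {
        dm <- dim(fw$feats[[j]])
        feats_all[[j]] <- array(0, dim = c(dm[1], dm[2], n))
      }
      feats_all[[j]][, , idx] <- fw$feats[[j]]
    }
    pt_all[, idx] <- head_fwd(stack_features(fw$feats),
                              params$head[[final]], cfg)$probs
  }

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      for (idx in batch_indices(n, config$batch_size)) {
        ii <- ord[idx]
        B <- length(ii)
        feats <- lapply(feats_all, function(X) X[, , ii, drop = FALSE])
        pt <- pt_all[, ii, drop = FALSE]
        log_pt <- log(pmax(pt, 1e-12))
        Y <- onehot(labels[ii], cfg$n_classes)
        for (L in students) {
          hc <- head_fwd(stack_features(feats[seq_len(L)]),
                         params$head[[L]], cfg)
          ps <- hc$probs
          log_ps <- log(pmax(ps, 1e-12))
          kl <- sum(ps * (log_ps - log_pt)) / B
          ce <- -mean(log(pmax(colSums(ps * Y), 1e-12)))
          loss <- config$kd_weight * kl + config$ce_weight * ce
          if (!is.finite(loss))
            stop("non-finite distillation loss at epoch ", ep)
          tot_loss <- tot_loss + loss * B
          g <- log_ps - log_pt
          dkl <- ps * sweep(g, 2, colSums(ps * g), "-") / B
          dce <- (ps - Y) / B
          dlogits <- config$kd_weight * dkl + config$ce_weight * dce
          if (config$kd_weight == 0 && config$ce_weight == 0) next
          hb <- head_bwd(dlogits, hc)
          r <- adam_step(params$head[[L]], hb$g, opts[[L]], config$lr)
          params$head[[L]] <- r$params; opts[[L]] <- r$opt
        }
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n))
      if (config$verbose)
        message(sprintf("stage2 epoch %d  loss %.4f", ep, tot_loss / n))
    }
  })
  model@params <- params
  model@trainedStage <- 2L
  model@history$stage2 <- hist
  model
}
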