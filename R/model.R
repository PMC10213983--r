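# Model definition: multi-scale convolutional feature extractors with
# channel/spatial attention (one per modality), and three exit heads of
# increasing modality depth (SE modality gate + transformer encoder + linear
# classifier).  Forward and backward passes are hand-derived; batches are
# channel-major arrays (C, L, B).

#' Model configuration
#'
#' Defaults describe the Sleep-EDF-shaped reference network: 30-s epochs at
#' 100 Hz on three modalities; per modality two convolutional branches (small
#' kernels 64/8/8 with strides 8/1/1 and an 8-wide max-pool after the first
#' block for waveforms above ~4 Hz; large kernels 512/6/6 with strides 64/1/1
#' and a 2-wide pool for slow-wave content), concatenated channel-wise and
#' passed through channel-then-spatial attention; every branch output is
#' aligned to a common `d_out`-long grid by adaptive max-pooling.  Exit L
#' stacks the first L modalities' feature maps, recalibrates them with a
#' squeeze-and-excitation gate, runs one transformer encoder block
#' (multi-head self-attention over the L*C tokens of length `d_out`), and
#' classifies with two linear layers.
#'
#' Filter widths `f1, f2, f3` (84, 52, 32) and the classifier hidden width
#' (286) are the package's reference configuration whose closed-form cost is
#' documented in the profiling functions; all are overridable.
#'
#' @param modalities Modality names in exit order (EEG exit first).
#' @param sample_rate Hz of the harmonized input grid.
#' @param epoch_seconds Epoch duration (s).
#' @param n_classes Number of stage classes.
#' @param f1,f2,f3 Filters of the three conv layers in each branch.
#' @param small_kernels,small_strides,small_pool1 Small-kernel branch spec.
#' @param large_kernels,large_strides,large_pool1 Large-kernel branch spec.
#' @param d_out Common feature length after branch alignment.
#' @param cbam_r Channel-attention MLP reduction ratio (must divide `2*f3`).
#' @param cbam_spatial_kernel Spatial-attention kernel width (same padding).
#' @param leaky_slope Negative slope of leaky-ReLU activations.
#' @param dropout Dropout probability after the first pooled conv block.
#' @param H Attention head count (must divide `d_out`).
#' @param ff Feed-forward width of the encoder block.
#' @param hidden Width of the first classifier linear layer.
#' @param post_ln_residual Residual wired into the encoder's closing layer
#'   norm: `"x"` connects the block input (as-printed wiring), `"io2"` uses
#'   only the feed-forward output (conventional wiring).
#' @param normalize Z-score every epoch per channel before the network.
#' @return Configuration list.
#' @export
sleepNetConfig <- function(modalities = c("eeg", "eog", "emg"),
                           sample_rate = 100, epoch_seconds = 30,
                           n_classes = 5,
                           f1 = 84, f2 = 52, f3 = 32,
                           small_kernels = c(64, 8, 8),
                           small_strides = c(8, 1, 1),
                           small_pool1 = 8,
                           large_kernels = c(512, 6, 6),
                           large_strides = c(64, 1, 1),
                           large_pool1 = 2,
                           d_out = 8,
                           cbam_r = 8,
                           cbam_spatial_kernel = 7,
                           leaky_slope = 0.01,
                           dropout = 0.5,
                           H = 8, ff = 16, hidden = 286,
                           post_ln_residual = c("x", "io2"),
                           normalize = TRUE) {
  cfg <- list(
    modalities = modalities, sample_rate = sample_rate,
    epoch_seconds = epoch_seconds, n_classes = n_classes,
    efem = list(f1 = f1, f2 = f2, f3 = f3,
                small = list(k = small_kernels, s = small_strides,
                             pool1 = small_pool1),
                large = list(k = large_kernels, s = large_strides,
                             pool1 = large_pool1),
                d_out = d_out, cbam_r = cbam_r,
                cbam_spatial_kernel = cbam_spatial_kernel,
                leaky_slope = leaky_slope, dropout = dropout),
    head = list(H = H, ff = ff, hidden = hidden,
                post_ln_residual = match.arg(post_ln_residual)),
    normalize = normalize)
  C <- 2 * f3
  if (C %% cbam_r != 0)
    stop("cbam_r (", cbam_r, ") must divide the fused channel count ", C)
  if (d_out %% H != 0)
    stop("head count H (", H, ") must divide d_out (", d_out, ")")
  sh <- efem_shapes(cfg)
  if (sh$small[4] < d_out || sh$large[4] < d_out)
    stop("branch output shorter than d_out; reduce d_out or pooling")
  cfg
}

#' Reduced-width configuration for desk-scale experiments
#'
#' Same topology as [sleepNetConfig()] with narrow layers (16/16/8 filters,
#' hidden width 32), sized so the full two-stage training regimen runs on a
#' single CPU in minutes.
#' @param ... Overrides passed to [sleepNetConfig()].
#' @export
reducedSleepNetConfig <- function(...) {
  sleepNetConfig(f1 = 16, f2 = 16, f3 = 8, hidden = 32, ...)
}

# per-branch position counts: after conv1, pool1, conv2, conv3
efem_shapes <- function(cfg) {
  Lin <- round(cfg$sample_rate * cfg$epoch_seconds)
  sh <- function(b) {
    L1 <- conv_out_len(Lin, b$k[1], b$s[1])
    P1 <- L1 %/% b$pool1
    L2 <- conv_out_len(P1, b$k[2], b$s[2])
    L3 <- conv_out_len(L2, b$k[3], b$s[3])
    c(L1, P1, L2, L3)
  }
  list(Lin = Lin, small = sh(cfg$efem$small), large = sh(cfg$efem$large))
}

#' Temporal span of one convolution window
#'
#' @param kernel Kernel size in samples.
#' @param sample_rate Sampling rate (Hz).
#' @return Seconds of signal covered by one convolution window.
#' @examples
#' convWindowSeconds(64, 100)   # 0.64
#' convWindowSeconds(512, 100)  # 5.12
#' @export
convWindowSeconds <- function(kernel, sample_rate) kernel / sample_rate

## ---- initialization --------------------------------------------------------

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
}

init_branch <- function(b, f1, f2, f3, Cin = 1) {
  list(conv1 = list(W = he_init(f1, Cin * b$k[1]), b = numeric(f1)),
       bn1 = list(gamma = rep(1, f1), beta = numeric(f1)),
       conv2 = list(W = he_init(f2, f1 * b$k[2]), b = numeric(f2)),
       bn2 = list(gamma = rep(1, f2), beta = numeric(f2)),
       conv3 = list(W = he_init(f3, f2 * b$k[3]), b = numeric(f3)),
       bn3 = list(gamma = rep(1, f3), beta = numeric(f3)))
}

init_efem <- function(cfg) {
  e <- cfg$efem
  C <- 2 * e$f3
  Ch <- C / e$cbam_r
  list(small = init_branch(e$small, e$f1, e$f2, e$f3),
       large = init_branch(e$large, e$f1, e$f2, e$f3),
       cbam = list(W1 = he_init(Ch, C), b1 = numeric(Ch),
                   W2 = he_init(C, Ch), b2 = numeric(C),
                   Wsp = he_init(1, 2 * e$cbam_spatial_kernel),
                   bsp = numeric(1)))
}

init_head <- function(cfg, L) {
  d <- cfg$efem$d_out
  C <- 2 * cfg$efem$f3
  h <- cfg$head$hidden
  ff <- cfg$head$ff
  Tn <- L * C
  list(
    se = list(c1 = list(W = he_init(L, L), b = numeric(L)),
              c2 = list(W = he_init(L, L), b = numeric(L)),
              g1 = list(W = he_init(L, L), b = numeric(L)),
              g2 = list(W = he_init(L, L), b = numeric(L))),
    enc = list(Wq = he_init(d, d), Wk = he_init(d, d), Wv = he_init(d, d),
               ln1 = list(gamma = rep(1, d), beta = numeric(d)),
               ff1 = list(W = he_init(ff, d), b = numeric(ff)),
               ff2 = list(W = he_init(d, ff), b = numeric(d)),
               ln2 = list(gamma = rep(1, d), beta = numeric(d))),
    cls = list(l1 = list(W = he_init(h, Tn * d), b = numeric(h)),
               l2 = list(W = he_init(cfg$n_classes, h),
                         b = numeric(cfg$n_classes))))
}

bn_state <- function(C) list(mean = numeric(C), var = rep(1, C))

init_state <- function(cfg) {
  e <- cfg$efem
  per_branch <- function() list(bn1 = bn_state(e$f1), bn2 = bn_state(e$f2),
                                bn3 = bn_state(e$f3))
  st <- list(efem = list())
  for (m in cfg$modalities)
    st$efem[[m]] <- list(small = per_branch(), large = per_branch())
  st
}

#' Create an untrained SleepNet model
#'
#' @param config A [sleepNetConfig()].
#' @param seed Integer seed for weight initialization.
#' @return A [SleepNet-class] object (trainedStage 0).
#' @export
sleepNet <- function(config = sleepNetConfig(), seed = 1L) {
  params <- with_seed(seed, {
    p <- list(efem = list(), head = list())
    for (m in config$modalities) p$efem[[m]] <- init_efem(config)
    for (L in seq_along(config$modalities)) p$head[[L]] <- init_head(config, L)
    p
  })
  new("SleepNet", config = config, params = params, state = init_state(config),
      trainedStage = 0L, history = list())
}

## ---- EFEM forward / backward ----------------------------------------------

branch_fwd <- function(x, bp, bst, bcfg, d_out, slope, dropout, training) {
  cc <- list()
  cc$c1 <- conv1d_fwd(x, bp$conv1$W, bp$conv1$b, bcfg$s[1], need_dx = FALSE)
  cc$b1 <- bn_fwd(cc$c1$y, bp$bn1$gamma, bp$bn1$beta,
                  bst$bn1$mean, bst$bn1$var, training)
  cc$a1 <- leaky_relu_fwd(cc$b1$y, slope)
  cc$p1 <- maxpool_fwd(cc$a1$y, bcfg$pool1)
  cc$do <- dropout_fwd(cc$p1$y, dropout, training)
  cc$c2 <- conv1d_fwd(cc$do$y, bp$conv2$W, bp$conv2$b, bcfg$s[2])
  cc$b2 <- bn_fwd(cc$c2$y, bp$bn2$gamma, bp$bn2$beta,
                  bst$bn2$mean, bst$bn2$var, training)
  cc$a2 <- leaky_relu_fwd(cc$b2$y, slope)
  cc$c3 <- conv1d_fwd(cc$a2$y, bp$conv3$W, bp$conv3$b, bcfg$s[3])
  cc$b3 <- bn_fwd(cc$c3$y, bp$bn3$gamma, bp$bn3$beta,
                  bst$bn3$mean, bst$bn3$var, training)
  cc$a3 <- leaky_relu_fwd(cc$b3$y, slope)
  L3 <- dim(cc$a3$y)[2]
  cc$align <- maxpool_fwd(cc$a3$y, L3 %/% d_out, n_windows = d_out)
  cc$y <- cc$align$y
  cc
}

branch_bwd <- function(dy, cc) {
  g <- list()
  d <- maxpool_bwd(dy, cc$align)
  d <- leaky_relu_bwd(d, cc$a3)
  bb <- bn_bwd(d, cc$b3)
  g$bn3 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  cb <- conv1d_bwd(bb$dx, cc$c3)
  g$conv3 <- list(W = cb$dW, b = cb$db)
  d <- leaky_relu_bwd(cb$dx, cc$a2)
  bb <- bn_bwd(d, cc$b2)
  g$bn2 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  cb <- conv1d_bwd(bb$dx, cc$c2)
  g$conv2 <- list(W = cb$dW, b = cb$db)
  d <- dropout_bwd(cb$dx, cc$do)
  d <- maxpool_bwd(d, cc$p1)
  d <- leaky_relu_bwd(d, cc$a1)
  bb <- bn_bwd(d, cc$b1)
  g$bn1 <- list(gamma = bb$dgamma, beta = bb$dbeta)
  cb <- conv1d_bwd(bb$dx, cc$c1)
  g$conv1 <- list(W = cb$dW, b = cb$db)
  # reorder to match param layout
  g[c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3")]
}

expand_rows <- function(M, d) {
  # (C, B) -> (C, d, B)
  aperm(array(M, dim = c(nrow(M), ncol(M), d)), c(1, 3, 2))
}

cbam_channel_fwd <- function(F, w) {
  C <- dim(F)[1]; d <- dim(F)[2]; B <- dim(F)[3]
  cc <- list(F = F)
  cc$avg <- colSums(aperm(F, c(2, 1, 3))) / d        # (C, B)
  op_count(C * d * B)
  cc$mx <- maxpool_fwd(F, d)
  mxm <- matrix(cc$mx$y, C, B)
  cc$d1a <- dense_fwd(cc$avg, w$W1, w$b1)
  cc$r1a <- relu_fwd(cc$d1a$y)
  cc$d2a <- dense_fwd(cc$r1a$y, w$W2, w$b2)
  cc$d1m <- dense_fwd(mxm, w$W1, w$b1)
  cc$r1m <- relu_fwd(cc$d1m$y)
  cc$d2m <- dense_fwd(cc$r1m$y, w$W2, w$b2)
  cc$Mc <- sigmoid_fwd(cc$d2a$y + cc$d2m$y)   # (C, B)
  cc$Mce <- expand_rows(cc$Mc, d)
  op_count(C * d * B)
  cc$y <- F * cc$Mce
  cc
}

cbam_channel_bwd <- function(dy, cc) {
  C <- dim(cc$F)[1]; d <- dim(cc$F)[2]; B <- dim(cc$F)[3]
  dMc <- colSums(aperm(dy * cc$F, c(2, 1, 3)))
  dF <- dy * cc$Mce
  dz <- sigmoid_bwd(dMc, cc$Mc)
  ba <- dense_bwd(dz, cc$d2a)
  bm <- dense_bwd(dz, cc$d2m)
  da1 <- ba$dx * cc$r1a$mask
  dm1 <- bm$dx * cc$r1m$mask
  ba1 <- dense_bwd(da1, cc$d1a)
  bm1 <- dense_bwd(dm1, cc$d1m)
  davg <- ba1$dx
  dmx <- bm1$dx
  dF <- dF + expand_rows(davg / d, d)
  dF <- dF + maxpool_bwd(array(dmx, dim = c(C, 1, B)), cc$mx)
  list(dF = dF,
       g = list(W1 = ba1$dW + bm1$dW, b1 = ba1$db + bm1$db,
                W2 = ba$dW + bm$dW, b2 = ba$db + bm$db))
}

cbam_spatial_fwd <- function(F, w, kernel) {
  C <- dim(F)[1]; d <- dim(F)[2]; B <- dim(F)[3]
  cc <- list(F = F, C = C)
  cc$avg <- colSums(F) / C                           # (d, B)
  op_count(C * d * B)
  Fp <- aperm(F, c(2, 1, 3))                    # (d, C, B)
  cc$mx <- maxpool_fwd(Fp, C)                   # (d, 1, B) over channels
  S <- array(0, dim = c(2, d, B))
  S[1, , ] <- cc$avg
  S[2, , ] <- matrix(cc$mx$y, d, B)
  pad <- (kernel - 1) %/% 2
  Sp <- array(0, dim = c(2, d + 2 * pad, B))
  Sp[, pad + seq_len(d), ] <- S
  cc$pad <- pad
  cc$conv <- conv1d_fwd(Sp, w$Wsp, w$bsp, 1L)
  cc$Ms <- sigmoid_fwd(cc$conv$y)               # (1, d, B)
  cc$Mse <- array(rep(as.vector(cc$Ms), each = C), dim = c(C, d, B))
  op_count(C * d * B)
  cc$y <- F * cc$Mse
  cc
}

cbam_spatial_bwd <- function(dy, cc) {
  C <- cc$C; d <- dim(cc$F)[2]; B <- dim(cc$F)[3]
  dMs <- array(colSums(dy * cc$F), dim = c(1, d, B))   # sum over channels
  dF <- dy * cc$Mse
  dconv <- sigmoid_bwd(dMs, cc$Ms)
  cb <- conv1d_bwd(dconv, cc$conv)
  dSp <- cb$dx
  dS <- dSp[, cc$pad + seq_len(d), , drop = FALSE]
  davg <- matrix(dS[1, , ], d, B)
  dmx <- matrix(dS[2, , ], d, B)
  dF <- dF + aperm(expand_rows(davg / C, C), c(2, 1, 3))
  dFp <- maxpool_bwd(array(dmx, dim = c(d, 1, B)), cc$mx)
  dF <- dF + aperm(dFp, c(2, 1, 3))
  list(dF = dF, g = list(Wsp = cb$dW, bsp = cb$db))
}

efem_fwd <- function(x, ep, est, cfg, training) {
  e <- cfg$efem
  cc <- list()
  cc$small <- branch_fwd(x, ep$small, est$small, e$small, e$d_out,
                         e$leaky_slope, e$dropout, training)
  cc$large <- branch_fwd(x, ep$large, est$large, e$large, e$d_out,
                         e$leaky_slope, e$dropout, training)
  F <- array(0, dim = c(2 * e$f3, e$d_out, dim(x)[3]))
  F[seq_len(e$f3), , ] <- cc$small$y
  F[e$f3 + seq_len(e$f3), , ] <- cc$large$y
  cc$ch <- cbam_channel_fwd(F, ep$cbam)
  cc$sp <- cbam_spatial_fwd(cc$ch$y, ep$cbam, e$cbam_spatial_kernel)
  cc$y <- cc$sp$y
  cc
}

efem_bwd <- function(dy, cc, f3) {
  sp <- cbam_spatial_bwd(dy, cc$sp)
  ch <- cbam_channel_bwd(sp$dF, cc$ch)
  dF <- ch$dF
  g <- list(
    small = branch_bwd(dF[seq_len(f3), , , drop = FALSE], cc$small),
    large = branch_bwd(dF[f3 + seq_len(f3), , , drop = FALSE], cc$large),
    cbam = list(W1 = ch$g$W1, b1 = ch$g$b1, W2 = ch$g$W2, b2 = ch$g$b2,
                Wsp = sp$g$Wsp, bsp = sp$g$bsp))
  g
}

# updated running statistics after a training-mode forward
branch_state_update <- function(cc) {
  list(bn1 = list(mean = cc$b1$run_mean, var = cc$b1$run_var),
       bn2 = list(mean = cc$b2$run_mean, var = cc$b2$run_var),
       bn3 = list(mean = cc$b3$run_mean, var = cc$b3$run_var))
}

## ---- exit heads ------------------------------------------------------------

se_fwd <- function(F, w) {
  # F: (L, C, d, B)
  dm <- dim(F); L <- dm[1]; B <- dm[4]
  n_pos <- dm[2] * dm[3]
  cc <- list(F = F, dm = dm)
  M <- matrix(F, nrow = L)
  cc$c1 <- dense_fwd(M, w$c1$W, w$c1$b)
  cc$r1 <- relu_fwd(cc$c1$y)
  cc$c2 <- dense_fwd(cc$r1$y, w$c2$W, w$c2$b)     # F' (L, C*d*B)
  Fp3 <- array(cc$c2$y, dim = c(L, n_pos, B))
  cc$z <- colSums(aperm(Fp3, c(2, 1, 3))) / n_pos
  if (L == 1) cc$z <- matrix(cc$z, 1, B)
  op_count(L * n_pos * B)
  cc$g1 <- dense_fwd(cc$z, w$g1$W, w$g1$b)
  cc$rg <- relu_fwd(cc$g1$y)
  cc$g2 <- dense_fwd(cc$rg$y, w$g2$W, w$g2$b)
  cc$Mse <- sigmoid_fwd(cc$g2$y)                  # (L, B)
  gate <- cc$Mse[, rep(seq_len(B), each = n_pos), drop = FALSE]
  cc$gate <- gate
  op_count(2 * L * n_pos * B)
  cc$y <- array(M + gate * cc$c2$y, dim = dm)     # F + Mse (x) F'
  cc
}

se_bwd <- function(dy, cc) {
  dm <- cc$dm; L <- dm[1]; B <- dm[4]
  n_pos <- dm[2] * dm[3]
  dM <- matrix(dy, nrow = L)
  dFp <- dM * cc$gate
  dgate_full <- dM * cc$c2$y
  idx <- rep(seq_len(B), each = n_pos)
  dMse <- colSums(aperm(array(dgate_full, dim = c(L, n_pos, B)),
                        c(2, 1, 3)))
  if (L == 1) dMse <- matrix(dMse, 1, B)
  dg2 <- sigmoid_bwd(dMse, cc$Mse)
  b2 <- dense_bwd(dg2, cc$g2)
  b1 <- dense_bwd(b2$dx * cc$rg$mask, cc$g1)
  dz <- b1$dx
  dFp <- dFp + (dz / n_pos)[, idx, drop = FALSE]
  c2 <- dense_bwd(dFp, cc$c2)
  c1 <- dense_bwd(c2$dx * cc$r1$mask, cc$c1)
  dF <- array(dM + c1$dx, dim = dm)
  list(dF = dF,
       g = list(c1 = list(W = c1$dW, b = c1$db),
                c2 = list(W = c2$dW, b = c2$db),
                g1 = list(W = b1$dW, b = b1$db),
                g2 = list(W = b2$dW, b = b2$db)))
}

mhsa_fwd <- function(X, w, H) {
  # X: (d, T, B) feature-major tokens
  d <- dim(X)[1]; Tn <- dim(X)[2]; B <- dim(X)[3]
  dh <- d %/% H
  scl <- 1 / sqrt(dh)
  Xm <- matrix(X, nrow = d)
  op_count(3 * 2 * d * d * Tn * B)
  Q <- array(w$Wq %*% Xm, dim = dim(X))
  K <- array(w$Wk %*% Xm, dim = dim(X))
  V <- array(w$Wv %*% Xm, dim = dim(X))
  O <- array(0, dim = dim(X))
  A <- vector("list", B)
  op_count(B * H * (2 * Tn * Tn * dh * 2 + 6 * Tn * Tn))
  for (b in seq_len(B)) {
    Ab <- vector("list", H)
    for (i in seq_len(H)) {
      rows <- (i - 1) * dh + seq_len(dh)
      S <- crossprod(matrix(Q[rows, , b], nrow = dh),
                     matrix(K[rows, , b], nrow = dh)) * scl
      Sm <- S - apply(S, 1, max)
      E <- exp(Sm)
      Ai <- E / rowSums(E)
      O[rows, , b] <- matrix(V[rows, , b], nrow = dh) %*% t(Ai)
      Ab[[i]] <- Ai
    }
    A[[b]] <- Ab
  }
  list(y = O, X = X, Q = Q, K = K, V = V, A = A, w = w, H = H, dh = dh,
       scl = scl)
}

mhsa_bwd <- function(dy, cc) {
  d <- dim(cc$X)[1]; Tn <- dim(cc$X)[2]; B <- dim(cc$X)[3]
  H <- cc$H; dh <- cc$dh
  dQ <- array(0, dim = dim(cc$X))
  dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    for (i in seq_len(H)) {
      rows <- (i - 1) * dh + seq_len(dh)
      Ai <- cc$A[[b]][[i]]
      dOh <- matrix(dy[rows, , b], nrow = dh)
      Vh <- matrix(cc$V[rows, , b], nrow = dh)
      dV[rows, , b] <- dOh %*% Ai
      dA <- crossprod(dOh, Vh)
      dS <- (dA - rowSums(dA * Ai)) * Ai * cc$scl
      dQ[rows, , b] <- matrix(cc$K[rows, , b], nrow = dh) %*% t(dS)
      dK[rows, , b] <- matrix(cc$Q[rows, , b], nrow = dh) %*% dS
    }
  }
  Xm <- matrix(cc$X, nrow = d)
  dQm <- matrix(dQ, nrow = d); dKm <- matrix(dK, nrow = d)
  dVm <- matrix(dV, nrow = d)
  dX <- crossprod(cc$w$Wq, dQm) + crossprod(cc$w$Wk, dKm) +
    crossprod(cc$w$Wv, dVm)
  list(dX = array(dX, dim = dim(cc$X)),
       g = list(Wq = tcrossprod(dQm, Xm), Wk = tcrossprod(dKm, Xm),
                Wv = tcrossprod(dVm, Xm)))
}

encoder_fwd <- function(X, w, H, slope, wiring) {
  cc <- list(X = X, wiring = wiring)
  cc$mhsa <- mhsa_fwd(X, w, H)
  op_count(length(X))
  cc$ln1 <- ln_fwd(cc$mhsa$y + X, w$ln1$gamma, w$ln1$beta)
  IO1 <- cc$ln1$y
  dm <- dim(IO1)
  M <- matrix(IO1, nrow = dm[1])
  cc$f1 <- dense_fwd(M, w$ff1$W, w$ff1$b)
  cc$fr <- relu_fwd(cc$f1$y)
  cc$f2 <- dense_fwd(cc$fr$y, w$ff2$W, w$ff2$b)
  op_count(length(X))
  IO2 <- array(cc$f2$y + M, dim = dm)
  pre <- if (wiring == "x") IO2 + X else IO2
  cc$ln2 <- ln_fwd(pre, w$ln2$gamma, w$ln2$beta)
  cc$y <- cc$ln2$y
  cc
}

encoder_bwd <- function(dy, cc) {
  l2 <- ln_bwd(dy, cc$ln2)
  dIO2 <- l2$dx
  dX_extra <- if (cc$wiring == "x") dIO2 else 0
  dm <- dim(dIO2)
  dM <- matrix(dIO2, nrow = dm[1])
  f2 <- dense_bwd(dM, cc$f2)
  f1 <- dense_bwd(f2$dx * cc$fr$mask, cc$f1)
  dIO1 <- array(f1$dx + dM, dim = dm)
  l1 <- ln_bwd(dIO1, cc$ln1)
  mh <- mhsa_bwd(l1$dx, cc$mhsa)
  dX <- mh$dX + l1$dx + dX_extra
  list(dX = dX,
       g = list(Wq = mh$g$Wq, Wk = mh$g$Wk, Wv = mh$g$Wv,
                ln1 = list(gamma = l1$dgamma, beta = l1$dbeta),
                ff1 = list(W = f1$dW, b = f1$db),
                ff2 = list(W = f2$dW, b = f2$db),
                ln2 = list(gamma = l2$dgamma, beta = l2$dbeta)))
}

head_fwd <- function(stack, hp, cfg) {
  # stack: (L, C, d, B)
  dm <- dim(stack); L <- dm[1]; C <- dm[2]; d <- dm[3]; B <- dm[4]
  cc <- list(dm = dm)
  cc$se <- se_fwd(stack, hp$se)
  # (L, C, d, B) -> tokens (d, L*C, B)
  X <- aperm(cc$se$y, c(3, 1, 2, 4))
  dim(X) <- c(d, L * C, B)
  cc$enc <- encoder_fwd(X, hp$enc, cfg$head$H, cfg$efem$leaky_slope,
                        cfg$head$post_ln_residual)
  flat <- matrix(cc$enc$y, nrow = d * L * C)
  cc$l1 <- dense_fwd(flat, hp$cls$l1$W, hp$cls$l1$b)
  cc$a1 <- leaky_relu_fwd(cc$l1$y, cfg$efem$leaky_slope)
  cc$l2 <- dense_fwd(cc$a1$y, hp$cls$l2$W, hp$cls$l2$b)
  cc$probs <- softmax_cols(cc$l2$y)
  cc
}

head_bwd <- function(dlogits, cc) {
  dm <- cc$dm; L <- dm[1]; C <- dm[2]; d <- dm[3]; B <- dm[4]
  l2 <- dense_bwd(dlogits, cc$l2)
  l1 <- dense_bwd(leaky_relu_bwd(l2$dx, cc$a1), cc$l1)
  denc <- array(l1$dx, dim = c(d, L * C, B))
  eb <- encoder_bwd(denc, cc$enc)
  dX <- eb$dX
  dim(dX) <- c(d, L, C, B)
  dse <- aperm(dX, c(2, 3, 1, 4))
  sb <- se_bwd(dse, cc$se)
  list(dstack = sb$dF,
       g = list(se = sb$g,
                enc = eb$g,
                cls = list(l1 = list(W = l1$dW, b = l1$db),
                           l2 = list(W = l2$dW, b = l2$db))))
}

## ---- full model forward ----------------------------------------------------

# z-score each epoch per channel
normalize_batch <- function(x) {
  # x: (1, L, B)
  m <- matrix(x, nrow = dim(x)[2])
  m <- sweep(m, 2, colMeans(m), "-")
  sdv <- sqrt(colMeans(m^2)) + 1e-8
  array(sweep(m, 2, sdv, "/"), dim = dim(x))
}

# assemble the (1, L, B) input array of one modality from an EpochSet
modality_batch <- function(es, m, idx, normalize) {
  M <- assay(es, m)[, idx, drop = FALSE]
  x <- array(M, dim = c(1, nrow(M), length(idx)))
  if (normalize) x <- normalize_batch(x)
  x
}

# run EFEMs for the first `depth` modalities; returns features + caches
features_fwd <- function(params, state, cfg, xs, depth, training) {
  feats <- vector("list", depth)
  caches <- vector("list", depth)
  for (j in seq_len(depth)) {
    m <- cfg$modalities[j]
    cc <- efem_fwd(xs[[j]], params$efem[[m]], state$efem[[m]], cfg, training)
    feats[[j]] <- cc$y
    caches[[j]] <- cc
  }
  list(feats = feats, caches = caches)
}

stack_features <- function(feats) {
  L <- length(feats)
  dm <- dim(feats[[1]])
  st <- array(0, dim = c(L, dm[1], dm[2], dm[3]))
  for (j in seq_len(L)) st[j, , , ] <- feats[[j]]
  st
}

#' Exit-head forward pass on stacked features
#'
#' Runs one exit head (squeeze-and-excitation modality gate, transformer
#' encoder block, two linear layers, softmax) on an L x C x d stack of
#' per-modality feature maps.  Primarily a building block, exported so the
#' head can be exercised and tested in isolation.
#'
#' @param stack Array of dim (L, C, d) or (L, C, d, B).
#' @param head_params Parameter list of one head (see [sleepNet()]).
#' @param config Model configuration.
#' @return Matrix of class probabilities (n_classes x B), columns summing
#'   to 1.
#' @export
predictProbs <- function(stack, head_params, config) {
  if (length(dim(stack)) == 3) dim(stack) <- c(dim(stack), 1)
  head_fwd(stack, head_params, config)$probs
}
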