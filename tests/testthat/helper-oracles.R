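# Independent scalar-loop oracles used to check the vectorized
# implementations.  These are deliberately naive re-derivations from the
# definitions, not calls into the package internals.

# channel attention: sigmoid(MLP(avgpool) + MLP(maxpool)), shared 2-layer MLP
oracle_channel_attention <- function(F, W1, b1, W2, b2) {
  C <- nrow(F)
  out <- numeric(C)
  mlp <- function(v) {
    h <- numeric(length(b1))
    for (i in seq_along(b1)) h[i] <- max(sum(W1[i, ] * v) + b1[i], 0)
    o <- numeric(length(b2))
    for (i in seq_along(b2)) o[i] <- sum(W2[i, ] * h) + b2[i]
    o
  }
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) { avg[c] <- mean(F[c, ]); mx[c] <- max(F[c, ]) }
  z <- mlp(avg) + mlp(mx)
  for (c in seq_len(C)) out[c] <- 1 / (1 + exp(-z[c]))
  out
}

# spatial attention: sigmoid(conv_k([avgpool; maxpool])), same padding
oracle_spatial_attention <- function(F, W, b, kernel = 7) {
  d <- ncol(F)
  avg <- numeric(d); mx <- numeric(d)
  for (j in seq_len(d)) { avg[j] <- mean(F[, j]); mx[j] <- max(F[, j]) }
  pad <- (kernel - 1) %/% 2
  S <- rbind(c(rep(0, pad), avg, rep(0, pad)),
             c(rep(0, pad), mx, rep(0, pad)))
  out <- numeric(d)
  for (j in seq_len(d)) {
    acc <- b
    for (t in seq_len(kernel))
      for (ch in 1:2)
        acc <- acc + W[(t - 1) * 2 + ch] * S[ch, j + t - 1]
    out[j] <- 1 / (1 + exp(-acc))
  }
  out
}

# full CBAM: channel attention, rescale, spatial attention, rescale
oracle_cbam <- function(F, W1, b1, W2, b2, Wsp, bsp, kernel = 7) {
  Mc <- oracle_channel_attention(F, W1, b1, W2, b2)
  Fp <- F
  for (c in seq_len(nrow(F))) Fp[c, ] <- F[c, ] * Mc[c]
  Ms <- oracle_spatial_attention(Fp, Wsp, bsp, kernel)
  Fpp <- Fp
  for (j in seq_len(ncol(F))) Fpp[, j] <- Fp[, j] * Ms[j]
  Fpp
}

# multi-head self-attention by explicit double loops (tokens are rows of X)
oracle_mhsa <- function(X, Wq, Wk, Wv, H) {
  Tn <- nrow(X); d <- ncol(X); dh <- d / H
  out <- matrix(0, Tn, d)
  for (h in seq_len(H)) {
    cols <- (h - 1) * dh + seq_len(dh)
    Q <- X %*% Wq[, cols, drop = FALSE]
    K <- X %*% Wk[, cols, drop = FALSE]
    V <- X %*% Wv[, cols, drop = FALSE]
    for (i in seq_len(Tn)) {
      s <- numeric(Tn)
      for (j in seq_len(Tn)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dh)
      a <- exp(s - max(s)); a <- a / sum(a)
      for (cidx in seq_len(dh)) out[i, cols[cidx]] <- sum(a * V[, cidx])
    }
  }
  out
}

# metrics recomputed per class with explicit loops
oracle_metrics <- function(ct) {
  K <- nrow(ct); n <- sum(ct)
  acc <- 0
  for (t in seq_len(K)) acc <- acc + ct[t, t]
  acc <- acc / n
  f1s <- numeric(K)
  for (t in seq_len(K)) {
    tp <- ct[t, t]
    fp <- sum(ct[, t]) - tp
    fn <- sum(ct[t, ]) - tp
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[t] <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
  }
  pe <- 0
  for (t in seq_len(K)) pe <- pe + sum(ct[t, ]) * sum(ct[, t])
  pe <- pe / n^2
  list(acc = acc, mf1 = mean(f1s),
       kappa = if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe))
}

# largest-remainder apportionment, re-derived independently
oracle_apportion <- function(n, p) {
  q <- n * p
  base <- floor(q)
  r <- q - base
  need <- n - sum(base)
  ord <- order(r, decreasing = TRUE)
  for (i in seq_len(need)) base[ord[i]] <- base[ord[i]] + 1
  as.integer(base)
}

# depth-one decision stump accuracy for a binary split on one feature
stump_accuracy <- function(x, y) {
  # y logical; best threshold and orientation on feature x
  ths <- sort(unique(x))
  best <- 0
  for (th in ths) {
    acc1 <- mean((x >= th) == y)
    best <- max(best, acc1, 1 - acc1)
  }
  best
}

# EEG delta-band power of every epoch in an EpochSet
delta_power <- function(es) {
  vapply(seq_len(ncol(es)), function(i) {
    x <- SummarizedExperiment::assay(es, "eeg")[, i]
    bandPower(x, sampleRate(es), 0.5, 4)
  }, numeric(1))
}

tiny_config <- function(...) {
  sleepNetConfig(f1 = 4, f2 = 4, f3 = 2, hidden = 8, ff = 4, H = 2,
                 cbam_r = 2, dropout = 0, ...)
}
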