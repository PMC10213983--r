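# Entropy-gated early-exit inference controlled by a single Speed threshold.

#' Normalized entropy of a class distribution
#'
#' Shannon entropy divided by its maximum `log(N)`:
#' `sum(p * log(p)) / log(1/N)`, with `0 * log 0 = 0`.  Equals 1 for the
#' uniform distribution, 0 for a one-hot distribution, and is invariant to
#' the logarithm base.
#'
#' @param p Nonnegative vector summing to 1.
#' @return Scalar in `[0, 1]`.
#' @examples
#' normalizedEntropy(rep(0.2, 5))        # 1
#' normalizedEntropy(c(1, 0, 0, 0, 0))   # 0
#' @export
normalizedEntropy <- function(p) {
  if (any(!is.finite(p)) || any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("input is not a probability distribution")
  p <- pmax(p, 0)
  nz <- p > 0
  sum(p[nz] * log(p[nz])) / log(1 / length(p))
}

norm_entropy_cols <- function(P) {
  # column-wise normalized entropy of a (K, B) probability matrix
  lp <- ifelse(P > 0, log(pmax(P, 1e-300)), 0)
  colSums(P * lp) / log(1 / nrow(P))
}

#' Early-exit halting decision
#'
#' A sample halts at the current exit iff its uncertainty is strictly lower
#' than the Speed threshold.  Speed 0 therefore never halts (all samples are
#' classified by the final exit) and any Speed above 1 always halts at the
#' first exit.
#'
#' @param uncertainty Normalized entropy in `[0, 1]` (vectorized).
#' @param speed Nonnegative Speed threshold.
#' @return Logical: `TRUE` = halt (emit prediction), `FALSE` = continue.
#' @export
decideExit <- function(uncertainty, speed) {
  stopifnot(speed >= 0)
  uncertainty < speed
}

# eval-mode probabilities of exit L for column indices idx, given
# precomputed features of the first L modalities
.exit_probs <- function(model, feats, L) {
  head_fwd(stack_features(feats[seq_len(L)]),
           model@params$head[[L]], model@config)$probs
}

#' Per-exit probabilities for every epoch
#'
#' Runs all requested exits on every epoch (no gating) in evaluation mode.
#' Used by threshold sweeps and calibration analyses.
#'
#' @param model A trained [SleepNet-class].
#' @param data An [EpochSet-class].
#' @param batch_size Epochs per forward batch.
#' @return List of probability matrices `p1`, `p2`, `p3`
#'   (n_classes x n_epochs) and uncertainty vectors `u1`, `u2`, `u3`.
#' @export
exitProbabilities <- function(model, data, batch_size = 128) {
  cfg <- model@config
  n <- ncol(data)
  depth <- length(cfg$modalities)
  probs <- lapply(seq_len(depth), function(L)
    matrix(NA_real_, cfg$n_classes, n))
  for (idx in batch_indices(n, batch_size)) {
    xs <- lapply(cfg$modalities, function(m)
      modality_batch(data, m, idx, cfg$normalize))
    fw <- features_fwd(model@params, model@state, cfg, xs, depth,
                       training = FALSE)
    for (L in seq_len(depth))
      probs[[L]][, idx] <- .exit_probs(model, fw$feats, L)
  }
  out <- list()
  for (L in seq_len(depth)) {
    out[[paste0("p", L)]] <- probs[[L]]
    out[[paste0("u", L)]] <- norm_entropy_cols(probs[[L]])
  }
  out
}

#' Adaptive early-exit prediction
#'
#' Routes every epoch through the network depth-first: EEG features and the
#' EEG exit first; epochs whose uncertainty is below Speed halt there, the
#' rest continue through the EOG features and exit, and finally the full
#' (ungated) final exit.  Computation for halted epochs is actually skipped:
#' deeper feature extractors and heads only see the still-active sub-batch.
#'
#' @param model A trained [SleepNet-class] (stage 2 for meaningful routing).
#' @param data An [EpochSet-class].
#' @param speed Nonnegative Speed threshold on normalized entropy.
#' @param batch_size Epochs per forward batch.
#' @return List with `predictions` (factor over the stage levels), `trace`
#'   (data frame: `exit`, `prediction`, `u1`, `u2`), `probs` (probability
#'   vector at the emitting exit, n_classes x n_epochs), and `exit_fractions`.
#' @export
adaptivePredict <- function(model, data, speed = 0, batch_size = 128) {
  stopifnot(speed >= 0)
  cfg <- model@config
  if (speed > 0 && model@trainedStage < 2L)
    warning("early exits are untrained; routing with speed > 0 is ",
            "uncalibrated")
  n <- ncol(data)
  depth <- length(cfg$modalities)
  exit_idx <- integer(n)
  pred <- integer(n)
  u_mat <- matrix(NA_real_, depth - 1, n)
  probs <- matrix(NA_real_, cfg$n_classes, n)

  for (idx in batch_indices(n, batch_size)) {
    active <- idx
    feats <- vector("list", depth)   # features of still-active samples
    for (L in seq_len(depth)) {
      m <- cfg$modalities[L]
      x <- modality_batch(data, m, active, cfg$normalize)
      cc <- efem_fwd(x, model@params$efem[[m]], model@state$efem[[m]],
                     cfg, training = FALSE)
      feats[[L]] <- cc$y
      # with speed 0 the gate can never fire: early heads are not evaluated
      if (L < depth && speed == 0) next
      p <- .exit_probs(model, feats, L)
      if (L < depth) {
        u <- norm_entropy_cols(p)
        u_mat[L, active] <- u
        halt <- decideExit(u, speed)
      } else {
        halt <- rep(TRUE, length(active))
      }
      if (any(halt)) {
        h <- active[halt]
        exit_idx[h] <- L
        pred[h] <- max.col(t(p[, halt, drop = FALSE]))
        probs[, h] <- p[, halt, drop = FALSE]
      }
      active <- active[!halt]
      if (length(active) == 0) break
      for (j in seq_len(L)) feats[[j]] <- feats[[j]][, , !halt, drop = FALSE]
    }
  }
  fractions <- vapply(seq_len(depth), function(L) mean(exit_idx == L),
                      numeric(1))
  names(fractions) <- paste0("exit", seq_len(depth))
  list(predictions = factor(SLEEP_STAGES[pred], levels = SLEEP_STAGES),
       trace = data.frame(exit = exit_idx,
                          prediction = SLEEP_STAGES[pred],
                          u1 = u_mat[1, ],
                          u2 = if (depth >= 3) u_mat[2, ] else NA_real_),
       probs = probs,
       exit_fractions = fractions)
}

#' Accuracy / routing / cost sweep over Speed values
#'
#' Evaluates every exit once on every epoch, then derives, for each Speed,
#' the routing fractions, total accuracy, and the routing-weighted expected
#' cost from the static per-exit path costs (each sample is charged the
#' feature extractors it traversed plus the head that emitted it).
#'
#' @param model A trained [SleepNet-class].
#' @param data A labeled [EpochSet-class].
#' @param speeds Numeric vector of Speed thresholds (nonempty).
#' @param flops A [countFlops()] report for the model's configuration
#'   (recomputed if omitted).
#' @param batch_size Epochs per forward batch.
#' @return Data frame with one row per Speed: `speed`, `accuracy`,
#'   `frac_exit1..3`, `expected_gflops`.
#' @export
speedSweep <- function(model, data, speeds, flops = NULL, batch_size = 128) {
  if (length(speeds) == 0) stop("empty speed list")
  if (is.null(flops)) flops <- countFlops(model@config, batch_size = 1)
  ep <- exitProbabilities(model, data, batch_size)
  labels <- as.integer(stages(data))
  depth <- length(model@config$modalities)
  preds <- lapply(seq_len(depth), function(L) max.col(t(ep[[paste0("p", L)]])))
  out <- lapply(speeds, function(s) {
    exit_idx <- rep(depth, length(labels))
    if (s > 0) {
      exit_idx[ep$u2 < s] <- 2L
      exit_idx[ep$u1 < s] <- 1L
    }
    pred <- preds[[depth]]
    for (L in seq_len(depth - 1)) pred[exit_idx == L] <- preds[[L]][exit_idx == L]
    fr <- vapply(seq_len(depth), function(L) mean(exit_idx == L), numeric(1))
    data.frame(speed = s,
               accuracy = mean(pred == labels),
               frac_exit1 = fr[1], frac_exit2 = fr[2], frac_exit3 = fr[3],
               expected_gflops = expectedFlops(flops, fr))
  })
  do.call(rbind, out)
}
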