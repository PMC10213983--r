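# User-facing single-sample views of the feature-extractor operations.
# The training/inference paths use the batched internals; these wrappers
# expose the same computations on plain C x d matrices so each algebraic
# step can be exercised directly.

#' Channel attention map
#'
#' Squeezes a C x d feature map by global average- and max-pooling over
#' positions, passes both C-vectors through one shared two-layer perceptron
#' (bottleneck C/r), sums and applies the logistic function.  Every weight is
#' strictly inside (0, 1).
#'
#' @param F Numeric matrix (C x d).
#' @param mlp_weights List with `W1` (C/r x C), `b1`, `W2` (C x C/r), `b2`.
#' @return C x 1 matrix of attention weights in (0, 1).
#' @export
channelAttention <- function(F, mlp_weights) {
  stopifnot(is.matrix(F), all(is.finite(F)))
  w <- mlp_weights
  mlp <- function(v) w$W2 %*% pmax(w$W1 %*% v + w$b1, 0) + w$b2
  avg <- matrix(rowMeans(F), ncol = 1)
  mx <- matrix(apply(F, 1, max), ncol = 1)
  matrix(1 / (1 + exp(-(mlp(avg) + mlp(mx)))), ncol = 1)
}

#' Rescale feature channels by a channel attention map
#'
#' @param F Numeric matrix (C x d).
#' @param Mc C x 1 channel weights.
#' @return Matrix of the same dimensions as `F`, row i scaled by `Mc[i]`.
#' @export
applyChannelAttention <- function(F, Mc) {
  if (nrow(F) != length(Mc))
    stop("channel attention has ", length(Mc), " weights for ", nrow(F),
         " channels")
  F * as.vector(Mc)
}

#' Spatial attention map
#'
#' Squeezes a C x d map by channel-wise mean and max into two 1 x d profiles,
#' stacks them and convolves with a single width-`kernel` filter under same
#' padding, then applies the logistic function.
#'
#' @param F Numeric matrix (C x d), typically channel-recalibrated.
#' @param conv_weights List with `W` (1 x 2*kernel) and `b` (length 1).
#' @param kernel Filter width (odd; default 7).
#' @return 1 x d matrix of weights in (0, 1).
#' @export
spatialAttention <- function(F, conv_weights, kernel = 7) {
  stopifnot(is.matrix(F))
  d <- ncol(F)
  S <- rbind(colMeans(F), apply(F, 2, max))
  pad <- (kernel - 1) %/% 2
  Sp <- cbind(matrix(0, 2, pad), S, matrix(0, 2, pad))
  x <- array(Sp, dim = c(2, d + 2 * pad, 1))
  y <- conv1d_fwd(x, conv_weights$W, conv_weights$b, 1L, need_dx = FALSE)$y
  matrix(1 / (1 + exp(-as.vector(y))), nrow = 1)
}

#' Rescale feature positions by a spatial attention map
#'
#' @param F Numeric matrix (C x d).
#' @param Ms 1 x d spatial weights.
#' @return Matrix of the same dimensions as `F`, column j scaled by `Ms[j]`.
#' @export
applySpatialAttention <- function(F, Ms) {
  if (ncol(F) != length(Ms))
    stop("spatial attention has ", length(Ms), " weights for ", ncol(F),
         " positions")
  sweep(F, 2, as.vector(Ms), "*")
}

single_waveform_array <- function(signal) {
  array(as.numeric(signal), dim = c(1, length(signal), 1))
}

check_branch_lengths <- function(signal, cfg) {
  for (nm in c("small", "large")) {
    k <- cfg$efem[[nm]]$k[1]
    if (length(signal) < k)
      stop(sprintf("signal of length %d is shorter than the %s-branch kernel (%d)",
                   length(signal), nm, k))
  }
}

#' Multi-scale convolutional features of one waveform
#'
#' Runs both convolutional branches of a modality's feature extractor (small
#' kernels for fast rhythms, large kernels for slow waves), aligns the two
#' outputs to the common feature length by max-pooling and concatenates them
#' along the channel axis — the feature map before attention.
#'
#' @param signal Numeric waveform (one epoch of one modality).
#' @param model A [SleepNet-class].
#' @param modality Which modality's extractor weights to use.
#' @return Numeric matrix (C x d_out) with C = 2 * f3.
#' @export
multiScaleConv <- function(signal, model, modality = "eeg") {
  cfg <- model@config
  check_branch_lengths(signal, cfg)
  x <- single_waveform_array(signal)
  ep <- model@params$efem[[modality]]
  est <- model@state$efem[[modality]]
  e <- cfg$efem
  s <- branch_fwd(x, ep$small, est$small, e$small, e$d_out, e$leaky_slope,
                  e$dropout, training = FALSE)
  l <- branch_fwd(x, ep$large, est$large, e$large, e$d_out, e$leaky_slope,
                  e$dropout, training = FALSE)
  rbind(matrix(s$y, dim(s$y)[1]), matrix(l$y, dim(l$y)[1]))
}

#' Full feature-extractor forward pass for one waveform
#'
#' [multiScaleConv()] followed by channel attention then spatial attention
#' (in that order).  The output shape is fixed by the configuration,
#' independent of the input values.
#'
#' @inheritParams multiScaleConv
#' @return Numeric matrix (C x d_out).
#' @export
efemForward <- function(signal, model, modality = "eeg") {
  cfg <- model@config
  check_branch_lengths(signal, cfg)
  x <- single_waveform_array(signal)
  cc <- efem_fwd(x, model@params$efem[[modality]],
                 model@state$efem[[modality]], cfg, training = FALSE)
  matrix(cc$y, dim(cc$y)[1])
}
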