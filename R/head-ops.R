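# User-facing single-sample views of the exit-head operations.

#' Squeeze-and-excitation modality recalibration
#'
#' Two shape-preserving 1x1 convolutions over the modality axis produce F';
#' global average pooling over the C x d grid gives one scalar per modality,
#' which two further 1x1 convolutions and a logistic squash turn into the
#' modality gate; the output is the residual sum `F + gate * F'`, with the
#' input's exact L x C x d shape.  With L = 1 the gate degenerates to a
#' single scalar.
#'
#' @param F Array of dim (L, C, d).
#' @param weights List with dense 1x1-conv weights `c1`, `c2` (recalibration)
#'   and `g1`, `g2` (gate), each a list of `W` (L x L) and `b` (length L).
#' @return Array of the same dimensions as `F`.
#' @export
seRecalibrate <- function(F, weights) {
  stopifnot(length(dim(F)) == 3)
  F4 <- array(F, dim = c(dim(F), 1))
  se_fwd(F4, weights)$y[, , , 1, drop = TRUE] |>
    array(dim = dim(F))
}

#' Multi-head self-attention over a token grid
#'
#' Tokens are rows of `X`; each of `H` heads projects queries, keys and
#' values to width `d/H`, scores token pairs by scaled dot product
#' (divisor `sqrt(d/H)`), row-softmaxes, and averages values; head outputs
#' are concatenated back to width d.
#'
#' @param X Token matrix (T x d).
#' @param weights List with projection matrices `Wq`, `Wk`, `Wv`, each d x d
#'   (queries are `X %*% Wq`).
#' @param H Head count; must divide d.
#' @return T x d matrix.
#' @export
multiHeadSelfAttention <- function(X, weights, H = 1) {
  stopifnot(is.matrix(X))
  d <- ncol(X)
  if (d %% H != 0)
    stop("token width ", d, " is not divisible by head count ", H)
  w <- list(Wq = t(weights$Wq), Wk = t(weights$Wk), Wv = t(weights$Wv))
  Xi <- array(t(X), dim = c(d, nrow(X), 1))
  t(matrix(mhsa_fwd(Xi, w, H)$y, nrow = d))
}

#' Transformer encoder block
#'
#' Residual + layer norm around multi-head self-attention, a position-wise
#' two-layer feed-forward with residual, and a closing layer norm whose
#' residual connects back to the block input (`wiring = "x"`, the default)
#' or only to the feed-forward output (`wiring = "io2"`).
#'
#' @param X Token matrix (T x d).
#' @param weights List with `Wq`, `Wk`, `Wv` (d x d, token-major as in
#'   [multiHeadSelfAttention()]), `ln1`/`ln2` (lists of `gamma`, `beta`,
#'   length d) and `ff1`/`ff2` (lists of `W`, `b`).
#' @param H Head count.
#' @param wiring `"x"` or `"io2"` (see [sleepNetConfig()]).
#' @return T x d matrix, same shape as the input.
#' @export
encoderBlock <- function(X, weights, H = 1, wiring = c("x", "io2")) {
  wiring <- match.arg(wiring)
  d <- ncol(X)
  w <- weights
  w$Wq <- t(weights$Wq); w$Wk <- t(weights$Wk); w$Wv <- t(weights$Wv)
  Xi <- array(t(X), dim = c(d, nrow(X), 1))
  out <- encoder_fwd(Xi, w, H, 0.01, wiring)$y
  t(matrix(out, nrow = d))
}
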