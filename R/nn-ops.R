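# Low-level differentiable operations.
#
# All operations work on double-precision arrays and return both the output
# and a cache from which the backward pass reconstructs gradients.  Batched
# signals are stored channel-major as arrays of dim (C, L, B); token grids as
# (d, T, B) so that per-token reductions (layer norm) act on contiguous
# columns.  Every matmul-bearing op reports its realized cost to the op
# counter when counting is enabled (1 multiply-accumulate = 2 FLOPs).

.ops <- new.env(parent = emptyenv())
.ops$enabled <- FALSE
.ops$flops <- 0

op_count <- function(flops) {
  if (.ops$enabled) .ops$flops <- .ops$flops + flops
  invisible(NULL)
}

#' Count realized floating-point work of an expression
#'
#' Evaluates `expr` with the package's operation counter enabled and returns
#' the result together with the number of floating-point operations the
#' network primitives actually executed (1 multiply-accumulate counted as 2
#' FLOPs, elementwise ops as 1).  Used to cross-check the closed-form
#' [countFlops()] profiler against instrumented execution, and to verify that
#' early-exit routing really skips computation.
#'
#' @param expr An expression invoking package model code.
#' @return A list with elements `value` (the expression's value) and `flops`.
#' @export
withOpCount <- function(expr) {
  old_enabled <- .ops$enabled
  old_flops <- .ops$flops
  .ops$enabled <- TRUE
  .ops$flops <- 0
  on.exit({
    .ops$enabled <- old_enabled
    .ops$flops <- old_flops
  })
  val <- force(expr)
  list(value = val, flops = .ops$flops)
}

## ---- basic activations -----------------------------------------------------

sigmoid_fwd <- function(x) {
  op_count(4 * length(x))
  1 / (1 + exp(-x))
}

sigmoid_bwd <- function(dy, y) dy * y * (1 - y)

relu_fwd <- function(x) {
  op_count(length(x))
  list(y = pmax(x, 0), mask = x > 0)
}

leaky_relu_fwd <- function(x, slope) {
  op_count(length(x))
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg, slope = slope)
}

leaky_relu_bwd <- function(dy, cache) {
  d <- dy
  d[cache$neg] <- cache$slope * dy[cache$neg]
  d
}

softmax_cols <- function(z) {
  # column-wise softmax of a (K, B) matrix
  op_count(5 * length(z))
  zm <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(zm)
  sweep(e, 2, colSums(e), "/")
}

## ---- dense -----------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  # x: (n_in, B); W: (n_out, n_in); b: (n_out)
  op_count(2 * nrow(W) * ncol(W) * ncol(x))
  list(y = W %*% x + b, x = x, W = W)
}

dense_bwd <- function(dy, cache) {
  list(dx = crossprod(cache$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

## ---- 1-D convolution (valid padding) --------------------------------------

conv_out_len <- function(L, k, stride) {
  if (L < k) stop("input length ", L, " shorter than kernel ", k)
  as.integer((L - k) %/% stride + 1)
}

.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(Cin, Lin, k, stride, B) {
  key <- paste(Cin, Lin, k, stride, B, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Lout <- conv_out_len(Lin, k, stride)
  pos <- outer(seq_len(k), (seq_len(Lout) - 1L) * stride, "+")  # k x Lout
  idx0 <- rep((as.vector(pos) - 1L) * Cin, each = Cin) + seq_len(Cin)
  idx <- rep(idx0, times = B) +
    rep((seq_len(B) - 1L) * Cin * Lin, each = length(idx0))
  out <- list(idx = idx, Lout = Lout)
  if (length(.im2col_cache) > 64) rm(list = ls(.im2col_cache),
                                     envir = .im2col_cache)
  .im2col_cache[[key]] <- out
  out
}

conv1d_fwd <- function(x, W, b, stride, need_dx = TRUE) {
  # x: (Cin, Lin, B); W: (Cout, Cin*k); b: (Cout)
  d <- dim(x); Cin <- d[1]; Lin <- d[2]; B <- d[3]
  k <- ncol(W) / Cin
  ii <- im2col_idx(Cin, Lin, k, stride, B)
  P <- x[ii$idx]
  dim(P) <- c(Cin * k, ii$Lout * B)                   # (Cin*k, Lout*B)
  op_count(2 * nrow(W) * ncol(W) * ncol(P))
  y <- W %*% P + b
  list(y = array(y, dim = c(nrow(W), ii$Lout, B)),
       P = P, W = W, need_dx = need_dx, k = k, stride = stride,
       idx = if (need_dx && stride != 1) ii$idx else NULL,
       xdim = d, Lout = ii$Lout)
}

conv1d_bwd <- function(dy, cache) {
  Cout <- dim(dy)[1]
  dY <- dy
  dim(dY) <- c(Cout, length(dy) / Cout)
  out <- list(dW = tcrossprod(dY, cache$P), db = rowSums(dY), dx = NULL)
  if (cache$need_dx) {
    dP <- crossprod(cache$W, dY)        # (Cin*k, Lout*B)
    Cin <- cache$xdim[1]; Lin <- cache$xdim[2]; B <- cache$xdim[3]
    k <- cache$k; Lout <- cache$Lout
    if (cache$stride == 1) {
      # col2im by kernel offset: each offset j writes a contiguous span
      dP4 <- array(dP, dim = c(Cin, k, Lout, B))
      dx <- array(0, dim = cache$xdim)
      for (j in seq_len(k)) {
        span <- j:(j + Lout - 1)
        slice <- dP4[, j, , , drop = FALSE]
        dim(slice) <- c(Cin, Lout, B)
        dx[, span, ] <- dx[, span, , drop = FALSE] + slice
      }
      out$dx <- dx
    } else {
      acc <- rowsum(as.vector(dP), group = cache$idx)
      dx <- numeric(prod(cache$xdim))
      dx[as.integer(rownames(acc))] <- acc
      out$dx <- array(dx, dim = cache$xdim)
    }
  }
  out
}

## ---- batch normalization (per channel over positions x batch) --------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[1]
  xm <- x
  dim(xm) <- c(C, length(x) / C)
  n <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * n / max(1, n - 1)
  } else {
    mu <- run_mean
    v <- run_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * ivar
  op_count(4 * length(x))
  y <- gamma * xhat + beta
  list(y = array(y, dim = d), xhat = xhat, ivar = ivar, gamma = gamma,
       dim = d, run_mean = run_mean, run_var = run_var, training = training)
}

bn_bwd <- function(dy, cache) {
  C <- cache$dim[1]
  dym <- dy
  dim(dym) <- c(C, length(dy) / C)
  n <- ncol(dym)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    dxhat <- dym * cache$gamma
    dx <- (cache$ivar / n) *
      (n * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dym * cache$gamma * cache$ivar
  }
  list(dx = array(dx, dim = cache$dim), dgamma = dgamma, dbeta = dbeta)
}

## ---- max pooling (non-overlapping) -----------------------------------------

maxpool_fwd <- function(x, w, n_windows = NULL) {
  # window = stride = w; optionally keep only the first n_windows windows
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  Lout <- if (is.null(n_windows)) L %/% w else n_windows
  stopifnot(Lout >= 1, Lout * w <= L)
  starts <- (seq_len(Lout) - 1L) * w + 1L
  y <- x[, starts, , drop = FALSE]
  am <- array(rep(starts, each = C), dim = c(C, Lout, B))
  if (w > 1) {
    for (j in seq_len(w - 1)) {
      cand <- x[, starts + j, , drop = FALSE]
      upd <- cand > y
      y[upd] <- cand[upd]
      am[upd] <- array(rep(starts + j, each = C), dim = dim(am))[upd]
    }
  }
  op_count((w - 1) * C * Lout * B)
  list(y = y, argmax = am, xdim = d)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$xdim; C <- d[1]; L <- d[2]; B <- d[3]
  Lout <- dim(dy)[2]
  lin <- rep(seq_len(C), times = Lout * B) +
    (as.vector(cache$argmax) - 1L) * C +
    rep((seq_len(B) - 1L) * C * L, each = C * Lout)
  dx <- numeric(prod(d))
  dx[lin] <- as.vector(dy)   # windows are disjoint: positions unique
  array(dx, dim = d)
}

## ---- dropout ---------------------------------------------------------------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim = dim(x))
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

## ---- layer normalization (per token over the feature axis) -----------------

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  # x: (d, T, B); normalize each column vector of length d
  dm <- dim(x); dd <- dm[1]
  xm <- matrix(x, nrow = dd)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu, "-")
  v <- colMeans(xc^2)
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivar, "*")
  op_count(8 * length(x))
  y <- xhat * gamma + beta
  list(y = array(y, dim = dm), xhat = xhat, ivar = ivar, gamma = gamma,
       dim = dm)
}

ln_bwd <- function(dy, cache) {
  dd <- cache$dim[1]
  dym <- matrix(dy, nrow = dd)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * cache$gamma
  dx <- sweep(dd * dxhat -
                matrix(colSums(dxhat), dd, ncol(dym), byrow = TRUE) -
                cache$xhat *
                matrix(colSums(dxhat * cache$xhat), dd, ncol(dym), byrow = TRUE),
              2, cache$ivar / dd, "*")
  list(dx = array(dx, dim = cache$dim), dgamma = dgamma, dbeta = dbeta)
}

## ---- parameter-tree helpers ------------------------------------------------

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(p, q, f) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- param_map2(p[[i]], q[[i]], f)
    out
  } else {
    f(p, q)
  }
}

param_count <- function(p) {
  if (is.list(p)) sum(vapply(p, param_count, numeric(1))) else length(p)
}

param_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_flatten), use.names = FALSE)
  else as.vector(p)
}

param_unflatten <- function(template, v) {
  i <- 0
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    n <- length(p)
    out <- p
    out[] <- v[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  fill(template)
}
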