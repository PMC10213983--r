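# Closed-form cost profiling: exact parameter counts and per-layer FLOPs
# enumeration, mirroring operation for operation what the forward pass
# executes (so the analytic counter and the instrumented counter agree).
#
# Counting convention: one multiply-accumulate of a convolution, linear or
# attention matmul costs 2 FLOPs (bias additions not itemized); elementwise
# passes cost 1 per element except batch norm (4), layer norm (8), sigmoid
# (4) and softmax (5); max-pooling costs one comparison per discarded
# element.  MAC totals (matmul FLOPs / 2) are reported alongside.

#' Exact trainable parameter count
#'
#' Closed-form count over the sub-network reachable under the active exits:
#' per conv layer `k * C_in * C_out + C_out`, per linear layer
#' `n_in * n_out + n_out`, per normalization layer `2 * C`, attention
#' projections `3 * d^2`.  Feature extractors are counted for every modality
#' an active exit consumes.
#'
#' @param config A [sleepNetConfig()].
#' @param active_exits Integer subset of `1:3`; exits reachable at the
#'   operating point (all three by default).
#' @return Integer parameter count.
#' @examples
#' countParams(sleepNetConfig()) / 1e6   # millions of parameters
#' @export
countParams <- function(config, active_exits = seq_along(config$modalities)) {
  e <- config$efem
  d <- e$d_out; C <- 2 * e$f3; Ch <- C / e$cbam_r
  h <- config$head$hidden; ff <- config$head$ff
  branch <- function(b) {
    (b$k[1] * 1 * e$f1 + e$f1) + 2 * e$f1 +
      (b$k[2] * e$f1 * e$f2 + e$f2) + 2 * e$f2 +
      (b$k[3] * e$f2 * e$f3 + e$f3) + 2 * e$f3
  }
  efem <- branch(e$small) + branch(e$large) +
    (C * Ch + Ch) + (Ch * C + C) + (e$cbam_spatial_kernel * 2 + 1)
  head_p <- function(L) {
    Tn <- L * C
    4 * (L * L + L) +
      3 * d * d + 2 * (2 * d) + (d * ff + ff) + (ff * d + d) +
      (Tn * d * h + h) + (h * config$n_classes + config$n_classes)
  }
  n_efem <- max(active_exits)
  n_efem * efem + sum(vapply(active_exits, head_p, numeric(1)))
}

# per-EFEM FLOPs for a batch of B samples (mirrors efem_fwd)
.efem_flops <- function(cfg, B) {
  e <- cfg$efem
  sh <- efem_shapes(cfg)
  d <- e$d_out; C <- 2 * e$f3; Ch <- C / e$cbam_r
  branch <- function(b, L) {
    # L = c(L1, P1, L2, L3)
    w_align <- L[4] %/% d
    2 * e$f1 * b$k[1] * L[1] * B + 4 * e$f1 * L[1] * B + e$f1 * L[1] * B +
      (b$pool1 - 1) * e$f1 * L[2] * B +
      2 * e$f2 * (e$f1 * b$k[2]) * L[3] * B + 4 * e$f2 * L[3] * B +
      e$f2 * L[3] * B +
      2 * e$f3 * (e$f2 * b$k[3]) * L[4] * B + 4 * e$f3 * L[4] * B +
      e$f3 * L[4] * B +
      (w_align - 1) * e$f3 * d * B
  }
  cbam_ch <- C * d * B + (d - 1) * C * B +
    2 * (2 * Ch * C * B + Ch * B + 2 * C * Ch * B) +
    4 * C * B + C * d * B
  cbam_sp <- C * d * B + (C - 1) * d * B +
    2 * 1 * (2 * e$cbam_spatial_kernel) * d * B + 4 * d * B + C * d * B
  branch(e$small, sh$small) + branch(e$large, sh$large) + cbam_ch + cbam_sp
}

# per-head FLOPs for a batch of B samples (mirrors head_fwd)
.head_flops <- function(cfg, L, B) {
  e <- cfg$efem
  d <- e$d_out; C <- 2 * e$f3
  h <- cfg$head$hidden; ff <- cfg$head$ff
  H <- cfg$head$H; dh <- d %/% H
  Tn <- L * C
  np <- C * d
  se <- 2 * L * L * np * B + L * np * B + 2 * L * L * np * B +  # c1,relu,c2
    L * np * B +                                                 # avg pool
    2 * L * L * B + L * B + 2 * L * L * B + 4 * L * B +          # gate
    2 * L * np * B                                               # apply+add
  mhsa <- 3 * 2 * d * d * Tn * B + B * H * (2 * Tn * Tn * dh * 2 + 6 * Tn * Tn)
  enc <- mhsa + d * Tn * B + 8 * d * Tn * B +                    # add, ln1
    2 * ff * d * Tn * B + ff * Tn * B + 2 * d * ff * Tn * B +    # ff
    d * Tn * B + 8 * d * Tn * B                                  # add, ln2
  cls <- 2 * h * (Tn * d) * B + h * B +
    2 * cfg$n_classes * h * B + 5 * cfg$n_classes * B
  se + enc + cls
}

#' Closed-form FLOPs profile
#'
#' Enumerates the floating-point cost of every stage for a batch:
#' per-modality feature extractors, per-exit heads, and the cumulative path
#' cost of exiting at each depth (the feature extractors traversed plus the
#' emitting head).  With routing fixed to the final exit the early heads
#' perform no computation, so the final path cost excludes them.
#'
#' @param config A [sleepNetConfig()].
#' @param batch_size Samples in the profiled batch.
#' @return Object of class `"FlopsReport"`: lists `efem_flops` (per
#'   modality), `head_flops` and `path_flops`/`path_gflops` (per exit),
#'   `path_macs` (multiply-accumulate counts), `batch_size`.
#' @examples
#' countFlops(sleepNetConfig(), batch_size = 256)
#' @export
countFlops <- function(config, batch_size = 256) {
  depth <- length(config$modalities)
  ef <- rep(.efem_flops(config, batch_size), depth)
  names(ef) <- config$modalities
  hf <- vapply(seq_len(depth), .head_flops, numeric(1), cfg = config,
               B = batch_size)
  path <- cumsum(ef) + hf
  structure(list(batch_size = batch_size,
                 efem_flops = ef,
                 head_flops = hf,
                 path_flops = unname(path),
                 path_gflops = unname(path) / 1e9,
                 path_macs = unname(path) / 2,
                 config_channels = 2 * config$efem$f3),
            class = "FlopsReport")
}

#' @export
print.FlopsReport <- function(x, ...) {
  cat("FLOPs profile (batch of", x$batch_size, "samples)\n")
  cat("  per-modality feature extractor:",
      sprintf("%.3f G", x$efem_flops[1] / 1e9), "\n")
  for (k in seq_along(x$head_flops))
    cat(sprintf("  exit %d: head %.3f G, cumulative path %.3f G (%.0f MMACs)\n",
                k, x$head_flops[k] / 1e9, x$path_gflops[k],
                x$path_macs[k] / 1e6))
  invisible(x)
}

#' Routing-weighted expected cost
#'
#' Convex combination of the per-exit cumulative path costs under the
#' observed exit fractions, in giga-FLOPs.
#'
#' @param report A [countFlops()] report.
#' @param exit_fractions Nonnegative fractions summing to 1, one per exit.
#' @return Expected giga-FLOPs for the report's batch size.
#' @export
expectedFlops <- function(report, exit_fractions) {
  if (length(exit_fractions) != length(report$path_gflops))
    stop("need one fraction per exit")
  if (abs(sum(exit_fractions) - 1) > 1e-6)
    stop("exit fractions must sum to 1")
  sum(exit_fractions * report$path_gflops)
}
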