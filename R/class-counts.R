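#' Published stage counts of four public polysomnography datasets
#'
#' Per-stage epoch counts of the Sleep-EDF (expanded and 20-subject) and
#' ISRUC (subgroup 1 and 3) datasets after relabeling to the five AASM
#' classes and wake trimming, as printed in the source datasets' standard
#' preparation.  Used as the default class proportions of the synthetic
#' generator and by the class-fraction bookkeeping checks.
#'
#' @format Named list of five-element integer vectors (W, N1, N2, N3, REM).
#' @export
psgClassCounts <- list(
  "sleep-edf-78" = c(W = 65951L, N1 = 21522L, N2 = 69132L, N3 = 13039L,
                     REM = 25835L),
  "sleep-edf-20" = c(W = 8183L, N1 = 2909L, N2 = 17509L, N3 = 6006L,
                     REM = 7701L),
  "isruc-1" = c(W = 18237L, N1 = 11110L, N2 = 27232L, N3 = 18188L,
                REM = 12420L),
  "isruc-3" = c(W = 1647L, N1 = 1188L, N2 = 2660L, N3 = 1939L, REM = 1155L)
)

#' Class fractions from labels or counts
#'
#' @param x Either a vector of class labels or a named vector of counts.
#' @param percent Return percentages (default) rather than fractions.
#' @return Named numeric vector of per-class fractions.
#' @examples
#' classFractions(psgClassCounts[["sleep-edf-20"]])["N2"]  # 41.4 percent
#' @export
classFractions <- function(x, percent = TRUE) {
  counts <- if (is.numeric(x)) x else c(table(x))
  if (sum(counts) == 0) stop("no observations")
  f <- counts / sum(counts)
  if (percent) 100 * f else f
}
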