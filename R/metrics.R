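# Confusion-table metrics: overall accuracy, macro F1, Cohen's kappa.

#' Confusion table over the five sleep stages
#'
#' @param true,predicted Vectors of stage labels (factor, character, or
#'   integer indices into `levels`).
#' @param levels Class order (rows = true, columns = predicted).
#' @return K x K integer matrix of counts.
#' @export
confusionTable <- function(true, predicted, levels = SLEEP_STAGES) {
  as_idx <- function(x) {
    if (is.numeric(x)) as.integer(x)
    else as.integer(factor(as.character(x), levels = levels))
  }
  ti <- as_idx(true); pi <- as_idx(predicted)
  if (length(ti) != length(pi)) stop("length mismatch")
  if (anyNA(ti) || anyNA(pi)) stop("labels outside the class levels")
  K <- length(levels)
  ct <- matrix(0L, K, K, dimnames = list(true = levels, predicted = levels))
  for (i in seq_along(ti)) ct[ti[i], pi[i]] <- ct[ti[i], pi[i]] + 1L
  ct
}

check_ct <- function(ct) {
  if (!is.matrix(ct) || nrow(ct) != ncol(ct) || any(ct < 0))
    stop("not a confusion table")
  if (sum(ct) == 0) stop("empty confusion table")
}

#' Overall accuracy from a confusion table
#'
#' Trace over total: `sum(TP_t) / N`.
#'
#' @param ct Square confusion matrix (rows = true, columns = predicted).
#' @return Fraction in `[0, 1]`.
#' @export
overallAccuracy <- function(ct) {
  check_ct(ct)
  sum(diag(ct)) / sum(ct)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of `2 * Pre * Rec / (Pre + Rec)` with
#' `Pre = TP/(TP+FP)` and `Rec = TP/(TP+FN)`.  A class with no true and no
#' predicted samples (or zero precision-plus-recall) contributes an F1 of 0.
#'
#' @inheritParams overallAccuracy
#' @return Fraction in `[0, 1]`.
#' @export
macroF1 <- function(ct) {
  check_ct(ct)
  tp <- diag(ct)
  prec <- ifelse(colSums(ct) > 0, tp / colSums(ct), 0)
  rec <- ifelse(rowSums(ct) > 0, tp / rowSums(ct), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(ACC - pe) / (1 - pe)` with expected agreement
#' `pe = sum(a_t * b_t) / N^2` from the marginal counts.  Degenerate tables
#' with `pe = 1` return 0 with a warning.
#'
#' @inheritParams overallAccuracy
#' @return Value in `[-1, 1]`.
#' @export
cohensKappa <- function(ct) {
  check_ct(ct)
  n <- sum(ct)
  acc <- sum(diag(ct)) / n
  pe <- sum(rowSums(ct) * colSums(ct)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate marginals (pe = 1); kappa defined as 0")
    return(0)
  }
  (acc - pe) / (1 - pe)
}
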