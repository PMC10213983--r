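#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @import SummarizedExperiment
NULL

#' AASM sleep stage labels
#'
#' The five-class stage alphabet, in the fixed order used by every
#' probability vector and confusion table in the package.
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' EpochSet: labeled multimodal 30-s polysomnography epochs
#'
#' `EpochSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' collection of fixed-duration polysomnography epochs: one assay per
#' modality (typically `eeg`, `eog`, `emg`), each a time-by-epoch matrix on a
#' common, rate-harmonized sampling grid, with per-epoch stage labels (and,
#' for synthetic data, difficulty tiers) in `colData`.
#'
#' @slot sampleRate Common sampling rate in Hz for all assays.
#' @slot epochSeconds Epoch duration in seconds (30 by convention).
#' @export
setClass("EpochSet",
  contains = "SummarizedExperiment",
  representation(sampleRate = "numeric", epochSeconds = "numeric")
)

setValidity("EpochSet", function(object) {
  msg <- NULL
  if (length(object@sampleRate) != 1 || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (length(object@epochSeconds) != 1 || object@epochSeconds <= 0)
    msg <- c(msg, "epochSeconds must be a single positive number")
  if (length(assays(object)) == 0)
    msg <- c(msg, "at least one modality assay is required")
  expected <- round(object@sampleRate * object@epochSeconds)
  for (nm in assayNames(object)) {
    if (nrow(assay(object, nm)) != expected)
      msg <- c(msg, sprintf(
        "assay '%s' has %d samples per epoch; expected %d (= rate x duration)",
        nm, nrow(assay(object, nm)), expected))
  }
  if (!"stage" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'stage' column")
  else if (!all(as.character(colData(object)$stage) %in% SLEEP_STAGES))
    msg <- c(msg, "stage labels must be in W/N1/N2/N3/REM")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EpochSet
#'
#' @param signals Named list of time-by-epoch numeric matrices, one per
#'   modality, all with identical dimensions.
#' @param stage Character or factor vector of per-epoch AASM stages.
#' @param sampleRate Common sampling rate (Hz).
#' @param epochSeconds Epoch duration in seconds.
#' @param tier Optional per-epoch difficulty tier (synthetic data).
#' @param subject Optional per-epoch subject identifier.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(signals, stage, sampleRate, epochSeconds = 30,
                     tier = NULL, subject = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1, !is.null(names(signals)))
  n <- ncol(signals[[1]])
  cd <- DataFrame(stage = factor(as.character(stage), levels = SLEEP_STAGES))
  if (!is.null(tier)) cd$tier <- as.character(tier)
  if (!is.null(subject)) cd$subject <- as.character(subject)
  se <- SummarizedExperiment(assays = signals, colData = cd)
  new("EpochSet", se, sampleRate = sampleRate, epochSeconds = epochSeconds)
}

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet with", ncol(object), "epochs of", object@epochSeconds,
      "s at", object@sampleRate, "Hz\n")
  cat("  modalities:", paste(assayNames(object), collapse = ", "), "\n")
  tab <- table(colData(object)$stage)
  cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if ("tier" %in% colnames(colData(object))) {
    tt <- table(colData(object)$tier)
    cat("  tiers: ", paste(sprintf("%s=%d", names(tt), tt), collapse = " "),
        "\n")
  }
})

#' SleepNet: the multi-exit sleep staging model
#'
#' Holds the model configuration, all trainable parameters (a nested list of
#' numeric arrays), non-trainable state (batch-norm running statistics), and
#' the training stage reached (0 = initialized, 1 = backbone + final exit
#' trained, 2 = early exits distilled).
#'
#' @slot config Model configuration list (see [sleepNetConfig()]).
#' @slot params Nested list of parameter arrays.
#' @slot state Nested list of batch-norm running statistics.
#' @slot trainedStage Integer 0, 1 or 2.
#' @slot history List of per-stage training histories (data frames).
#' @export
setClass("SleepNet",
  representation(config = "list", params = "list", state = "list",
                 trainedStage = "integer", history = "list")
)

setMethod("show", "SleepNet", function(object) {
  cfg <- object@config
  cat("SleepNet multi-exit classifier\n")
  cat("  modalities:", paste(cfg$modalities, collapse = ", "),
      "| feature grid:", 2 * cfg$efem$f3, "x", cfg$efem$d_out, "\n")
  cat("  parameters:", format(param_count(object@params), big.mark = ","),
      "| trained stage:", object@trainedStage, "\n")
})
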