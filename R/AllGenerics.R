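#' Accessors for EpochSet
#'
#' `stages()` returns the per-epoch AASM stage factor, `tiers()` the
#' synthetic difficulty tier (or `NULL`), `subjects()` the subject ids (or
#' `NULL`), `modalities()` the assay names, and `sampleRate()` the common
#' sampling rate in Hz.
#'
#' @param x An [EpochSet-class].
#' @return See individual accessor descriptions.
#' @name EpochSet-accessors
NULL

#' @rdname EpochSet-accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("tiers", function(x) standardGeneric("tiers"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("modalities", function(x) standardGeneric("modalities"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname EpochSet-accessors
setMethod("stages", "EpochSet", function(x) colData(x)$stage)

#' @rdname EpochSet-accessors
setMethod("tiers", "EpochSet", function(x) colData(x)$tier)

#' @rdname EpochSet-accessors
setMethod("subjects", "EpochSet", function(x) colData(x)$subject)

#' @rdname EpochSet-accessors
setMethod("modalities", "EpochSet", function(x) assayNames(x))

#' @rdname EpochSet-accessors
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)
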