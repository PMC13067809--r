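#' @rdname Recording-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname Recording-accessors
#' @export
setGeneric("leadLabels", function(x) standardGeneric("leadLabels"))
#' @rdname Recording-accessors
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname Recording-accessors
#' @export
setGeneric("electrodeKind", function(x) standardGeneric("electrodeKind"))
#' @rdname Recording-accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname Recording-accessors
#' @export
setGeneric("truthRTimes", function(x) standardGeneric("truthRTimes"))
#' @rdname Recording-accessors
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' Accessors for Recording objects
#'
#' `samplingRate` returns the sampling frequency (Hz); `leadLabels` the
#' channel labels; `participantId` and `electrodeKind` the provenance
#' metadata; `signalMatrix` the channels x samples value matrix (mV);
#' `truthRTimes` the ground-truth R-peak times (s) of a synthetic
#' recording (or `NULL`); `recordDuration` the record length in seconds.
#'
#' @param x a [Recording-class] (or, where indicated, [BeatMatrix-class]).
#' @return See details above.
#' @name Recording-accessors
NULL

#' @rdname Recording-accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname Recording-accessors
setMethod("leadLabels", "Recording", function(x) x@leadLabels)
#' @rdname Recording-accessors
setMethod("participantId", "Recording", function(x) x@participantId)
#' @rdname Recording-accessors
setMethod("electrodeKind", "Recording", function(x) x@electrode)
#' @rdname Recording-accessors
setMethod("signalMatrix", "Recording", function(x) x@samples)
#' @rdname Recording-accessors
setMethod("truthRTimes", "Recording", function(x) x@truth$rTimes)
#' @rdname Recording-accessors
setMethod("recordDuration", "Recording", function(x) ncol(x@samples) / x@fs)

#' @rdname Recording-accessors
setMethod("samplingRate", "BeatMatrix",
          function(x) S4Vectors::metadata(x)$fs)

#' Accessors for BeatMatrix objects
#'
#' `beatValues` returns the window-length x n_beats matrix of aligned
#' heartbeats (mV); `beatLabels` the per-beat `colData` (participant, lead,
#' electrode, R time); `rIndex` the 1-based row of the R peak within each
#' window.
#'
#' @param x a [BeatMatrix-class].
#' @name BeatMatrix-accessors
#' @export
beatValues <- function(x) SummarizedExperiment::assay(x, "beats")

#' @rdname BeatMatrix-accessors
#' @export
beatLabels <- function(x) SummarizedExperiment::colData(x)

#' @rdname BeatMatrix-accessors
#' @export
rIndex <- function(x) S4Vectors::metadata(x)$rIndex
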