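#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor family for the containers in this package: `sigData()`
#' returns the underlying channels x observations numeric matrix,
#' `sampleRate()` the sampling rate in Hz, `channelLabels()` the channel
#' identifiers, `bits()` the 0/1 matrix of a [BinaryMatrix-class] or
#' [CoalitionSeries-class], `hilbertAmplitude()` / `hilbertPhase()` the two
#' components of an [AnalyticSegment-class], and `scoreValue()` the
#' normalized value of a [MeasureScore-class].
#'
#' @param x an object of one of the package's classes
#' @return the slot contents documented above.
#' @name accessors
#' @aliases sigData sampleRate channelLabels bits hilbertAmplitude
#'   hilbertPhase scoreValue
#' @examples
#' seg <- syntheticEEG(n = 4, durationSec = 2, fs = 150, seed = 1)
#' dim(sigData(seg)); sampleRate(seg)
NULL

#' @rdname accessors
#' @export
setGeneric("sigData", function(x) standardGeneric("sigData"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("bits", function(x) standardGeneric("bits"))

#' @rdname accessors
#' @export
setGeneric("hilbertAmplitude", function(x) standardGeneric("hilbertAmplitude"))

#' @rdname accessors
#' @export
setGeneric("hilbertPhase", function(x) standardGeneric("hilbertPhase"))

#' @rdname accessors
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))

#' @rdname binarize
#' @export
setGeneric("binarize", function(x, ...) standardGeneric("binarize"))

#' @rdname synchronyCoalitionEntropy
#' @export
setGeneric("synchronyCoalitionEntropy",
           function(x, seed = 1L, ...) standardGeneric("synchronyCoalitionEntropy"))
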