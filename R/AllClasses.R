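#' Multichannel time-series segment
#'
#' The unit of analysis: a channels x observations real matrix with a
#' sampling rate and channel labels. EEG analyses in this package work on
#' such segments (typically 10 s windows).
#'
#' @slot data numeric matrix, channels in rows, observations in columns
#' @slot fs sampling rate in Hz
#' @slot labels character vector of channel identifiers, one per row
#' @export
setClass("Segment",
         representation(data = "matrix", fs = "numeric", labels = "character"))

setValidity("Segment", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be numeric")
  if (nrow(d) < 2L) return("a Segment needs at least 2 channels")
  if (ncol(d) < 2L) return("a Segment needs at least 2 observations")
  if (!all(is.finite(d))) {
    bad <- which(!apply(is.finite(d), 1L, all))
    return(sprintf("non-finite values in channel(s): %s",
                   paste(object@labels[bad], collapse = ", ")))
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@labels) != nrow(d)) return("one label per channel required")
  TRUE
})

#' Construct a Segment
#'
#' @param data channels x observations numeric matrix
#' @param fs sampling rate (Hz)
#' @param labels channel labels; defaults to `ch1, ch2, ...`
#' @return a [Segment-class]
#' @export
#' @examples
#' Segment(matrix(rnorm(20), 2), fs = 10)
Segment <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  new("Segment", data = data, fs = as.numeric(fs), labels = as.character(labels))
}

#' Analytic (Hilbert) representation of a segment
#'
#' Instantaneous amplitude (modulus of the analytic signal) and phase
#' (argument, in (-pi, pi]) per channel and observation.
#'
#' @slot amplitude non-negative numeric matrix, channels x observations
#' @slot phase numeric matrix in (-pi, pi], same shape
#' @slot fs sampling rate in Hz
#' @slot labels channel identifiers
#' @export
setClass("AnalyticSegment",
         representation(amplitude = "matrix", phase = "matrix",
                        fs = "numeric", labels = "character"))

setValidity("AnalyticSegment", function(object) {
  if (!identical(dim(object@amplitude), dim(object@phase)))
    return("amplitude and phase must have identical shape")
  if (any(object@amplitude < 0)) return("amplitude must be non-negative")
  if (any(object@phase <= -pi - 1e-12) || any(object@phase > pi + 1e-12))
    return("phase must lie in (-pi, pi]")
  TRUE
})

#' Binary activation / synchrony matrix
#'
#' Channels x observations 0/1 matrix, either of activations (amplitude
#' above the channel's own mean) or of synchronies. The input type for all
#' three diversity measures. When produced by [binarize()], the per-channel
#' thresholds are carried along.
#'
#' @slot bits 0/1 integer matrix, channels x observations
#' @slot kind "activation" or "synchrony"
#' @slot thresholds per-channel binarization thresholds (possibly empty)
#' @export
setClass("BinaryMatrix",
         representation(bits = "matrix", kind = "character",
                        thresholds = "numeric"))

setValidity("BinaryMatrix", function(object) {
  if (!all(object@bits %in% c(0L, 1L))) return("entries must be 0 or 1")
  if (!object@kind %in% c("activation", "synchrony"))
    return("kind must be 'activation' or 'synchrony'")
  if (length(object@thresholds) &&
      length(object@thresholds) != nrow(object@bits))
    return("thresholds must be empty or one per channel")
  TRUE
})

#' Construct a BinaryMatrix
#' @param bits 0/1 matrix (channels x observations)
#' @param kind "activation" (default) or "synchrony"
#' @param thresholds optional per-channel thresholds
#' @return a [BinaryMatrix-class]
#' @export
BinaryMatrix <- function(bits, kind = "activation", thresholds = numeric(0)) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  new("BinaryMatrix", bits = bits, kind = kind,
      thresholds = as.numeric(thresholds))
}

#' Per-reference-channel synchrony coalition series
#'
#' For a reference channel i, the n x T 0/1 matrix whose (j, t) entry is 1
#' when channels i and j are phase-synchronous at time t (absolute wrapped
#' phase difference below the threshold). Row i is identically 1.
#'
#' @slot psi 0/1 matrix n x T
#' @slot refChannel reference channel index
#' @export
setClass("CoalitionSeries",
         representation(psi = "matrix", refChannel = "integer"))

setValidity("CoalitionSeries", function(object) {
  if (!all(object@psi %in% c(0L, 1L))) return("entries must be 0 or 1")
  i <- object@refChannel
  if (i < 1L || i > nrow(object@psi)) return("refChannel out of range")
  if (!all(object@psi[i, ] == 1L)) return("self-synchrony row must be all 1")
  TRUE
})

#' A raw/normalized measure score
#'
#' Diversity measures in this package are reported as a raw value together
#' with the normalizer used (shuffled-input or random-matrix value) and
#' their ratio. The seed that generated the normalizer is recorded so the
#' score is exactly reproducible.
#'
#' @slot measure measure name ("LZc", "ACE", "SCE")
#' @slot raw raw (unnormalized) value
#' @slot normalizer value for the shuffled / random reference input
#' @slot normalized raw / normalizer
#' @slot seed seed used for the normalizer
#' @slot flags character vector of quality flags (e.g. "short-input")
#' @export
setClass("MeasureScore",
         representation(measure = "character", raw = "numeric",
                        normalizer = "numeric", normalized = "numeric",
                        seed = "integer", flags = "character"))

setValidity("MeasureScore", function(object) {
  if (object@raw < 0) return("raw must be non-negative")
  if (object@normalized < 0) return("normalized must be non-negative")
  TRUE
})

MeasureScore <- function(measure, raw, normalizer, seed,
                         flags = character(0)) {
  normalized <- if (normalizer > 0) raw / normalizer else 0
  if (normalizer <= 0) flags <- c(flags, "zero-normalizer")
  new("MeasureScore", measure = measure, raw = as.numeric(raw),
      normalizer = as.numeric(normalizer), normalized = normalized,
      seed = as.integer(seed), flags = flags)
}

#' Panel of all nine per-segment measures
#'
#' Bundles, for one segment, the three diversity measures (LZc, ACE, SCE),
#' the two control measures (mean pairwise phase synchrony and mean
#' absolute channel correlation) and the five normalized spectral band
#' powers (delta, theta, alpha, beta, gamma, summing to 1).
#'
#' @slot lzc,ace,sce [MeasureScore-class] objects
#' @slot phaseSync mean pairwise synchrony, in \\[0, 1\\]
#' @slot sumCov mean absolute pairwise Pearson correlation, in \\[0, 1\\]
#' @slot bandPower named numeric of length 5 summing to 1
#' @slot seed the panel-level seed
#' @export
setClass("MeasurePanel",
         representation(lzc = "MeasureScore", ace = "MeasureScore",
                        sce = "MeasureScore", phaseSync = "numeric",
                        sumCov = "numeric", bandPower = "numeric",
                        seed = "integer"))

setValidity("MeasurePanel", function(object) {
  if (abs(sum(object@bandPower) - 1) > 1e-9)
    return("band powers must sum to 1")
  if (object@phaseSync < 0 || object@phaseSync > 1)
    return("phaseSync must lie in [0, 1]")
  if (object@sumCov < 0 || object@sumCov > 1)
    return("sumCov must lie in [0, 1]")
  TRUE
})

#' Modular Kuramoto oscillator network
#'
#' Coupling matrix K (row i holds the incoming connections of oscillator
#' i), phase-lag matrix alpha = pi/2 - beta on the edges, community
#' membership, and the per-oscillator connection count.
#'
#' @slot K coupling matrix (oscillators x oscillators)
#' @slot alpha phase-lag matrix (same shape; meaningful where K != 0)
#' @slot communities integer community membership per oscillator
#' @slot nConn connections per oscillator
#' @slot betaExt the inter-community phase-lag parameter used
#' @export
setClass("KuramotoNetwork",
         representation(K = "matrix", alpha = "matrix",
                        communities = "integer", nConn = "integer",
                        betaExt = "numeric"))

setValidity("KuramotoNetwork", function(object) {
  if (!identical(dim(object@K), dim(object@alpha)))
    return("K and alpha must have identical shape")
  if (any(diag(object@K) != 0)) return("no self-coupling allowed")
  if (length(object@communities) != nrow(object@K))
    return("one community per oscillator")
  deg <- rowSums(object@K != 0)
  if (any(deg != object@nConn))
    return("every oscillator must have exactly nConn incoming connections")
  TRUE
})

#' A completed Kuramoto simulation
#'
#' @slot theta phases (oscillators x time steps), wrapped into (-pi, pi]
#' @slot dt Euler step size
#' @slot nSteps,nDiscard total steps and initial steps to discard
#' @slot seed seed for the initial phases
#' @export
setClass("KuramotoRun",
         representation(theta = "matrix", dt = "numeric",
                        nSteps = "integer", nDiscard = "integer",
                        seed = "integer"))

setValidity("KuramotoRun", function(object) {
  if (!all(is.finite(object@theta))) return("non-finite phases")
  if (object@nDiscard >= object@nSteps)
    return("nDiscard must be smaller than nSteps")
  TRUE
})

#' Community mean-field signals of a Kuramoto run
#'
#' One real signal per community: the real part of the mean unit phasor of
#' its oscillators, on the post-discard steps. Behaves as a [Segment-class]
#' with a nominal sampling rate of 1/dt so the diversity measures can be
#' applied directly; spectral band-power analysis of these unitless series
#' is not meaningful and not supported.
#' @export
setClass("CommunitySignals", contains = "Segment")

setValidity("CommunitySignals", function(object) {
  if (any(abs(object@data) > 1 + 1e-12))
    return("community signals are means of unit phasors, |X| <= 1")
  TRUE
})

#' Electrode layout
#'
#' Labels and 3-D coordinates for a set of electrodes, with optional
#' anatomical lobe tags. Lobe membership is supplied, never computed.
#'
#' @slot labels unique electrode labels
#' @slot coords n x 3 numeric matrix of positions
#' @slot lobe character per electrode ("frontal", "parietal", "temporal",
#'   "occipital") or NA when untagged
#' @export
setClass("ElectrodeLayout",
         representation(labels = "character", coords = "matrix",
                        lobe = "character"))

setValidity("ElectrodeLayout", function(object) {
  if (anyDuplicated(object@labels)) return("labels must be unique")
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (nrow(object@coords) != length(object@labels))
    return("one coordinate row per label")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@lobe) != length(object@labels))
    return("one lobe tag (possibly NA) per electrode")
  TRUE
})

#' Construct an ElectrodeLayout
#' @param labels electrode labels
#' @param coords n x 3 coordinate matrix
#' @param lobe optional lobe tags
#' @return an [ElectrodeLayout-class]
#' @export
ElectrodeLayout <- function(labels, coords, lobe = NULL) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (is.null(lobe)) lobe <- rep(NA_character_, length(labels))
  new("ElectrodeLayout", labels = as.character(labels), coords = coords,
      lobe = as.character(lobe))
}

#' k-medoids cluster assignment
#'
#' @slot cluster cluster id per electrode
#' @slot medoid logical flag per electrode; exactly k are TRUE
#' @slot cost total distance of points to their cluster medoid
#' @slot labels electrode labels (in layout order)
#' @export
setClass("ClusterAssignment",
         representation(cluster = "integer", medoid = "logical",
                        cost = "numeric", labels = "character"))

setValidity("ClusterAssignment", function(object) {
  k <- length(unique(object@cluster))
  if (sum(object@medoid) != k) return("exactly one medoid per cluster")
  m <- which(object@medoid)
  if (!all(object@cluster[m] %in% object@cluster) ||
      anyDuplicated(object@cluster[m]))
    return("each medoid must represent its own cluster")
  TRUE
})

## ---- accessors & show ----

#' @rdname accessors
setMethod("sigData", "Segment", function(x) x@data)
#' @rdname accessors
setMethod("sampleRate", "Segment", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "Segment", function(x) x@labels)
#' @rdname accessors
setMethod("sampleRate", "AnalyticSegment", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "AnalyticSegment", function(x) x@labels)
#' @rdname accessors
setMethod("hilbertAmplitude", "AnalyticSegment", function(x) x@amplitude)
#' @rdname accessors
setMethod("hilbertPhase", "AnalyticSegment", function(x) x@phase)
#' @rdname accessors
setMethod("bits", "BinaryMatrix", function(x) x@bits)
#' @rdname accessors
setMethod("bits", "CoalitionSeries", function(x) x@psi)
#' @rdname accessors
setMethod("scoreValue", "MeasureScore", function(x) x@normalized)

setMethod("show", "Segment", function(object) {
  cat(sprintf("%s: %d channels x %d observations @ %g Hz\n",
              class(object), nrow(object@data), ncol(object@data),
              object@fs))
})

setMethod("show", "AnalyticSegment", function(object) {
  cat(sprintf("AnalyticSegment: %d channels x %d observations @ %g Hz\n",
              nrow(object@amplitude), ncol(object@amplitude), object@fs))
})

setMethod("show", "BinaryMatrix", function(object) {
  cat(sprintf("BinaryMatrix (%s): %d channels x %d observations, density %.3f\n",
              object@kind, nrow(object@bits), ncol(object@bits),
              mean(object@bits)))
})

setMethod("show", "MeasureScore", function(object) {
  cat(sprintf("%s: normalized %.4f (raw %.4g / normalizer %.4g, seed %d)%s\n",
              object@measure, object@normalized, object@raw,
              object@normalizer, object@seed,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "MeasurePanel", function(object) {
  cat("MeasurePanel\n")
  cat(sprintf("  LZc %.4f  ACE %.4f  SCE %.4f\n",
              object@lzc@normalized, object@ace@normalized,
              object@sce@normalized))
  cat(sprintf("  PhaseSync %.4f  sumCov %.4f\n",
              object@phaseSync, object@sumCov))
  cat("  band power:", paste(sprintf("%s %.3f", names(object@bandPower),
                                     object@bandPower), collapse = "  "),
      "\n")
})

setMethod("show", "KuramotoNetwork", function(object) {
  cat(sprintf("KuramotoNetwork: %d oscillators, %d communities, %d connections each, betaExt %g\n",
              nrow(object@K), length(unique(object@communities)),
              object@nConn, object@betaExt))
})

setMethod("show", "KuramotoRun", function(object) {
  cat(sprintf("KuramotoRun: %d oscillators, %d steps (dt %g, %d discarded), seed %d\n",
              nrow(object@theta), object@nSteps, object@dt,
              object@nDiscard, object@seed))
})

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d electrodes%s\n", length(object@labels),
              if (all(is.na(object@lobe))) "" else " (lobe-tagged)"))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d clusters over %d points, cost %.4g\n",
              length(unique(object@cluster)), length(object@cluster),
              object@cost))
  cat("  medoids:", paste(object@labels[object@medoid], collapse = ", "),
      "\n")
})
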