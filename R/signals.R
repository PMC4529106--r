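## Time-series transforms shared by all measures: analytic signal,
## binarization, pairwise synchrony coalitions, surrogate data,
## filtering/preprocessing and the surface Laplacian.

# Analytic signal of one real vector via the FFT half-spectrum method:
# zero the negative frequencies, double the positive ones, keep DC (and
# Nyquist for even length) untouched.
analyticVector <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Analytic (Hilbert) signal of a segment
#'
#' Computes, per channel, the analytic signal whose modulus is the
#' instantaneous amplitude and whose argument is the instantaneous Hilbert
#' phase. The full segment is transformed with no taper; `edgeDiscard`
#' optionally drops that many samples at each end of the result to trim
#' Hilbert edge effects (default 0, i.e. keep everything).
#'
#' @param segment a [Segment-class]
#' @param edgeDiscard samples to drop at each edge of the output
#' @return an [AnalyticSegment-class]
#' @export
#' @examples
#' t <- seq(0, 9.996, by = 1 / 250)
#' seg <- Segment(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs = 250)
#' a <- analytic(seg)
#' range(hilbertAmplitude(a)[, 100:2400])  # ~1 away from the edges
analytic <- function(segment, edgeDiscard = 0L) {
  stopifnot(is(segment, "Segment"))
  validObject(segment)
  d <- sigData(segment)
  z <- t(apply(d, 1L, analyticVector))
  if (edgeDiscard > 0) {
    keep <- (edgeDiscard + 1L):(ncol(d) - edgeDiscard)
    z <- z[, keep, drop = FALSE]
  }
  new("AnalyticSegment", amplitude = Mod(z), phase = Arg(z),
      fs = sampleRate(segment), labels = channelLabels(segment))
}

#' Binarize amplitudes at each channel's mean
#'
#' Each channel's instantaneous amplitude is thresholded at that channel's
#' own temporal mean: a bit is 1 when the amplitude strictly exceeds the
#' mean. The strict inequality makes a constant channel all-inactive. By
#' construction every channel's bit row depends only on that channel, so
#' all channels are equally "active" under this scheme.
#'
#' @param x an [AnalyticSegment-class], or a plain non-negative numeric
#'   matrix of amplitudes (channels x observations)
#' @param ... unused
#' @return a [BinaryMatrix-class] of kind "activation" carrying the
#'   per-channel thresholds
#' @rdname binarize
#' @export
#' @examples
#' binarize(matrix(c(1, 3, 1, 3), nrow = 1))  # threshold 2 -> 0 1 0 1
setMethod("binarize", "AnalyticSegment", function(x, ...) {
  binarize(hilbertAmplitude(x))
})

#' @rdname binarize
#' @export
setMethod("binarize", "matrix", function(x, ...) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  thr <- rowMeans(x)
  b <- (x > thr) * 1L
  BinaryMatrix(b, kind = "activation", thresholds = thr)
})

#' @rdname binarize
#' @export
setMethod("binarize", "BinaryMatrix", function(x, ...) {
  binarize(bits(x) + 0)
})

#' Synchrony coalition series for one reference channel
#'
#' Channels i and j count as synchronous at time t when the absolute
#' wrapped difference of their instantaneous phases is strictly less than
#' `phaseThreshold` (default 0.8 radians, about 45 degrees). Differences
#' are wrapped into (-pi, pi] before comparison. The self-synchrony row
#' (j = i) is identically 1; it adds no entropy but fixes the coalition
#' alphabet at 2^n.
#'
#' @param analytic an [AnalyticSegment-class]
#' @param refChannel index of the reference channel i
#' @param phaseThreshold synchrony threshold in radians, in (0, pi)
#' @return a [CoalitionSeries-class]
#' @export
synchronyCoalitions <- function(analytic, refChannel,
                                phaseThreshold = 0.8) {
  stopifnot(is(analytic, "AnalyticSegment"))
  ph <- hilbertPhase(analytic)
  n <- nrow(ph)
  if (length(refChannel) != 1L || refChannel < 1L || refChannel > n)
    stop("invalid reference channel index: ", refChannel)
  if (phaseThreshold <= 0 || phaseThreshold >= pi)
    stop("phaseThreshold must lie in (0, pi)")
  d <- ph - matrix(ph[refChannel, ], n, ncol(ph), byrow = TRUE)
  psi <- (abs(wrapPhase(d)) < phaseThreshold) * 1L
  psi[refChannel, ] <- 1L
  new("CoalitionSeries", psi = psi, refChannel = as.integer(refChannel))
}

#' Phase-randomized surrogate of a segment
#'
#' Fourier transforms each channel, adds an independent random phase to
#' every frequency (conjugate-symmetric, so the inverse transform is
#' real), and inverts. The per-channel amplitude spectrum -- and hence the
#' power spectrum and variance -- is preserved to numerical precision while
#' all phase structure, within and across channels, is destroyed.
#'
#' @param segment a [Segment-class] with at least 4 observations
#' @param seed RNG seed for the random phases
#' @return a [Segment-class] of the same shape
#' @export
phaseRandomize <- function(segment, seed = 1L) {
  stopifnot(is(segment, "Segment"))
  d <- sigData(segment)
  n <- nrow(d); T <- ncol(d)
  if (T < 4L) stop("need at least 4 observations")
  half <- (T - 1L) %/% 2L          # strictly-positive, non-Nyquist bins
  out <- withSeed(seed, {
    t(apply(d, 1L, function(x) {
      X <- stats::fft(x)
      phi <- numeric(T)
      if (half >= 1L) {
        p <- stats::runif(half, 0, 2 * pi)
        phi[2L:(half + 1L)] <- p
        phi[T:(T - half + 1L)] <- -p
      }
      if (T %% 2L == 0L)            # Nyquist must stay real: random sign
        phi[T / 2L + 1L] <- sample(c(0, pi), 1L)
      Re(stats::fft(X * exp(1i * phi), inverse = TRUE) / T)
    }))
  })
  Segment(out, fs = sampleRate(segment), labels = channelLabels(segment))
}

butterFilter <- function(d, fs, w, type, order = 4L) {
  flt <- signal::butter(order, w / (fs / 2), type = type)
  t(apply(d, 1L, function(x) signal::filtfilt(flt, x)))
}

#' Preprocess a segment
#'
#' Applies, in order and each only when requested: zero-phase Butterworth
#' notch filters (default width +/- 1 Hz, 4th order, forward-backward);
#' band-pass or high-pass Butterworth filtering; anti-aliased integer-factor
#' downsampling; per-channel linear detrending (least-squares line, which
#' also removes the mean); per-channel mean subtraction. With all stages
#' disabled the segment is returned unchanged.
#'
#' @param segment a [Segment-class]
#' @param notch frequencies (Hz) to notch out, or NULL
#' @param band `c(low, high)` band-pass edges (Hz), or NULL
#' @param highpass high-pass edge (Hz), or NULL (ignored when `band` given)
#' @param decimateTo target sampling rate (Hz); must divide fs
#' @param detrend subtract the per-channel least-squares line?
#' @param demean subtract the per-channel mean?
#' @param notchWidth half-width of each notch (Hz)
#' @return a preprocessed [Segment-class]
#' @export
preprocessSegment <- function(segment, notch = NULL, band = NULL,
                              highpass = NULL, decimateTo = NULL,
                              detrend = FALSE, demean = FALSE,
                              notchWidth = 1) {
  stopifnot(is(segment, "Segment"))
  d <- sigData(segment)
  fs <- sampleRate(segment)
  checkEdge <- function(f, what) {
    if (any(f <= 0) || any(f >= fs / 2))
      stop(what, " edge(s) outside (0, fs/2): ", paste(f, collapse = ", "))
  }
  for (f0 in notch) {
    checkEdge(c(f0 - notchWidth, f0 + notchWidth), "notch")
    d <- butterFilter(d, fs, c(f0 - notchWidth, f0 + notchWidth), "stop")
  }
  if (!is.null(band)) {
    checkEdge(band, "band-pass")
    d <- butterFilter(d, fs, band, "pass")
  } else if (!is.null(highpass)) {
    checkEdge(highpass, "high-pass")
    d <- butterFilter(d, fs, highpass, "high")
  }
  if (!is.null(decimateTo)) {
    q <- fs / decimateTo
    if (abs(q - round(q)) > 1e-9)
      stop("fs (", fs, ") is not an integer multiple of decimateTo (",
           decimateTo, ")")
    d <- t(apply(d, 1L, function(x) signal::decimate(x, round(q))))
    fs <- decimateTo
  }
  if (detrend) {
    tt <- seq_len(ncol(d))
    d <- t(apply(d, 1L, function(x) stats::residuals(stats::lm.fit(
      cbind(1, tt), x))))
  }
  if (demean) d <- d - rowMeans(d)
  Segment(d, fs = fs, labels = channelLabels(segment))
}

#' Nearest-neighbour surface Laplacian
#'
#' Spatial high-pass re-referencing: each channel is replaced by itself
#' minus the inverse-distance-weighted mean of its k nearest neighbouring
#' electrodes (weights proportional to 1/distance, normalized to sum to 1).
#' This is a local approximation to the surface Laplacian used to sharpen
#' EEG topography; the output is invariant to adding a common constant to
#' all channels.
#'
#' @param segment a [Segment-class]
#' @param layout an [ElectrodeLayout-class] covering every channel of the
#'   segment (matched by label)
#' @param k number of nearest neighbours (default 4)
#' @return the spatially filtered [Segment-class]
#' @export
surfaceLaplacian <- function(segment, layout, k = 4L) {
  stopifnot(is(segment, "Segment"), is(layout, "ElectrodeLayout"), k >= 1L)
  idx <- match(channelLabels(segment), layout@labels)
  if (anyNA(idx))
    stop("layout is missing coordinates for channel(s): ",
         paste(channelLabels(segment)[is.na(idx)], collapse = ", "))
  xyz <- layout@coords[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(xyz))
  diag(D) <- Inf
  if (any(D[upper.tri(D)] == 0)) stop("duplicate electrode coordinates")
  n <- nrow(xyz)
  if (k > n - 1L) stop("k exceeds the number of available neighbours")
  d <- sigData(segment)
  out <- d
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    w <- 1 / D[i, nb]
    w <- w / sum(w)
    out[i, ] <- d[i, ] - as.numeric(w %*% d[nb, , drop = FALSE])
  }
  Segment(out, fs = sampleRate(segment), labels = channelLabels(segment))
}
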