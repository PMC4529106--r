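## The three diversity measures (LZc, ACE, SCE) and the control measures
## (PhaseSync, sumCov, normalized band powers).

asBitVector <- function(sequence) {
  if (is.character(sequence)) {
    if (length(sequence) != 1L) stop("supply a single string or a 0/1 vector")
    sequence <- as.integer(strsplit(sequence, "")[[1]])
  }
  s <- as.integer(sequence)
  if (length(s) < 1L) stop("sequence must have length >= 1")
  if (anyNA(s) || !all(s %in% c(0L, 1L)))
    stop("sequence must contain only the symbols 0 and 1")
  s
}

#' Lempel-Ziv word count of a binary sequence
#'
#' Counts the number of words in the Lempel-Ziv parsing of a 0/1 sequence.
#' The default parser is the 1976 exhaustive-history production parsing
#' (each new word is the shortest extension of the longest already-seen
#' prefix); `parser = "lz78"` counts incremental-dictionary phrases
#' instead. The two give nearly identical normalized results.
#'
#' @param sequence a 0/1 integer vector or a single string like "0101"
#' @param parser "lz76" (default) or "lz78"
#' @return the number of words (positive integer)
#' @export
#' @examples
#' lzWordCount("0001101001000101")  # 6
#' lzWordCount("0000000000")        # 2
lzWordCount <- function(sequence, parser = c("lz76", "lz78")) {
  parser <- match.arg(parser)
  s <- asBitVector(sequence)
  if (parser == "lz76") lz76_count_cpp(s) else lz78_count_cpp(s)
}

#' Concatenate a binary matrix observation by observation
#'
#' Flattens a channels x observations 0/1 matrix into one binary sequence:
#' all channels at t = 1 (in channel order), then all channels at t = 2,
#' and so on.
#'
#' @param binary a [BinaryMatrix-class] or plain 0/1 matrix
#' @return integer 0/1 vector of length n * T
#' @export
#' @examples
#' concatObservations(rbind(c(1, 0), c(0, 1)))  # 1 0 0 1
concatObservations <- function(binary) {
  b <- if (is(binary, "BinaryMatrix")) bits(binary) else binary
  asBitVector(as.vector(b))
}

#' Lempel-Ziv complexity of a binary matrix (LZc)
#'
#' Concatenates the matrix observation by observation, counts Lempel-Ziv
#' words, and normalizes by the word count of the same sequence randomly
#' shuffled, so that a fully random input scores about 1 and duplicated or
#' ordered structure pulls the score toward 0. A single seeded shuffle is
#' used by default; on EEG-sized inputs the shuffle-to-shuffle spread of
#' the normalizer is a small fraction of a percent, and `nShuffles > 1`
#' averages several normalizers if desired.
#'
#' @param binary a [BinaryMatrix-class] or plain 0/1 matrix
#' @param seed seed for the shuffle(s)
#' @param nShuffles number of random shuffles averaged into the normalizer
#' @param parser passed to [lzWordCount()]
#' @return a [MeasureScore-class]
#' @export
lzComplexity <- function(binary, seed = 1L, nShuffles = 1L,
                         parser = c("lz76", "lz78")) {
  parser <- match.arg(parser)
  s <- concatObservations(binary)
  flags <- character(0)
  if (length(s) < 100L) {
    warning("sequence shorter than 100 symbols; ",
            "shuffle normalization is unreliable")
    flags <- "short-input"
  }
  raw <- lzWordCount(s, parser)
  norms <- withSeed(seed, vapply(seq_len(nShuffles), function(i)
    lzWordCount(sample(s), parser), numeric(1)))
  MeasureScore("LZc", raw, mean(norms), seed, flags)
}

#' Encode coalition columns as integer symbols
#'
#' Maps each n x 1 binary observation (coalition) to a distinct number,
#' `sum(bits * 2^(0:(n-1)))`. Injective for n up to 52 channels using
#' exact double arithmetic; for 53-62 channels an equally injective string
#' encoding is used internally. More channels are rejected.
#'
#' @param binary a [BinaryMatrix-class], [CoalitionSeries-class] or 0/1
#'   matrix
#' @return numeric (or character, for n > 52) vector of length T
#' @export
#' @examples
#' coalitionSymbols(cbind(c(0, 0), c(0, 1), c(0, 1), c(1, 1)))  # 0 2 2 3
coalitionSymbols <- function(binary) {
  b <- if (is(binary, "BinaryMatrix") || is(binary, "CoalitionSeries"))
    bits(binary) else binary
  n <- nrow(b)
  if (n > 62L)
    stop("coalition encoding supports at most 62 channels; ",
         "select a channel subset first")
  if (n <= 52L) as.numeric(2^(seq_len(n) - 1L) %*% b)
  else apply(b, 2L, paste0, collapse = "")
}

#' Plug-in Shannon entropy of a symbol sequence
#'
#' Maximum-likelihood (plug-in) entropy of the empirical distribution, in
#' bits. No bias correction is applied: the measures built on this entropy
#' are normalized by equally-undersampled shuffled or random reference
#' data, which is the bias control.
#'
#' @param symbols vector of symbols (any atomic type)
#' @return entropy in bits (non-negative)
#' @export
#' @examples
#' shannonEntropy(c(0, 2, 2, 3))  # 1.5
shannonEntropy <- function(symbols) {
  if (length(symbols) < 1L) stop("need at least one symbol")
  p <- tabulate(match(symbols, unique(symbols))) / length(symbols)
  -sum(p * log2(p))
}

#' Amplitude coalition entropy (ACE)
#'
#' Entropy over time of the constitution of the set of active channels:
#' the coalition columns of the binary activation matrix are encoded as
#' symbols and their plug-in entropy is normalized by the value obtained
#' after randomly permuting the position of every entry of the matrix
#' (the attainable upper bound for these dimensions, since for T < 2^n
#' not all coalitions can be sampled). `shuffle = "within-channel"`
#' permutes each row separately instead.
#'
#' @param binary a [BinaryMatrix-class] or plain 0/1 matrix
#' @param seed seed for the shuffle
#' @param shuffle "matrix" (default; permute all entries jointly) or
#'   "within-channel"
#' @return a [MeasureScore-class]; a constant matrix yields a flagged 0
#' @export
amplitudeCoalitionEntropy <- function(binary, seed = 1L,
                                      shuffle = c("matrix",
                                                  "within-channel")) {
  shuffle <- match.arg(shuffle)
  b <- if (is(binary, "BinaryMatrix")) bits(binary) else binary
  raw <- shannonEntropy(coalitionSymbols(b))
  shuf <- withSeed(seed, {
    if (shuffle == "matrix") matrix(sample(b), nrow(b))
    else t(apply(b, 1L, sample))
  })
  MeasureScore("ACE", raw, shannonEntropy(coalitionSymbols(shuf)), seed)
}

# Entropy of the coalition columns of a random 0/1 matrix of the given
# shape with independent Bernoulli(0.5) entries: the SCE normalizer.
randomCoalitionEntropy <- function(n, T, seed) {
  withSeed(seed, {
    r <- matrix(stats::rbinom(n * T, 1L, 0.5), n)
    shannonEntropy(coalitionSymbols(r))
  })
}

#' Synchrony coalition entropy (SCE)
#'
#' For each reference channel i, the synchrony coalition series (which
#' channels are phase-locked to channel i at each time) is encoded as
#' symbols; its plug-in entropy is normalized by the entropy of a random
#' coalition matrix of identical shape in which each entry is 1 with
#' probability 0.5 (one such matrix per segment, seeded). The overall SCE
#' is the mean of the per-channel values. Unlike LZc and ACE, SCE does not
#' score exactly 1 for temporally shuffled real signals, because the
#' probability of two shuffled channels being synchronous is below 0.5.
#'
#' A [BinaryMatrix-class] may also be given, in which case the matrix
#' itself is treated as a single synchrony coalition series and its column
#' entropy is normalized the same way -- the form used when studying the
#' measures on directly constructed synchrony matrices.
#'
#' @param x an [AnalyticSegment-class] or a [BinaryMatrix-class]
#' @param seed seed for the random normalizer matrix
#' @param phaseThreshold synchrony threshold in radians (analytic input)
#' @param ... unused
#' @return a [MeasureScore-class]; for analytic input, `raw` is the mean
#'   per-reference-channel coalition entropy
#' @rdname synchronyCoalitionEntropy
#' @export
setMethod("synchronyCoalitionEntropy", "AnalyticSegment",
          function(x, seed = 1L, phaseThreshold = 0.8, ...) {
  n <- nrow(hilbertPhase(x))
  T <- ncol(hilbertPhase(x))
  if (n < 2L) stop("need at least 2 channels")
  N <- randomCoalitionEntropy(n, T, seed)
  H <- vapply(seq_len(n), function(i)
    shannonEntropy(coalitionSymbols(
      synchronyCoalitions(x, i, phaseThreshold))), numeric(1))
  MeasureScore("SCE", mean(H), N, seed)
})

#' @rdname synchronyCoalitionEntropy
#' @export
setMethod("synchronyCoalitionEntropy", "BinaryMatrix",
          function(x, seed = 1L, ...) {
  b <- bits(x)
  N <- randomCoalitionEntropy(nrow(b), ncol(b), seed)
  MeasureScore("SCE", shannonEntropy(coalitionSymbols(b)), N, seed)
})

#' Mean pairwise phase synchrony
#'
#' The fraction of (ordered channel pair, time) combinations that are
#' phase-synchronous (absolute wrapped phase difference strictly below the
#' threshold). Self-pairs are excluded: they are constantly synchronous
#' and would only inflate the mean.
#'
#' @param analytic an [AnalyticSegment-class]
#' @param phaseThreshold synchrony threshold in radians
#' @return a number in \\[0, 1\\]
#' @export
phaseSync <- function(analytic, phaseThreshold = 0.8) {
  stopifnot(is(analytic, "AnalyticSegment"))
  ph <- hilbertPhase(analytic)
  n <- nrow(ph)
  if (n < 2L) stop("need at least 2 channels")
  tot <- 0
  for (i in seq_len(n - 1L)) {
    d <- ph[(i + 1L):n, , drop = FALSE] -
      matrix(ph[i, ], n - i, ncol(ph), byrow = TRUE)
    tot <- tot + sum(abs(wrapPhase(d)) < phaseThreshold)
  }
  tot / (n * (n - 1L) / 2 * ncol(ph))
}

#' Mean absolute pairwise correlation (sumCov)
#'
#' Mean of |Pearson r| over all unordered distinct channel pairs of the
#' raw signal.
#'
#' @param segment a [Segment-class]; every channel must have nonzero
#'   variance
#' @return a number in \\[0, 1\\]
#' @export
sumCov <- function(segment) {
  stopifnot(is(segment, "Segment"))
  d <- sigData(segment)
  v <- apply(d, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance channel(s): ",
         paste(channelLabels(segment)[v == 0], collapse = ", "))
  C <- abs(stats::cor(t(d)))
  mean(C[upper.tri(C)])
}

bandDefinitions <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 70))
}

#' Normalized spectral band powers
#'
#' FFT power spectrum per channel, averaged across channels, integrated
#' over the conventional EEG bands (delta 1-4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-70 Hz; half-open bins `[low, high)` so boundary
#' frequencies are counted once), and normalized so the five band powers
#' sum to 1.
#'
#' @param segment a [Segment-class] with fs >= 140 Hz (gamma resolvable)
#' @return named numeric of length 5 summing to 1
#' @export
bandPowers <- function(segment) {
  stopifnot(is(segment, "Segment"))
  fs <- sampleRate(segment)
  if (fs < 140) stop("fs must be >= 140 Hz to resolve the gamma band")
  d <- sigData(segment)
  T <- ncol(d)
  nf <- floor(T / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / T
  P <- rowMeans(vapply(seq_len(nrow(d)), function(i)
    Mod(stats::fft(d[i, ]))[seq_len(nf)]^2, numeric(nf)))
  bp <- vapply(bandDefinitions(), function(b)
    sum(P[freqs >= b[1] & freqs < b[2]]), numeric(1))
  bp / sum(bp)
}

#' Compute the full nine-measure panel for one segment
#'
#' One analytic-signal pass feeds all measures: LZc and ACE from the
#' amplitude-binarized matrix, SCE and PhaseSync from the phases, sumCov
#' and the five normalized band powers from the raw signal. The three
#' normalizer seeds are derived deterministically from `seed` and recorded
#' in the scores.
#'
#' @param segment a [Segment-class]
#' @param seed panel-level seed
#' @param phaseThreshold synchrony threshold in radians
#' @param edgeDiscard passed to [analytic()]
#' @param bands compute band powers? (requires fs >= 140; set FALSE for
#'   unitless simulation output)
#' @return a [MeasurePanel-class]
#' @export
measurePanel <- function(segment, seed = 1L, phaseThreshold = 0.8,
                         edgeDiscard = 0L, bands = TRUE) {
  stopifnot(is(segment, "Segment"))
  seeds <- deriveSeeds(seed, 3L)
  a <- analytic(segment, edgeDiscard)
  b <- binarize(a)
  bp <- if (bands) bandPowers(segment)
  else stats::setNames(rep(0.2, 5), names(bandDefinitions()))
  new("MeasurePanel",
      lzc = lzComplexity(b, seeds[1]),
      ace = amplitudeCoalitionEntropy(b, seeds[2]),
      sce = synchronyCoalitionEntropy(a, seeds[3],
                                      phaseThreshold = phaseThreshold),
      phaseSync = phaseSync(a, phaseThreshold),
      sumCov = sumCov(segment),
      bandPower = bp,
      seed = as.integer(seed))
}

#' Flatten a MeasurePanel to a named numeric vector
#'
#' @param panel a [MeasurePanel-class]
#' @return named numeric with the nine measure values
#' @export
panelScores <- function(panel) {
  stopifnot(is(panel, "MeasurePanel"))
  c(LZc = panel@lzc@normalized, ACE = panel@ace@normalized,
    SCE = panel@sce@normalized, PhaseSync = panel@phaseSync,
    sumCov = panel@sumCov, panel@bandPower)
}
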