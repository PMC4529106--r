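## Seeded generators for every synthetic input used by the simulations and
## the test-suite: random binary matrices, duplicated-channel and
## sorted-subsequence manipulations, and a two-state synthetic EEG
## emulator. No external data are needed anywhere in the package.

#' Random Bernoulli binary matrix
#'
#' @param n,T channels and observations
#' @param p probability of a 1 (default 0.5)
#' @param seed RNG seed
#' @return a [BinaryMatrix-class]
#' @export
randomBinaryMatrix <- function(n = 25L, T = 2500L, p = 0.5, seed = 1L) {
  stopifnot(n >= 1L, T >= 1L)
  b <- withSeed(seed, matrix(stats::rbinom(n * T, 1L, p), n))
  BinaryMatrix(b)
}

#' Random binary matrix with duplicated channels
#'
#' Draws a random Bernoulli(0.5) matrix and replaces `kDuplicates` rows
#' (random indices other than row 1, drawn without replacement from a
#' seeded permutation, so the duplicate sets are nested: k and k+1 differ
#' by exactly one additional duplicated row) by copies of row 1. With
#' `kDuplicates = n - 1` all rows are identical.
#'
#' @param n,T channels and observations (defaults 25 x 2500)
#' @param kDuplicates number of rows to replace, 0 .. n-1
#' @param seed RNG seed (drives both the matrix and the permutation)
#' @return a [BinaryMatrix-class]
#' @export
duplicatedChannelMatrix <- function(n = 25L, T = 2500L, kDuplicates = 0L,
                                    seed = 1L) {
  if (kDuplicates < 0L || kDuplicates > n - 1L)
    stop("kDuplicates must lie in 0 .. n-1")
  withSeed(seed, {
    b <- matrix(stats::rbinom(n * T, 1L, 0.5), n)
    perm <- sample(2:n)
    if (kDuplicates > 0L)
      b[perm[seq_len(kDuplicates)], ] <- rep(b[1L, ],
                                             each = kDuplicates)
    BinaryMatrix(b)
  })
}

#' Random binary matrix with sorted subsequences
#'
#' Per channel, an independent random window of `sortLength` consecutive
#' bits (start chosen uniformly so the window never wraps) is replaced by
#' the same bits sorted ascending -- zeros left, ones right. The
#' per-channel ones-count is invariant; increasing `sortLength` makes each
#' row increasingly ordered.
#'
#' @param n,T channels and observations
#' @param sortLength window length, 0 .. T
#' @param seed RNG seed
#' @return a [BinaryMatrix-class]
#' @export
sortedSubsequenceMatrix <- function(n = 25L, T = 2500L, sortLength = 0L,
                                    seed = 1L) {
  if (sortLength < 0L || sortLength > T)
    stop("sortLength must lie in 0 .. T")
  withSeed(seed, {
    b <- matrix(stats::rbinom(n * T, 1L, 0.5), n)
    if (sortLength > 0L) {
      for (i in seq_len(n)) {
        start <- sample.int(T - sortLength + 1L, 1L)
        w <- start:(start + sortLength - 1L)
        b[i, w] <- sort(b[i, w])
      }
    }
    BinaryMatrix(b)
  })
}

# Band-limited Gaussian noise: white noise filtered into [low, high) Hz.
bandNoise <- function(T, fs, low, high, order = 2L) {
  x <- stats::rnorm(T + 200L)  # pad to absorb filter transients
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(flt, x)[101:(T + 100L)]
  y / stats::sd(y)
}

#' Synthetic multichannel EEG-like segment
#'
#' A stand-in generator for two contrasting dynamical regimes, not a
#' biophysical model. `awake_like` superimposes, per channel, independent
#' band-limited noise in the five conventional bands (unit-variance
#' components weighted delta 1.0, theta 0.8, alpha 0.8, beta 0.6, gamma
#' 0.4) plus a mild common broadband drive (weight 0.25), giving diverse,
#' weakly coupled channels. `anaesthesia_like` is dominated by one common
#' 1-4 Hz slow oscillation (weight 3.0) shared by all channels plus weak
#' independent broadband noise (weight 0.3), giving strongly synchronized,
#' slow-wave-heavy channels. By construction the anaesthesia-like state
#' has the higher normalized delta power and the lower LZc/ACE/SCE.
#'
#' @param n channels (default 25)
#' @param durationSec segment length in seconds (default 10)
#' @param fs sampling rate, >= 140 Hz (default 250)
#' @param state "awake_like" or "anaesthesia_like"
#' @param seed RNG seed
#' @return a [Segment-class]
#' @export
syntheticEEG <- function(n = 25L, durationSec = 10, fs = 250,
                         state = c("awake_like", "anaesthesia_like"),
                         seed = 1L) {
  state <- match.arg(state)
  if (fs < 140) stop("fs must be >= 140 Hz")
  T <- round(durationSec * fs)
  bands <- bandDefinitions()
  weights <- c(delta = 1.0, theta = 0.8, alpha = 0.8, beta = 0.6,
               gamma = 0.4)
  d <- withSeed(seed, {
    if (state == "awake_like") {
      common <- bandNoise(T, fs, 1, 70)
      t(vapply(seq_len(n), function(i) {
        x <- numeric(T)
        for (bn in names(bands))
          x <- x + weights[bn] * bandNoise(T, fs, bands[[bn]][1],
                                           bands[[bn]][2])
        x + 0.25 * common
      }, numeric(T)))
    } else {
      slow <- bandNoise(T, fs, 1, 4)
      t(vapply(seq_len(n), function(i)
        3.0 * slow + 0.3 * bandNoise(T, fs, 1, 70), numeric(T)))
    }
  })
  Segment(d, fs = fs,
          labels = paste0("ch", seq_len(n)))
}
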