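# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals.

# Exhaustive-history Lempel-Ziv word count, by direct definition: at each
# position find the longest prefix of the remainder that occurs starting
# at an earlier index (overlap allowed), take one symbol more as the next
# word, cap at the end of the sequence.
lz76Oracle <- function(s) {
  if (is.character(s)) s <- as.integer(strsplit(s, "")[[1]])
  n <- length(s)
  p <- 1L
  c <- 0L
  while (p <= n) {
    best <- 0L
    for (start in seq_len(p - 1L)) {
      l <- 0L
      while (p + l <= n && s[start + l] == s[p + l]) l <- l + 1L
      if (l > best) best <- l
    }
    w <- min(best + 1L, n - p + 1L)
    p <- p + w
    c <- c + 1L
  }
  c
}

# Plug-in entropy straight from the formula, via string-keyed counting.
entropyOracle <- function(symbols) {
  p <- as.numeric(table(as.character(symbols))) / length(symbols)
  -sum(p * log2(p))
}

# Area under the ROC curve by explicit threshold sweep + trapezoid rule.
arocOracle <- function(a, b) {
  thr <- sort(unique(c(a, b)), decreasing = TRUE)
  fa <- c(0, vapply(thr, function(C) mean(b >= C), numeric(1)))
  hit <- c(0, vapply(thr, function(C) mean(a >= C), numeric(1)))
  sum(diff(fa) * (utils::head(hit, -1) + utils::tail(hit, -1)) / 2)
}

# Exact two-sided rank-sum p-value by full enumeration of all group
# assignments of the pooled (tie-free) sample.
wilcoxonEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  W0 <- sum(rank(pooled)[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(length(pooled), na)
  W <- apply(splits, 2L, function(idx)
    sum(rank(pooled)[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(W - mu) >= abs(W0 - mu) - 1e-12)
}

# Benjamini-Hochberg step-up, straight from the definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# An AnalyticSegment built directly from a phase matrix (unit amplitude),
# bypassing the Hilbert transform, for phase-logic tests.
phaseSegment <- function(phase, fs = 1) {
  new("AnalyticSegment", amplitude = matrix(1, nrow(phase), ncol(phase)),
      phase = phase, fs = fs,
      labels = paste0("ch", seq_len(nrow(phase))))
}

# Uncoupled Kuramoto network (K = 0) of n oscillators.
uncoupledNetwork <- function(n) {
  new("KuramotoNetwork", K = matrix(0, n, n), alpha = matrix(0, n, n),
      communities = rep(1L, n), nConn = 0L, betaExt = 0)
}

# Small fully connected network with uniform coupling k and zero lag.
fullNetwork <- function(n, k) {
  K <- matrix(k, n, n); diag(K) <- 0
  new("KuramotoNetwork", K = K, alpha = matrix(0, n, n),
      communities = rep(1L, n), nConn = as.integer(n - 1L), betaExt = 0)
}

circularDiff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}
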