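test_that("LZ76 word count matches hand-checkable cases", {
  expect_equal(lzWordCount("0"), 1L)
  expect_equal(lzWordCount("1"), 1L)
  expect_equal(lzWordCount("0000000000"), 2L)
  expect_equal(lzWordCount("0001101001000101"), 6L)  # frozen from oracle
  expect_error(lzWordCount("0102"), "symbols")
  expect_error(lzWordCount(integer(0)), "length")
})

test_that("LZ76 equals the brute-force parser on random strings", {
  set.seed(3)
  for (r in 1:200) {
    L <- sample(1:40, 1)
    s <- rbinom(L, 1, runif(1, 0.1, 0.9))
    expect_equal(lzWordCount(s), lz76Oracle(s))
  }
})

test_that("suffix-array and scan implementations of LZ76 agree at scale", {
  set.seed(17)
  cases <- list(rbinom(5000, 1, 0.5),
                rbinom(5000, 1, 0.02),
                rep(rbinom(200, 1, 0.5), each = 25),
                sort(rbinom(5000, 1, 0.5)))
  for (s in cases)
    expect_equal(SignalDiversity:::lz76_count_cpp(as.integer(s)),
                 SignalDiversity:::lz76_count_ks_cpp(as.integer(s)))
})

test_that("the LZ78 dictionary parser behaves like an LZ parser", {
  expect_equal(lzWordCount("0", parser = "lz78"), 1L)
  # 0|1|00|01|1(incomplete) -> 5 phrases
  expect_equal(lzWordCount("0100011", parser = "lz78"), 5L)
  set.seed(4)
  s <- rbinom(5000, 1, 0.5)
  r76 <- lzWordCount(s) / lzWordCount(sample(s))
  r78 <- lzWordCount(s, parser = "lz78") /
    lzWordCount(sample(s), parser = "lz78")
  expect_lt(abs(r76 - r78), 0.05)  # nearly identical normalized outcomes
})

test_that("observations are concatenated column by column", {
  expect_equal(concatObservations(rbind(c(1, 0), c(0, 1))),
               c(1L, 0L, 0L, 1L))
  expect_equal(concatObservations(matrix(c(1, 0, 1), nrow = 1)),
               c(1L, 0L, 1L))
  expect_equal(concatObservations(matrix(c(1, 0, 1), ncol = 1)),
               c(1L, 0L, 1L))
})

test_that("coalition columns encode injectively", {
  expect_equal(coalitionSymbols(matrix(c(1, 0, 0), ncol = 1)), 1)
  expect_equal(coalitionSymbols(matrix(c(0, 1, 0), ncol = 1)), 2)
  expect_equal(coalitionSymbols(matrix(0, 3, 1)), 0)
  expect_equal(coalitionSymbols(cbind(c(0, 0), c(0, 1), c(0, 1), c(1, 1))),
               c(0, 2, 2, 3))
  expect_error(coalitionSymbols(matrix(0L, 63, 2)), "62")
})

test_that("plug-in entropy matches the formula", {
  expect_equal(shannonEntropy(rep(7, 10)), 0)
  expect_equal(shannonEntropy(c(0, 2, 2, 3)), 1.5)
  expect_equal(shannonEntropy(1:16), 4)      # uniform over 2^4 symbols
  set.seed(8)
  for (r in 1:50) {
    s <- sample(0:3, sample(1:8, 1), replace = TRUE)
    expect_equal(shannonEntropy(s), entropyOracle(s))
  }
})

test_that("LZc scores ~1 for random input and ~0 for duplicated input", {
  b <- randomBinaryMatrix(25, 2500, seed = 21)
  expect_lt(abs(scoreValue(lzComplexity(b, seed = 1)) - 1), 0.02)
  dup <- duplicatedChannelMatrix(25, 2500, 24, seed = 21)
  expect_lt(scoreValue(lzComplexity(dup, seed = 1)), 0.2)
})

test_that("short sequences are flagged", {
  expect_warning(sc <- lzComplexity(randomBinaryMatrix(3, 20, seed = 1)),
                 "100")
  expect_true("short-input" %in% sc@flags)
})

test_that("ACE decreases monotonically with duplicated channels", {
  vals <- vapply(c(0, 6, 12, 18, 24), function(k)
    scoreValue(amplitudeCoalitionEntropy(
      duplicatedChannelMatrix(25, 2500, k, seed = 31), seed = 1)),
    numeric(1))
  expect_lt(abs(vals[1] - 1), 0.02)
  expect_true(all(diff(vals) < 0.01))
  expect_lt(vals[5], 0.1)
})

test_that("a constant matrix yields a flagged zero ACE", {
  cm <- BinaryMatrix(matrix(1L, 4, 50))
  sc <- amplitudeCoalitionEntropy(cm, seed = 2)
  expect_equal(scoreValue(sc), 0)
  expect_true("zero-normalizer" %in% sc@flags)
})

test_that("within-channel ACE shuffle preserves row densities", {
  b <- randomBinaryMatrix(6, 400, p = 0.2, seed = 5)
  sc <- amplitudeCoalitionEntropy(b, seed = 3, shuffle = "within-channel")
  expect_gt(scoreValue(sc), 0.5)
})

test_that("LZc and ACE are channel-order invariant up to shuffle noise; SCE exactly", {
  b <- randomBinaryMatrix(10, 800, seed = 6)
  perm <- bits(b)[c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6), ]
  expect_lt(abs(scoreValue(lzComplexity(b, 1)) -
                  scoreValue(lzComplexity(BinaryMatrix(perm), 1))), 0.03)
  expect_lt(abs(scoreValue(amplitudeCoalitionEntropy(b, 1)) -
                  scoreValue(amplitudeCoalitionEntropy(BinaryMatrix(perm),
                                                       1))), 0.03)
  expect_equal(scoreValue(synchronyCoalitionEntropy(b, seed = 2)),
               scoreValue(synchronyCoalitionEntropy(BinaryMatrix(perm),
                                                    seed = 2)))
})

test_that("SCE is zero for identical channels", {
  fs <- 100; tt <- (0:499) / fs
  x <- sin(2 * pi * 7 * tt) * (1 + 0.3 * sin(2 * pi * 0.5 * tt))
  seg <- Segment(rbind(x, x, x), fs = fs)
  sc <- synchronyCoalitionEntropy(analytic(seg), seed = 4)
  expect_equal(scoreValue(sc), 0)
})

test_that("SCE of a hand-built 4-state coalition cycle is 2/N bits", {
  # ref channel 1: ch2 alternates sync every sample, ch3 every 2 samples,
  # so the coalition columns cycle uniformly through 4 states
  T <- 400
  ph <- rbind(rep(0, T),
              rep(c(0, pi), T / 2),
              rep(c(0, 0, pi, pi), T / 4))
  a <- phaseSegment(ph)
  H1 <- shannonEntropy(coalitionSymbols(synchronyCoalitions(a, 1L)))
  expect_equal(H1, 2)
  sc <- synchronyCoalitionEntropy(a, seed = 11)
  N <- sc@normalizer
  # oracle: mean over reference channels of column entropies, over N
  Hs <- vapply(1:3, function(i)
    entropyOracle(apply(bits(synchronyCoalitions(a, i)), 2, paste,
                        collapse = "")), numeric(1))
  expect_equal(scoreValue(sc), mean(Hs) / N)
})

test_that("SCE of temporally shuffled signals stays below 1", {
  set.seed(12)
  seg <- syntheticEEG(n = 10, durationSec = 4, fs = 250, seed = 3)
  shuf <- Segment(t(apply(sigData(seg), 1, sample)),
                  fs = 250, labels = channelLabels(seg))
  sc <- synchronyCoalitionEntropy(analytic(shuf), seed = 5)
  expect_lt(scoreValue(sc), 0.995)
})

test_that("phase synchrony mean matches its analytic value", {
  T <- 50
  a <- phaseSegment(rbind(rep(0.3, T), rep(0.3, T)))
  expect_equal(phaseSync(a), 1)
  anti <- phaseSegment(rbind(rep(0, T), rep(pi, T)))
  expect_equal(phaseSync(anti), 0)
  # independent uniform phases: P(|wrapped diff| < 0.8) = 2*0.8/(2*pi)
  set.seed(23)
  ph <- matrix(runif(20 * 4000, -pi, pi), 20)
  expect_equal(phaseSync(phaseSegment(ph)), 2 * 0.8 / (2 * pi),
               tolerance = 0.02)
})

test_that("sumCov measures mean absolute pairwise correlation", {
  x <- rnorm(100)
  same <- Segment(rbind(x, x + 0, x * 2), fs = 10)
  expect_equal(sumCov(same), 1)
  anti <- Segment(rbind(x, -x), fs = 10)
  expect_equal(sumCov(anti), 1)
  const <- Segment(rbind(x, rep(1, 100)), fs = 10)
  expect_error(sumCov(const), "ch2")
  # independent white noise: E|r| = sqrt(2 / (pi * (T - 1)))
  set.seed(30)
  T <- 2500
  vals <- replicate(20, sumCov(Segment(matrix(rnorm(25 * T), 25), fs = 250)))
  expect_equal(mean(vals), sqrt(2 / (pi * (T - 1))), tolerance = 0.05)
})

test_that("band powers integrate the spectrum into half-open bands", {
  fs <- 250; tt <- (0:2499) / fs
  alpha <- Segment(rbind(sin(2 * pi * 10 * tt), sin(2 * pi * 10 * tt)),
                   fs = fs)
  bp <- bandPowers(alpha)
  expect_gt(bp["alpha"], 0.99)
  delta <- Segment(rbind(sin(2 * pi * 2 * tt), sin(2 * pi * 2 * tt)),
                   fs = fs)
  expect_gt(bandPowers(delta)["delta"], 0.99)
  two <- Segment(rbind(sin(2 * pi * 2 * tt) + sin(2 * pi * 20 * tt),
                       sin(2 * pi * 2 * tt) + sin(2 * pi * 20 * tt)),
                 fs = fs)
  bp2 <- bandPowers(two)
  expect_equal(unname(bp2["delta"]), 0.5, tolerance = 0.01)
  expect_equal(unname(bp2["beta"]), 0.5, tolerance = 0.01)
  # boundary lines go to the upper band: 13 Hz is beta, 4 Hz is theta
  b13 <- bandPowers(Segment(rbind(sin(2 * pi * 13 * tt),
                                  sin(2 * pi * 13 * tt)), fs = fs))
  expect_gt(b13["beta"], 0.99)
  b4 <- bandPowers(Segment(rbind(sin(2 * pi * 4 * tt),
                                 sin(2 * pi * 4 * tt)), fs = fs))
  expect_gt(b4["theta"], 0.99)
  expect_error(bandPowers(Segment(matrix(rnorm(200), 2), fs = 100)), "140")
})

test_that("the measure panel bundles all nine measures consistently", {
  seg <- syntheticEEG(n = 8, durationSec = 4, fs = 250, seed = 2)
  p <- measurePanel(seg, seed = 5)
  sc <- panelScores(p)
  expect_named(sc, c("LZc", "ACE", "SCE", "PhaseSync", "sumCov",
                     "delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(sum(sc[6:10]), 1, tolerance = 1e-9)
  expect_true(all(sc >= 0))
  # deterministic given the seed
  p2 <- measurePanel(seg, seed = 5)
  expect_equal(panelScores(p2), sc)
  expect_equal(p@lzc@seed, p2@lzc@seed)
})

test_that("surrogate-normalized measures keep the broadband > slow-wave ordering", {
  aw <- syntheticEEG(n = 8, durationSec = 4, fs = 250,
                     state = "awake_like", seed = 41)
  an <- syntheticEEG(n = 8, durationSec = 4, fs = 250,
                     state = "anaesthesia_like", seed = 41)
  val <- function(seg) scoreValue(lzComplexity(binarize(analytic(seg)), 1))
  raw <- c(val(aw), val(an))
  surr <- c(val(aw) / val(phaseRandomize(aw, 3)),
            val(an) / val(phaseRandomize(an, 3)))
  expect_gt(raw[1], raw[2])
  expect_gt(surr[1], surr[2])
})
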