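test_that("analytic signal recovers amplitude and phase of a sinusoid", {
  fs <- 250; T <- 2500
  tt <- (seq_len(T) - 1) / fs
  x <- cos(2 * pi * 10 * tt)
  seg <- Segment(rbind(x, x + 0), fs = fs)
  a <- analytic(seg)
  mid <- 100:(T - 100)
  expect_true(all(abs(hilbertAmplitude(a)[1, mid] - 1) < 0.01))
  # phase advances by 2*pi*f/fs per sample away from the edges
  dphi <- diff(hilbertPhase(a)[1, mid])
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_equal(mean(dphi), 2 * pi * 10 / fs, tolerance = 1e-3)
  # amplitude scales linearly, phase is amplitude-invariant
  segA <- Segment(rbind(3.7 * x, x), fs = fs)
  aA <- analytic(segA)
  expect_true(all(abs(hilbertAmplitude(aA)[1, mid] - 3.7) < 0.05))
  expect_equal(hilbertPhase(aA)[1, mid], hilbertPhase(a)[1, mid],
               tolerance = 1e-6)
})

test_that("analytic signal of the zero signal is zero", {
  seg <- Segment(rbind(numeric(64), rnorm(64)), fs = 32)
  a <- analytic(seg)
  expect_true(all(hilbertAmplitude(a)[1, ] < 1e-12))
})

test_that("non-finite input is rejected with the channel named", {
  d <- matrix(rnorm(40), 2)
  d[2, 5] <- NaN
  expect_error(Segment(d, fs = 10, labels = c("good", "bad")), "bad")
})

test_that("edgeDiscard trims both ends", {
  seg <- Segment(matrix(rnorm(200), 2), fs = 10)
  a <- analytic(seg, edgeDiscard = 10L)
  expect_equal(ncol(hilbertAmplitude(a)), 80L)
})

test_that("binarization thresholds at the channel mean, strictly", {
  b <- binarize(matrix(c(1, 3, 1, 3), nrow = 1))
  expect_equal(as.vector(bits(b)), c(0L, 1L, 0L, 1L))
  expect_equal(b@thresholds, 2)
  # constant channel: ties go to 0, so it is all-inactive
  bc <- binarize(rbind(rep(2, 6), c(1, 3, 1, 3, 1, 3)))
  expect_true(all(bits(bc)[1, ] == 0L))
})

test_that("each channel's bits depend only on that channel", {
  set.seed(41)
  amp <- matrix(rexp(6 * 50), 6)
  full <- bits(binarize(amp))
  for (i in 1:6) {
    other <- amp
    other[-i, ] <- rexp(5 * 50) * 10   # rescale all other channels
    expect_equal(bits(binarize(other))[i, ], full[i, ])
  }
})

test_that("binarization is idempotent on non-constant 0/1 rows", {
  set.seed(7)
  b <- randomBinaryMatrix(5, 40, seed = 7)
  expect_equal(bits(binarize(b)), bits(b))
})

test_that("synchrony coalitions follow the strict 0.8 rad rule", {
  T <- 20
  ph <- rbind(rep(0, T), rep(0, T), rep(pi, T), rep(0.8, T))
  a <- phaseSegment(ph)
  psi <- bits(synchronyCoalitions(a, 1L))
  expect_true(all(psi[1, ] == 1L))  # self row
  expect_true(all(psi[2, ] == 1L))  # identical channel
  expect_true(all(psi[3, ] == 0L))  # antiphase
  expect_true(all(psi[4, ] == 0L))  # exactly at threshold: strictly less
})

test_that("synchrony is symmetric across reference channels", {
  set.seed(13)
  ph <- matrix(runif(5 * 30, -pi, pi), 5)
  a <- phaseSegment(ph)
  psis <- lapply(1:5, function(i) bits(synchronyCoalitions(a, i)))
  for (i in 1:5) for (j in 1:5)
    expect_equal(psis[[i]][j, ], psis[[j]][i, ])
})

test_that("wrapping handles differences beyond pi", {
  # phases 3 and -3: raw difference 6, wrapped |difference| = 2*pi - 6 < 0.8
  a <- phaseSegment(rbind(rep(3, 4), rep(-3, 4)))
  expect_true(all(bits(synchronyCoalitions(a, 1L))[2, ] == 1L))
  expect_error(synchronyCoalitions(a, 7L), "channel")
})

test_that("phase randomization preserves the amplitude spectrum exactly", {
  set.seed(5)
  for (T in c(128, 129)) {  # even and odd lengths
    seg <- Segment(matrix(rnorm(3 * T), 3), fs = 50)
    sur <- phaseRandomize(seg, seed = 9)
    for (i in 1:3) {
      m0 <- Mod(fft(sigData(seg)[i, ]))
      m1 <- Mod(fft(sigData(sur)[i, ]))
      expect_lt(max(abs(m1 - m0)) / max(m0), 1e-8)
    }
    v0 <- apply(sigData(seg), 1, var)
    v1 <- apply(sigData(sur), 1, var)
    expect_true(all(abs(v1 - v0) / v0 < 1e-6))
  }
})

test_that("different surrogate seeds give different samples", {
  seg <- Segment(matrix(rnorm(2 * 64), 2), fs = 32)
  s1 <- phaseRandomize(seg, seed = 1)
  s2 <- phaseRandomize(seg, seed = 2)
  expect_false(isTRUE(all.equal(sigData(s1), sigData(s2))))
})

test_that("surrogates of white noise stay white", {
  # lag-1 autocorrelation of surrogate matches the input's on average
  set.seed(99)
  ac <- replicate(120, {
    seg <- Segment(matrix(rnorm(2 * 200), 2), fs = 100)
    sur <- phaseRandomize(seg, seed = sample.int(1e6, 1))
    c(acf(sigData(seg)[1, ], 1, plot = FALSE)$acf[2],
      acf(sigData(sur)[1, ], 1, plot = FALSE)$acf[2])
  })
  expect_lt(abs(mean(ac[2, ]) - mean(ac[1, ])), 3 / sqrt(120 * 200) * 3)
})

test_that("preprocessing stages behave as designed", {
  fs <- 250; T <- 2500
  tt <- (seq_len(T) - 1) / fs
  rms <- function(x) sqrt(mean(x^2))
  # notch on a recording-length sinusoid (filters are applied before
  # segmenting, so the zero-phase edge transient is a negligible share)
  tl <- (seq_len(60 * fs) - 1) / fs
  mains <- sin(2 * pi * 50 * tl)
  out <- preprocessSegment(Segment(rbind(mains, mains), fs = fs),
                           notch = 50)
  expect_lt(rms(sigData(out)[1, ]), 0.05 * rms(mains))

  # detrend removes slope and mean
  lin <- Segment(rbind(0.5 * tt + 3, -2 * tt + 1), fs = fs)
  dt <- sigData(preprocessSegment(lin, detrend = TRUE))
  expect_lt(abs(coef(lm(dt[1, ] ~ tt))[2]), 1e-10)
  expect_lt(abs(mean(dt[1, ])), 1e-10)

  # alpha band-pass keeps a 10 Hz line within 1 dB of unity
  alpha10 <- sin(2 * pi * 10 * tt)
  bp <- preprocessSegment(Segment(rbind(alpha10, alpha10), fs = fs),
                          band = c(8, 13))
  mid <- 250:2250
  gain <- rms(sigData(bp)[1, mid]) / rms(alpha10[mid])
  expect_lt(abs(20 * log10(gain)), 1)

  # all stages disabled: identity
  set.seed(55)
  seg <- Segment(matrix(rnorm(2 * T), 2), fs = fs)
  idn <- preprocessSegment(seg)
  expect_identical(sigData(idn), sigData(seg))

  # decimation: integer factor enforced, fs updated, length divided
  dec <- preprocessSegment(seg, decimateTo = 125)
  expect_equal(sampleRate(dec), 125)
  expect_equal(ncol(sigData(dec)), T / 2)
  expect_error(preprocessSegment(seg, decimateTo = 100), "integer")
  expect_error(preprocessSegment(seg, band = c(8, 200)), "edge")
})

test_that("surface Laplacian removes common signal and keeps local", {
  layout <- ElectrodeLayout(paste0("e", 1:4),
                            cbind(c(0, 1, 2, 3), 0, 0))
  x <- rnorm(50)
  common <- Segment(rbind(x, x, x, x), fs = 10,
                    labels = paste0("e", 1:4))
  out <- surfaceLaplacian(common, layout, k = 2)
  expect_true(all(abs(sigData(out)) < 1e-12))

  # one active channel among silent neighbours (3 electrodes, k = 2):
  # active channel unchanged; neighbours get -w * x with w from 1/distance
  lay3 <- ElectrodeLayout(c("a", "b", "c"), cbind(c(0, 1, 3), 0, 0))
  seg3 <- Segment(rbind(x, numeric(50), numeric(50)), fs = 10,
                  labels = c("a", "b", "c"))
  out3 <- surfaceLaplacian(seg3, lay3, k = 2)
  expect_equal(sigData(out3)[1, ], x)
  # b: neighbours a (d=1) and c (d=2): w_a = 2/3
  expect_equal(sigData(out3)[2, ], -2 / 3 * x)
  # c: neighbours b (d=2) and a (d=3): w_a = 2/5
  expect_equal(sigData(out3)[3, ], -2 / 5 * x)

  # invariance to adding a common constant
  shifted <- Segment(sigData(seg3) + 5, fs = 10, labels = c("a", "b", "c"))
  expect_equal(sigData(surfaceLaplacian(shifted, lay3, k = 2)),
               sigData(out3))

  dup <- ElectrodeLayout(c("a", "b", "c"), cbind(c(0, 0, 3), 0, 0))
  expect_error(surfaceLaplacian(seg3, dup, k = 1), "duplicate")
})
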