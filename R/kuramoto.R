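## Modular Kuramoto oscillator simulator: 8 fully intra-connected
## communities of 32 phase oscillators with sparse random inter-community
## coupling and a tunable inter-community phase lag.

#' Build a modular Kuramoto network
#'
#' Constructs the coupling and phase-lag matrices of a modular oscillator
#' network: each oscillator is completely connected within its own
#' community (coupling 0.6, phase-lag parameter beta fixed at 0.15) and
#' receives `nInter` incoming connections from uniformly sampled
#' oscillators of other communities (coupling 0.4, phase-lag parameter
#' `betaExt`). The lag matrix is alpha = pi/2 - beta on every edge. With
#' the defaults each oscillator has exactly 31 + 32 = 63 connections.
#'
#' @param betaExt inter-community phase-lag parameter, in \\[0, pi/2\\].
#'   Larger beta means smaller lag and more inter-community synchrony.
#' @param seed seed for sampling the inter-community edges
#' @param nCommunities,communitySize network shape (defaults 8 x 32)
#' @param nInter incoming inter-community connections per oscillator
#' @param kIntra,kInter coupling strengths (defaults 0.6 and 0.4)
#' @param betaIntra intra-community phase-lag parameter (default 0.15)
#' @return a [KuramotoNetwork-class]
#' @export
buildKuramotoNetwork <- function(betaExt = 0.15, seed = 1L,
                                 nCommunities = 8L, communitySize = 32L,
                                 nInter = 32L, kIntra = 0.6, kInter = 0.4,
                                 betaIntra = 0.15) {
  if (betaExt < 0 || betaExt > pi / 2)
    stop("betaExt must lie in [0, pi/2]")
  n <- nCommunities * communitySize
  comm <- rep(seq_len(nCommunities), each = communitySize)
  K <- matrix(0, n, n)
  beta <- matrix(0, n, n)
  for (c_ in seq_len(nCommunities)) {
    m <- which(comm == c_)
    K[m, m] <- kIntra
    beta[m, m] <- betaIntra
  }
  diag(K) <- 0
  withSeed(seed, {
    for (i in seq_len(n)) {
      others <- which(comm != comm[i])
      tgt <- sample(others, nInter)
      K[i, tgt] <- kInter
      beta[i, tgt] <- betaExt
    }
  })
  alpha <- pi / 2 - beta
  alpha[K == 0] <- 0
  new("KuramotoNetwork", K = K, alpha = alpha, communities = comm,
      nConn = as.integer(communitySize - 1L + nInter),
      betaExt = betaExt)
}

#' Simulate a Kuramoto network
#'
#' Euler integration of the phase dynamics
#' `dtheta_i/dt = 1 + (1/(N+1)) * sum_j K_ij sin(theta_j - theta_i -
#' alpha_ij)` (all natural frequencies 1), from i.i.d. uniform initial
#' phases on \\[0, 2pi). The coupling sum is evaluated as the imaginary
#' part of `e^{-i theta_i} (K e^{-i alpha}) e^{i theta}`, which is
#' algebraically identical to the pairwise sum. Phases accumulate
#' unwrapped during integration and are stored wrapped into (-pi, pi];
#' column t of the result is the state after t Euler steps.
#'
#' @param network a [KuramotoNetwork-class]
#' @param dt Euler step (default 0.05)
#' @param nSteps number of generated steps (default 1500)
#' @param nDiscard initial steps discarded by downstream analyses
#'   (default 500)
#' @param seed seed for the initial phases
#' @param theta0 optional explicit initial phases (overrides `seed`)
#' @return a [KuramotoRun-class]
#' @export
simulateKuramoto <- function(network, dt = 0.05, nSteps = 1500L,
                             nDiscard = 500L, seed = 1L, theta0 = NULL) {
  stopifnot(is(network, "KuramotoNetwork"))
  n <- nrow(network@K)
  M <- network@K * exp(-1i * network@alpha)
  Mr <- Re(M); Mi <- Im(M)
  th <- if (is.null(theta0)) withSeed(seed, stats::runif(n, 0, 2 * pi))
  else { stopifnot(length(theta0) == n); as.numeric(theta0) }
  theta <- matrix(0, n, nSteps)
  scale <- dt / (network@nConn + 1)
  for (t in seq_len(nSteps)) {
    ct <- cos(th); st <- sin(th)
    zr <- Mr %*% ct - Mi %*% st
    zi <- Mr %*% st + Mi %*% ct
    th <- th + dt + scale * (ct * zi - st * zr)
    theta[, t] <- th
  }
  new("KuramotoRun", theta = wrapPhase(theta), dt = dt,
      nSteps = as.integer(nSteps), nDiscard = as.integer(nDiscard),
      seed = as.integer(seed))
}

#' Community mean-field signals
#'
#' One real time series per community: the real part of the mean unit
#' phasor over the community's oscillators, computed on the post-discard
#' steps only. The result behaves as a [Segment-class] with nominal
#' sampling rate 1/dt.
#'
#' @param run a [KuramotoRun-class]
#' @param network the [KuramotoNetwork-class] that produced it
#' @return a [CommunitySignals-class]
#' @export
communitySignals <- function(run, network) {
  stopifnot(is(run, "KuramotoRun"), is(network, "KuramotoNetwork"))
  keep <- (run@nDiscard + 1L):run@nSteps
  z <- exp(1i * run@theta[, keep, drop = FALSE])
  comms <- sort(unique(network@communities))
  X <- t(vapply(comms, function(c_)
    Re(colMeans(z[network@communities == c_, , drop = FALSE])),
    numeric(length(keep))))
  new("CommunitySignals", data = X, fs = 1 / run@dt,
      labels = paste0("C", comms))
}

#' Sweep the inter-community phase lag
#'
#' For each value of `betaExt`, builds and simulates the network
#' `nRuns` times (fresh seeded edges and initial phases per run), extracts
#' the community signals, and computes LZc, ACE, SCE and PhaseSync on them
#' (communities treated as channels). Returns per-beta means and standard
#' errors.
#'
#' @param betaValues grid of betaExt values
#' @param nRuns independent runs per grid point
#' @param seed base seed; all run seeds derive from it
#' @param ... passed to [buildKuramotoNetwork()]
#' @param dt,nSteps,nDiscard passed to [simulateKuramoto()]
#' @return a data.frame with columns betaExt, lzc, ace, sce, phaseSync and
#'   their standard errors (`*SE`)
#' @export
betaSweep <- function(betaValues = seq(0, 0.6, by = 0.05), nRuns = 10L,
                      seed = 1L, dt = 0.05, nSteps = 1500L,
                      nDiscard = 500L, ...) {
  seeds <- matrix(deriveSeeds(seed, 2L * nRuns * length(betaValues)),
                  ncol = 2L)
  res <- lapply(seq_along(betaValues), function(bi) {
    vals <- vapply(seq_len(nRuns), function(r) {
      row <- (bi - 1L) * nRuns + r
      net <- buildKuramotoNetwork(betaExt = betaValues[bi],
                                  seed = seeds[row, 1L], ...)
      run <- simulateKuramoto(net, dt = dt, nSteps = nSteps,
                              nDiscard = nDiscard, seed = seeds[row, 2L])
      xc <- communitySignals(run, net)
      p <- measurePanel(xc, seed = seeds[row, 1L], bands = FALSE)
      c(lzc = p@lzc@normalized, ace = p@ace@normalized,
        sce = p@sce@normalized, phaseSync = p@phaseSync)
    }, numeric(4))
    m <- rowMeans(vals)
    se <- apply(vals, 1L, stats::sd) / sqrt(nRuns)
    data.frame(betaExt = betaValues[bi],
               lzc = m["lzc"], ace = m["ace"], sce = m["sce"],
               phaseSync = m["phaseSync"],
               lzcSE = se["lzc"], aceSE = se["ace"], sceSE = se["sce"],
               phaseSyncSE = se["phaseSync"], row.names = NULL)
  })
  do.call(rbind, res)
}
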