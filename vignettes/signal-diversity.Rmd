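---
title: "Signal-diversity measures for multichannel recordings: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-diversity measures for multichannel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SignalDiversity)
```

# The measures

This package quantifies the *diversity* of multichannel time series —
typically spontaneous EEG — with three related scores. All three operate
on binary matrices derived from the signal and are normalized so that a
maximally random input scores about 1 and a perfectly regular one tends
to 0.

**LZc (Lempel–Ziv complexity).** Each channel is reduced to a 0/1
activation series by thresholding its instantaneous Hilbert amplitude at
that channel's own temporal mean (strictly greater than the mean counts
as active). The binary matrix is concatenated observation by observation
— all channels at $t_1$, then all channels at $t_2$, … — into one
sequence $s$, and the number of words $c(s)$ in the exhaustive-history
Lempel–Ziv parsing is counted: each new word is the shortest extension of
the longest prefix of the remainder that has already occurred at an
earlier starting position. The score is

$$\mathrm{LZc} = \frac{c(s)}{c(\mathrm{shuffle}(s))},$$

the denominator being the word count of the same sequence randomly
permuted — the attainable maximum for these symbol counts and length. A
single seeded shuffle is used; see *Numerical choices* for why.

**ACE (amplitude coalition entropy).** The same activation matrix is read
column-wise as a sequence of *coalitions* — the subset of channels active
at each instant, encoded as the integer $\sum_i b_{i,t} 2^{i-1}$ — and
the plug-in Shannon entropy (base 2) of that symbol sequence is divided
by the entropy obtained after randomly permuting the position of every
entry of the matrix. Shuffled-data normalization, rather than the
analytic bound of $n$ bits, matters because a segment of $T$ observations
can sample at most $T$ of the $2^n$ coalitions: both numerator and
denominator are equally undersampled, which is the bias control.

**SCE (synchrony coalition entropy).** For each reference channel $i$, a
coalition matrix $\Psi^{(i)}$ records which channels are phase-locked to
$i$ at each instant: channels $i,j$ count as synchronous when their
instantaneous Hilbert phases differ by less than 0.8 rad (≈45°) in
absolute wrapped value. The entropy over time of $\Psi^{(i)}$'s columns
is normalized by $N$, the column entropy of a random coalition matrix of
identical shape whose entries are independent Bernoulli(0.5); the overall
SCE is the mean over reference channels. Unlike LZc and ACE, SCE does not
reach 1 for temporally shuffled signals: two independent uniform phases
are synchronous with probability $2 \times 0.8 / 2\pi \approx 0.25$, not
0.5.

Three control measures accompany them: **PhaseSync**, the mean pairwise
synchrony indicator over distinct channel pairs and time; **sumCov**, the
mean absolute Pearson correlation over channel pairs; and the five
normalized spectral **band powers** (δ 1–4, θ 4–8, α 8–13, β 13–30, γ
30–70 Hz) summing to 1. `measurePanel()` computes all nine from one
analytic-signal pass.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `phaseThreshold` | 0.8 | rad | synchrony criterion for SCE/PhaseSync |
| binarization threshold | per-channel mean | amplitude | activation criterion (strict `>`) |
| `nShuffles` | 1 | – | shuffles averaged into the LZc normalizer |
| `edgeDiscard` | 0 | samples | trimmed at each end after the Hilbert transform |
| segment length | 10 | s | unit of analysis |
| notch | off (±1 Hz, order 4 when on) | Hz | mains removal |
| Laplacian `k` | 4 | neighbours | spatial high-pass re-referencing |
| `dThreshold` | 0.8 | – | "large effect" cut for per-subject counts |

The strict inequality in the binarization makes a constant channel
all-inactive rather than all-active; since every channel is thresholded
at its own mean, all channels are equally "active" by construction and no
channel's bits depend on any other channel.

# The Kuramoto testbed

To show that SCE captures a different flavour of diversity than LZc/ACE,
the package simulates a modular network of 256 phase oscillators: 8
communities of 32, each oscillator completely coupled within its
community (strength 0.6) and receiving 32 random incoming connections
from other communities (strength 0.4), giving exactly 63 connections per
oscillator. Phases evolve by Euler integration (step 0.05, 1500 steps,
first 500 discarded, natural frequency 1 for all) of

$$\dot\theta_i = 1 + \frac{1}{N+1}\sum_j K_{ij}
  \sin(\theta_j - \theta_i - \alpha_{ij}),$$

with lag $\alpha = \pi/2 - \beta$; $\beta$ is fixed at 0.15 within
communities and swept (`betaSweep()`, grid 0–0.6 by 0.05, bounded by
$\beta \in [0, \pi/2]$) for inter-community edges. One real signal per
community — the real part of its mean unit phasor — is analysed exactly
like an 8-channel recording. Small $\beta_\mathrm{ext}$ (large lag)
yields little inter-community synchrony, large $\beta_\mathrm{ext}$
nearly total synchrony; in between, synchrony patterns fluctuate and SCE
peaks — at $\beta_\mathrm{ext} = 0.15$ with the defaults — while LZc and
ACE, driven by amplitude diversity, show at most a shallow dip there. In
our sweeps that dip is comparable to its standard error at 10 runs per
grid point, so its exact location is noise-sensitive, whereas the SCE
peak and the monotone growth of PhaseSync are robust.

Design notes: the 32 inter-community connections are *incoming* and
directed, keeping the per-oscillator sum over exactly $N = 63$ terms;
whether to symmetrize is not determined by the model description, and we
do not. One $\beta_\mathrm{ext}$ applies to all inter-community edges of
a run. The Euler step is evaluated as
$\mathrm{Im}\!\left(e^{-i\theta_i}\,[K e^{-i\alpha}\, e^{i\theta}]_i\right)$
— four real matrix–vector products — which is algebraically identical to
the pairwise sum. Phases accumulate unwrapped during integration and are
wrapped into $(-\pi, \pi]$ for storage, so the uncoupled network ($K=0$)
reproduces the closed-form drift $\theta_i(t) = \theta_i(0) + t\,dt$ on
the circle to accumulated rounding (about $10^{-11}$ over 1500 steps).

# Channel selection

High-density montages are thinned to $k$ spatially uniform electrodes by
k-medoids clustering of the 3-D electrode coordinates: alternate between
assigning each electrode to its nearest medoid (Euclidean; ties to the
lower index) and recomputing each cluster's medoid as the member with
least mean distance to its co-members, to a fixed point (cap 300
iterations). Because a single random initialization can converge to a
poor local optimum, `nRestarts = 10` seeded starts are run and the
lowest-cost result kept. On a discrete grid the *minimum* pairwise medoid
distance of even the optimal medoid set falls short of the ideal
continuum spacing $\sqrt{\mathrm{area}/k}$ (two medoids can sit on
adjacent grid lines while the partition is still balanced), so spatial
uniformity should be judged — and is tested — by the mean
nearest-neighbour medoid spacing, which stays within 25% of the ideal.
Anatomical lobe restriction uses supplied tags; no geometric lobe
inference is attempted.

# Statistics layer

Within subject, states are compared by Cohen's $d$ across segments
(pooled-SD form), counting subjects with $|d| > 0.8$ per direction.
Across subjects, per-subject mean scores enter a two-sided Wilcoxon
rank-sum test (exact for small tie-free samples, normal approximation
with tie correction otherwise) and the empirical AROC, computed as the
Mann–Whitney probability $P(a > b) + \tfrac12 P(a = b)$ — identical to
the trapezoid area under the threshold-sweep ROC curve, and satisfying
$\mathrm{AROC}(A,B) + \mathrm{AROC}(B,A) = 1$. All p-values of one
`compareStates()` call form a single Benjamini–Hochberg family. Change
correlations (`changeCorrelations()`) correlate per-subject
state-ratio vectors between measure pairs, two-tailed, flagging
$p \le 0.05$; subjects with a zero denominator are excluded with a
warning.

# Synthetic data

All inputs used by the tests are generated in code, seeded:

* `randomBinaryMatrix()` — i.i.d. Bernoulli entries; the "fully random"
  reference scoring ≈1 on LZc/ACE.
* `duplicatedChannelMatrix()` — $k$ rows replaced by copies of row 1,
  with nested duplicate sets across $k$, so sweeping $k$ from 0 to
  $n-1$ traces the monotone decay of all three measures toward 0.
* `sortedSubsequenceMatrix()` — per-channel windows sorted
  zeros-then-ones, an alternative regularity manipulation that preserves
  each row's ones-count.
* `syntheticEEG()` — a two-regime stand-in, **not** a biophysical model:
  the awake-like state superimposes independent band-limited noise in the
  five conventional bands (unit-variance components weighted 1.0, 0.8,
  0.8, 0.6, 0.4 from δ to γ) plus a mild common broadband drive (0.25);
  the anaesthesia-like state is one shared 1–4 Hz oscillation (weight
  3.0) plus weak independent broadband noise (0.3). These weights were
  fixed once, to give the slow-wave state the dominant δ power and strong
  inter-channel coherence seen in deep sedation, and the awake state a
  broadband, weakly coupled profile.

What passing tests on these generators shows — and what it does not: the
generators reproduce the *contracted* properties (spectral ordering,
coherence ordering, and hence the direction of all three measures) with
subject- and segment-level variability coming only from seeds. Real EEG
adds artifacts, non-stationarity, volume conduction, reference effects
and genuine between-subject heterogeneity, none of which are emulated;
separability results on synthetic data therefore demonstrate that the
pipeline measures what it claims to measure, not that real recordings
will separate as cleanly.

# Numerical choices

* **Hilbert transform** via the FFT half-spectrum method on the full
  segment, no taper; `edgeDiscard` (default 0) can trim edge effects.
* **Single-shuffle LZc normalizer**: on EEG-sized inputs
  (25 × 2500) the word count of a shuffled sequence varies across
  shuffles with a coefficient of variation of roughly 0.2% — small enough
  that one seeded shuffle suffices for 3-digit stability; `nShuffles`
  averages several if tighter normalizer stability is wanted.
* **Plug-in entropy, no bias correction** — the shuffled/random-matrix
  normalizers are equally biased, which cancels in the ratio. Log base 2
  throughout; the normalized ratios are base-invariant.
* **Coalition encoding** uses exact powers of two in doubles up to 52
  channels and an equivalent string key for 53–62; more channels are
  rejected rather than risking collisions.
* **Phase wrapping** into $(-\pi, \pi]$ touches only out-of-range values,
  keeping in-range differences bit-exact so the strict 0.8 rad comparison
  is not blurred by modulo rounding. A phase difference of exactly 0.8 is
  *not* synchronous.
* **Degenerate inputs**: constant binary matrices yield a flagged ACE of
  0 (zero normalizer); sequences shorter than 100 symbols warn and flag
  the LZc score; zero-variance channels are rejected by `sumCov` with the
  channel named.
* **Band integration** uses half-open bins $[f_\mathrm{low},
  f_\mathrm{high})$, so a 4 Hz line is θ and a 13 Hz line is β, counted
  once.
* **Filtering order** in `preprocessSegment()`: notch → band/high-pass →
  decimate → detrend → demean, each stage optional; with everything
  disabled the function is the identity. Zero-phase (forward–backward)
  4th-order Butterworth filters are used; on short isolated segments
  their edge transients dominate whole-segment residual power, so filters
  should be applied to recordings before segmentation (as the CLI does).
* **Problem sizes in the shipped checks** were chosen to run on one CPU
  in minutes: 10 repetitions of the 25 × 2500 duplicated-channel sweep,
  10 seeds per point of the 13-point Kuramoto sweep, and 7 simulated
  subjects × 60 ten-second segments per state for the separability
  analysis.

# Known limitations

* The LZc/ACE/SCE normalizations are stochastic; scores carry a
  shuffle-seed dependence of order 0.2% (LZc) that is recorded in every
  `MeasureScore`.
* SCE's random-matrix normalizer assumes a synchrony probability of 0.5,
  which real phase dynamics do not attain; SCE values are therefore
  comparable between conditions but not anchored to 1 for surrogate data.
* The surface Laplacian is a k-nearest-neighbour inverse-distance
  approximation, not a spline Laplacian; with the default $k = 4$ it is a
  local sharpening filter and its output scale differs from spline
  implementations.
* The EDF reader supports the common fixed-rate 16-bit layout only (no
  annotations, no variable rates).
* Visual artifact rejection, channel interpolation and ICA are out of
  scope; inputs are assumed artifact-free.
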