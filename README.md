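# SignalDiversity

Signal-diversity measures for multichannel time series, built for
spontaneous EEG. During deep sedation the brain's electrical activity
becomes slower, more synchronized and more stereotyped; this package
quantifies that loss of diversity with three normalized scores computed
per recording segment, together with the simulation, channel-selection
and statistics machinery needed to validate and apply them.

## The measures

Given a segment **X** (n channels × T observations), each channel is
reduced to a 0/1 *activation* series by thresholding its instantaneous
Hilbert amplitude `a_i(t)` at the channel's own temporal mean `T_i`
(active when `a_i(t) > T_i`, strictly). Three scores are computed:

* **LZc** — concatenate the binary matrix observation by observation into
  one sequence `s` and count the words `c(s)` of its exhaustive-history
  Lempel–Ziv parsing:

      LZc = c(s) / c(shuffle(s))

  The shuffled denominator is the attainable maximum for that symbol
  composition, so a fully random matrix scores ≈1 and duplicated or
  ordered structure pulls the score toward 0.

* **ACE** (amplitude coalition entropy) — encode each n×1 column (the
  *coalition* of active channels) as the integer `Σ b_i 2^(i-1)` and take
  the plug-in Shannon entropy over time, divided by the same entropy
  after randomly permuting every entry of the matrix.

* **SCE** (synchrony coalition entropy) — for each reference channel i,
  build the coalition matrix `Ψ(i)` of channels whose Hilbert phase lies
  within 0.8 rad of channel i's at each instant; SCE is the mean over i
  of the column entropy of `Ψ(i)`, normalized by the column entropy N of
  a same-shape random Bernoulli(0.5) matrix:

      SCE(i) = -(1/N) Σ_ψ p(Ψ(i)=ψ) log2 p(Ψ(i)=ψ)

Control measures: mean pairwise phase synchrony (PhaseSync), mean
absolute channel correlation (sumCov), and normalized spectral band
powers (δ, θ, α, β, γ summing to 1). A modular Kuramoto oscillator
network (8 communities × 32 oscillators, tunable inter-community phase
lag) provides a testbed where SCE demonstrably diverges from LZc/ACE;
k-medoids clustering of electrode coordinates selects spatially uniform
channel subsets; and a statistics layer supplies per-subject Cohen's d,
Wilcoxon rank-sum tests with Benjamini–Hochberg FDR correction, AROC,
and between-measure change correlations.

## Worked example

```r
library(SignalDiversity)

awake <- syntheticEEG(n = 25, durationSec = 10, fs = 250,
                      state = "awake_like", seed = 1)
sedated <- syntheticEEG(n = 25, durationSec = 10, fs = 250,
                        state = "anaesthesia_like", seed = 1)
measurePanel(awake, seed = 7)
#> MeasurePanel
#>   LZc 0.9582  ACE 0.9959  SCE 0.9852
#>   PhaseSync 0.2651  sumCov 0.0527
#>   band power: delta 0.328  theta 0.245  alpha 0.224  beta 0.134  gamma 0.070
measurePanel(sedated, seed = 7)
#> MeasurePanel
#>   LZc 0.1615  ACE 0.2643  SCE 0.1095
#>   PhaseSync 0.9797  sumCov 0.9901
#>   band power: delta 0.919  theta 0.072  alpha 0.001  beta 0.003  gamma 0.005
```

The awake-like segment — independent broadband channels — scores near 1
on all three diversity measures, with low synchrony and a flat spectrum.
The slow-wave segment — one shared 1–4 Hz oscillation — collapses to
LZc 0.16 / ACE 0.26 / SCE 0.11 while synchrony, inter-channel correlation
and δ power saturate. Individual scores expose their parts:

```r
lzComplexity(binarize(analytic(awake)), seed = 7)
#> LZc: normalized 0.9577 (raw 3804 / normalizer 3972, seed 7)
```

A command-line front end is installed as `sigdiv` (see
`exec/sigdiv`), with subcommands `compute`, `kuramoto`, `select`,
`stats` and `fixtures`; every run writes a `.prov` provenance record of
all options and seeds.

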