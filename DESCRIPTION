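Package: SignalDiversity
Title: Complexity and Coalition-Entropy Measures for Multichannel Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Signal-diversity measures for multichannel time series such as
    spontaneous EEG: Lempel-Ziv complexity (LZc) of the concatenated
    binarized observation sequence, amplitude coalition entropy (ACE) and
    synchrony coalition entropy (SCE), with the surrounding machinery needed
    to compute and validate them. Includes Hilbert analytic-signal
    transforms, amplitude binarization, pairwise phase-synchrony coalitions,
    phase-randomized surrogate data, Butterworth filtering and decimation, a
    nearest-neighbour surface Laplacian, spectral band powers, a modular
    Kuramoto oscillator simulator, spatially uniform electrode selection via
    k-medoids clustering, per-subject effect sizes with rank-sum tests, FDR
    correction and ROC analysis, and seeded generators for all synthetic
    inputs used in the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, signal, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, cluster, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'SignalDiversity-package.R'
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'signals.R'
    'complexity.R'
    'kuramoto.R'
    'channels.R'
    'stats.R'
    'fixtures.R'
    'io.R'
    'cli.R'
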