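Package: motorconn
Title: Spectral Power, Functional and Effective Connectivity for Layered
    Motor-Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multichannel neural time series from layered
    premotor and primary motor cortical areas: zero-phase Butterworth and
    notch filtering, common-average re-referencing, epoching and
    anti-aliased downsampling; multitaper (DPSS) power spectra with
    frequency-band aggregation; magnitude-squared coherence with a
    Monte-Carlo block-shuffle surrogate null; time-resolved partial
    directed coherence (TPDC) from sliding-window vector autoregressive
    fits with time-reversal significance testing; spike detection,
    Haar-wavelet feature selection and super-paramagnetic clustering into
    single units; and maximum-likelihood path (mediation) models linking
    directed connectivity, coherence and power to unit activity, with
    RMSEA and AIC fit indices. Includes ground-truth synthetic data
    generators (band-coupled 1/f field potentials, vector autoregressions,
    spiking traces, mediation tables) so every stage is testable end to
    end, plus Bonferroni-corrected group comparisons and a reproducible
    pipeline driver with a hashed manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5,
    yaml,
    optparse
Config/testthat/edition: 3
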