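Package: campdice
Title: Analysis of Stochastic Neuropeptide-Evoked cAMP Transients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying stochastic, spatially localized
    neuropeptide signaling from two-photon fluorescence recordings of
    cAMP biosensors. Provides a synthetic-session generator with
    ground-truth event logs, neuropil-ring and photobleaching
    correction, trial alignment to stimulation onsets, a two-tailed
    auROC hit/miss classifier, a fixed-probability ("dice") model of
    release with bootstrap confidence intervals and permutation tests,
    persistence and amplitude metrics, distance-binned XNOR/F1/Pearson
    similarity curves with bootstrap chance bands, fluorescence-lifetime
    (FLIM) first-moment estimation from photon decay histograms, and
    demultiplexing of interleaved-LED fiber photometry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
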