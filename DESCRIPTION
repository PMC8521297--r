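Package: chronocell
Title: Circadian Single-Cell Signalling Topology and Bioluminescence Rhythm Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two complementary analyses of circadian neural circuits:
    (1) quality control, normalization, clustering and negative-binomial exact-test
    differential expression for droplet scRNA-seq UMI count matrices, followed by
    inference of ligand-receptor signalling network topology between cell clusters
    (outer-product edge weights, min-max scaling, summed connectivity, source-node
    calls, day/night comparison); and (2) analysis of bioluminescence and
    fluorescence reporter time series (moving-average detrending, FFT-initialized
    damped-cosine least-squares fitting, relative-amplitude-error rhythmicity
    classification, Rayleigh phase coherence, ROI phase maps, phase-response
    curves and waveform-change metrics). A synthetic-data module generates count
    matrices and reporter traces with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    minpack.lm,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
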