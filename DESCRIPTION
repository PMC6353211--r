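Package: tfdwell
Title: Single-Molecule Residence Times, Bound Fractions, FRAP Kinetics and
    Target-Gene Activity of Nuclear Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of live-cell single-molecule tracking experiments on
    DNA-binding proteins: trajectory linking with gap closing, extraction of
    chromatin-binding events by spatiotemporal thresholding, survival (1-CDF)
    curves with photobleaching correction against an immobile histone control,
    mono/bi-exponential dwell-time fitting with F-test model selection,
    Rayleigh-mixture fitting of single-step displacement histograms to obtain
    the bound fraction and pseudo-first-order association rate, double
    exponential FRAP recovery fitting with a numerically solved global
    half-time, and downstream classification of transcription-factor variants
    from promoter/peak intersections, fold changes versus a non-transfected
    reference, row-standardized clustering and qPCR normalized relative
    quantities. Ships seeded simulators for trajectories, FRAP curves and
    negative-binomial count matrices so that every stage can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
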