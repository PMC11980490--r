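Package: phytostress
Title: Multi-Modal Phenotyping of Drought-Stressed Pepper Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-modal monitoring of drought stress in
    pepper plants grown in soil amended with biochar. Decomposes visible-light
    plant images into per-channel intensity histograms and computes integral
    area, barycenter, full width at half maximum and a green-dominance
    statistic; summarises thermal infrared canopy rasters (mean, minimum,
    low-temperature fraction); analyses plant electrical-signal time series
    (amplitude statistics, autocorrelation period, one-sided Fourier amplitude
    spectrum and sub-5 Hz characteristic frequency); and quantifies
    differential pulse voltammetry fingerprints (baseline correction, peak
    detection, peak resolution and overlap). A calibrated synthetic-acquisition
    generator emulates the full treatment-by-day study grid so every stage of
    the pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
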