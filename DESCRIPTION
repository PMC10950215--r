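Package: reefscan
Title: Simulated Underwater Hyperspectral Surveys and Benthic Community
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for benthic reef monitoring built around
    simulated underwater hyperspectral transect scans with known ground
    truth.  Generates patchy reef label maps and push-broom radiance
    cubes (grey reference plate, two-way water attenuation, sensor
    noise), preprocesses spectra (Savitzky-Golay smoothing, low-signal
    band removal, plate normalization, per-spectrum standardization),
    classifies every pixel with a spectral-spatial residual network
    trained on polygon regions of interest, estimates percent cover both
    from classified maps and from photoquadrat point-intercept sampling,
    and compares surveys with community statistics: Shannon diversity
    and equitability, one-way ANOVA with Tukey HSD letters, Bray-Curtis
    dissimilarity, ANOSIM and non-metric multidimensional scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    vegan
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
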