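Package: enose
Title: Gas Sensor Array Pattern Recognition with a Hybrid Genetic-Neural Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for electronic-nose (e-nose) odor classification from
    multichannel metal-oxide gas sensor recordings. Provides a synthetic
    sensor-array simulator (saturating responses, drift, noise), smoothed
    moving-average preprocessing and saturation normalization, windowed
    gradient feature extraction, a real-coded genetic algorithm with an
    oscillatory fitness function and elitist selection, a from-scratch
    backpropagation-with-momentum neural network, an odor-fingerprint
    database with a 6-of-8 channel matching rule, and PCA diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
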