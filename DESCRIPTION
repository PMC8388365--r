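Package: broilersound
Title: Multi-Perspective Evaluation of Denoising Methods for Broiler Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Benchmarks classical audio denoising methods on poultry-house
    soundscapes from two angles: waveform fidelity (signal-to-noise ratio and
    root-mean-square error against a known clean reference) and downstream
    recognition (accuracy of k-nearest-neighbour and random-forest classifiers
    trained on 39-dimensional MFCC features of the four broiler call classes:
    crow, cough, purr and wing flap). Implements basic spectral subtraction,
    improved spectral subtraction based on multi-taper (Slepian) spectrum
    estimation, decision-directed Wiener filtering, and sparse decomposition
    over a discretized Gabor dictionary via genetic-algorithm-assisted
    orthogonal matching pursuit with a fixed atom budget. A seeded synthetic
    soundscape generator provides clean references, event annotations and
    controlled stationary plus impulsive noise at a target SNR.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    jsonlite,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
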