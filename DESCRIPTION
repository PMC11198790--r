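Package: baoscnn
Title: Boosted Atomic Orbital Search for CNN Hyperparameter Neuroevolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the Boosted Atomic Orbital Search (BAOS) metaheuristic,
    an Atomic Orbital Search variant augmented with Levy-flight photon-rate
    updates and stagnation restarts, together with a deep-neuroevolution
    pipeline that searches a nine-dimensional mixed continuous/discrete
    convolutional-network hyperparameter space using stratified k-fold
    cross-validated accuracy as fitness. Includes analytic benchmark
    objectives, a synthetic generator for patch-based habitat morphotype
    images (strap-like leaves, oval leaves, branched stems, background
    texture), grid slicing and colour-overlay utilities, classification
    metrics, and a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
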