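Package: sustaind
Title: Population-Level Concept Learning with Neural Flocking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates SUSTAIN-d, a population-level decomposition of the
    SUSTAIN category-learning model in which thousands of neuron-like units
    coordinate through a "neural flocking" learning rule (a Kohonen move
    toward the stimulus followed by a recurrent contraction toward the
    winners' centroid) to form virtual clusters. Includes the six
    Shepard-Hovland-Jenkins category-learning problems with supervised
    trial-and-error training, attention and connection-weight learning,
    unit recruitment, unsupervised spatial foraging simulations with
    occupancy-normalised activation maps, spatial autocorrelograms and
    expanding-annulus grid scores, noise and lesion robustness experiments,
    an anterior/posterior dual-bank hippocampus model, and grid-search
    parameter fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
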