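Package: wingrda
Title: Phylogenetic Redundancy Analysis of Flight-Feather Attachment Osteology
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links categorical skeletal characters of flight-feather
    attachment to wing aspect ratio and body mass with phylogenetic
    comparative methods: principal coordinates of Hamming distances with
    Cailliez correction, joint maximum-likelihood estimation of Pagel's
    lambda, phylogenetic centering and whitening by the inverse square
    root of the scaled covariance, redundancy analysis and variation
    partitioning with permutation tests across a tree ensemble, passive
    placement of extinct taxa, and simulation-based phylogenetic ANOVA
    with Holm adjustment.  Ships the study character/trait tables as a
    fixture and a synthetic-data generator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
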