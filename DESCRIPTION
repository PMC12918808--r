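Package: frepscreen
Title: Scoring and Simulation for Pooled Fractionation Reporter Screens of mRNA Condensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled CRISPRi fractionation screens that
    measure reporter-mRNA partitioning into condensate-enriched pellet
    fractions. Implements barcode counting from reads with Hamming-distance
    matching, neighborhood-normalized z-scores (NNS) for pellet-versus-total
    log-ratios, gene-level FRep scores with replicate combination by
    one-sample t-tests, classification of heat-shock time-course score
    trajectories into responder groups, length-bin normalized condensation
    and ribosome-association scoring for fractionated RNA-seq, a qPCR
    delta-delta-Ct condensation calculator, and a negative-binomial
    synthetic-data generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
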