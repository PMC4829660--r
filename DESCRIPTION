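Package: repliconscope
Title: Quantification of DNA Replication Foci, Replicon Parameters and
    Genome Duplication Kinetics
Version: 0.1.0
Authors@R:
    person("Replicon", "Scope Developers", email = "repliconscope@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify nuclear replication foci (RFi) in 3D
    fluorescence image stacks at conventional and super-resolution
    levels, estimate replication fork speed and inter-origin distances
    from stretched (combed) DNA fibre tracks, measure genome size from
    DNA flow-cytometry histograms with an internal diploid reference,
    derive cell-cycle stage durations from time-lapse stage labels, and
    combine these measurements into genome duplication parameters
    (total replicons, replicon lifetime, forks operating in parallel and
    replicons per replication focus) with first-order error propagation.
    A synthetic-data module generates every input modality with known
    ground truth so the whole chain is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
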