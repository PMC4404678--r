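Package: fcstrength
Title: Voxel-Wise Functional Connectivity Strength Mapping with Monte
    Carlo Cluster-Extent Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state functional connectivity strength (FCS) analysis
    of a sensory-motor network: temporal band-pass filtering, spatial
    smoothing and nuisance regression of 4D BOLD images; voxel-wise
    weighted degree centrality over a sweep of correlation thresholds with
    subject-level global-mean normalisation; seed-based resting-state
    functional connectivity networks; covariate-adjusted voxel-wise group
    comparison; from-scratch Monte Carlo cluster-extent correction with a
    millimetre neighbour radius; and partial-correlation association of
    regional connectivity with clinical scores. Includes a synthetic
    two-group BOLD cohort generator with planted connectivity ground truth
    for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
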