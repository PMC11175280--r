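Package: needleplan
Title: Automatic Needle-Path Planning for Percutaneous Liver Tumor Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans straight percutaneous ablation-needle trajectories from
    labeled abdominal CT volumes. Given an integer label map distinguishing
    skin, liver, tumor and risk structures (vessels, bone, lung), the planner
    enumerates candidate paths from skin-surface voxels to the tumor centroid,
    rejects paths violating clinical hard constraints (collision with risk
    structures, needle length, liver-capsule insertion angle), scores the
    survivors on soft constraints (clearance from risk structures, path
    length, capsule angle) by min-max normalized weighted summation on a 0-10
    scale, and alternatively screens them weight-free by pairwise Pareto
    fronts with global intersection and interactive dominator queries. A
    synthetic abdominal phantom generator with analytic ground truth, a JSON
    planning-record store and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
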