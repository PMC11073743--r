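Package: ralandscape
Title: Energy Landscape Analysis and Trajectory Clustering of Rheumatoid
    Arthritis Disease-Activity States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse multistability of rheumatoid-arthritis patient
    states under treat-to-target drug treatment. Seven routinely collected
    disease-activity factors are binarized to remission/nonremission spins on a
    fixed 12-visit grid, a pairwise maximum-entropy (Boltzmann machine) model is
    fitted by exact-enumeration gradient ascent, and the fitted energy landscape
    is characterised: per-state energies, steepest-descent dynamics, local
    minima and their basins, minimax energy barriers, the disconnectivity tree,
    the inter-pattern transition threshold, and quadrant summaries of a cohort.
    Patient trajectories (spins, energy, HAQ) are clustered with k-means under
    dynamic time warping, with elbow and silhouette diagnostics. A synthetic
    cohort generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
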