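Package: epiredox
Title: Optical Redox Imaging and Cell-Competition Quantification for Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for intravital two-photon optical redox
    imaging of the epidermal basal stem-cell layer. Detects the dermo-epidermal
    interface from second-harmonic collagen signal, isolates tissue layers by
    anisotropic 3D Euclidean distance banding, computes per-pixel and per-cell
    NAD(P)H/FAD redox ratios with baseline and neighbour normalization, derives
    tissue-level cell-competition metrics (mutant coverage, epidermal thickness,
    nuclear density, proliferation counts), evaluates the 13C6-glucose
    isotopologue flux-ratio panel (including the pyruvate-dehydrogenase to
    citrate-synthase flux ratio), and applies hierarchical per-animal statistics.
    A synthetic-tissue generator with exact ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    class,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
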