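Package: molconn
Title: Molecular Connectivity from Dynamic Reference-Tissue PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Subject-level molecular connectomes from framewise DVR-1
    binding-potential time series of dynamic reference-tissue PET,
    alongside hemodynamic functional connectivity from BOLD fMRI.
    Provides regional time-series extraction against an integer-labelled
    atlas, framewise binding potentials under a bolus-plus-constant-
    infusion equilibrium, piecewise-linear detrending, Fisher-z
    correlation connectomes with familywise-error edge statistics,
    small-world graph metrics with degree-preserving null models,
    spatial group independent component analysis, pharmacological-
    challenge effect maps, and a synthetic simultaneous PET/BOLD cohort
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
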