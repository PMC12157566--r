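Package: spineprint
Title: Functional Connectivity Fingerprinting for the Brain and Spinal Cord
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for functional connectome fingerprinting of parcelled fMRI
    time series, with first-class support for cervical spinal cord
    parcellations alongside conventional brain atlases. Implements
    physiological (RETROICOR-style) nuisance regressor construction, joint
    confound and band-pass denoising by projection onto a shared orthogonal
    space, robust (trimmed-mean) parcellation of voxel time series, Pearson
    functional connectivity matrices, the identifiability matrix and its
    summary metrics (Idiff, Cohen's d, top-K identification accuracy),
    differential identifiability via principal-component reconstruction,
    edge-wise ICC(1,1) test-retest reliability maps with percentile
    thresholding and nodal strength, and brain-spine cross-regression
    residual fingerprinting. A synthetic multi-subject cohort generator with
    controllable group, subject-stable and run-specific correlation
    components supports testing and power exploration without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
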