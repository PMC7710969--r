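Package: tdcsfc
Title: Resting-State Connectivity Metrics and tDCS Electric-Field Modelling
    for Motor-Cortex Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pre/post resting-state fMRI connectivity
    around a transcranial direct current stimulation (tDCS) plus motor-training
    intervention. Implements interhemispheric Fisher-z connectivity,
    voxel-wise intrinsic connectivity (root-mean-square correlation, computed
    through a truncated singular value decomposition), integrated local
    correlation with a Gaussian spatial kernel, seed-to-voxel maps, task-fMRI
    peak-voxel seed selection, confound regression with aCompCor noise
    components and discrete-cosine high-pass filtering, paired group
    statistics with sign-flip permutation cluster inference, and a
    tumor-aware piecewise-linear finite-element model of the tDCS electric
    field on labelled head phantoms with an analytic conducting-sphere
    validation oracle. A synthetic-data module generates paired resting
    runs with planted inter-regional correlations, block-design task runs,
    motion traces, and multi-compartment spherical head phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
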