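Package: isfcdecode
Title: Inter-Subject Functional Correlation Analysis and Task-State Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating inter-subject functional correlation (ISFC)
    from multi-subject BOLD-like node time series and for decoding task states
    from connectivity patterns. Implements signal-level cleaning (linear
    detrending, nuisance and derivative regression, discrete-cosine high-pass
    filtering, removal of task-evoked responses via a canonical double-gamma
    haemodynamic response model), ISFC and within-subject functional
    connectivity estimation with Fisher r-to-z transformation and
    symmetrisation, template-matching classification under
    leave-one-subject-out cross-validation, group-split similarity analysis,
    edge-wise discriminative mapping, subnetwork-restricted and scan-length
    analyses, and nonparametric permutation inference with max-statistic
    family-wise error control. Includes a synthetic multi-subject data
    generator with known ground truth for validation, plus readers and writers
    for delimited run matrices, dataset manifests and BrainNet-viewer node and
    edge files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
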