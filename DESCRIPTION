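Package: qpcrstab
Title: Reference-Gene Stability, Amplification Efficiency and
    Normalization for qPCR Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relative-quantification qPCR studies: simulation of
    quantification-cycle (Cq) datasets and raw amplification curves with
    known ground truth; replicate quality control, interplate calibration
    and descriptive statistics; four reference-gene stability methods
    (comparative delta-Ct, BestKeeper, NormFinder-style model-based
    variance decomposition, and stepwise-exclusion M-values in the GeNorm
    tradition); four single-reaction amplification-efficiency estimators
    (window-of-linearity regression, saturation-baseline regression,
    logistic plus exponential fitting, and linear regression of per-cycle
    efficiency); efficiency-corrected normalization of target genes by
    reference-gene combinations; and a stratified-subsampling protocol for
    assessing the robustness of stability rankings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    nortest,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
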