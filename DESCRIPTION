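Package: remmotor
Title: Multimodal Quantification of Motor Activity During REM Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying motor activity during REM sleep from
    synchronized wrist actigraphy, forearm electromyography (EMG), and video
    annotations, aimed at REM sleep behavior disorder (RBD) research. Implements
    an acceleration-magnitude activity-count model (autocalibration to 1 g,
    Euclidean-Norm-Minus-One, 1 s binning, zero-phase high-pass Butterworth
    filtering, zero-rounding, 3 s mini-epoch classification), REM-period
    selection and mini-epoch gridding of 30 s hypnograms, rule-based EMG
    mini-epoch scoring against a per-period atonia baseline, cross-modality
    agreement statistics (Cohen's kappa, directional conditional probabilities,
    Mantel-Haenszel pooled odds ratios, participant bootstrap confidence
    intervals, consensus-stratified activity counts), stage-wise movement-load
    comparisons (Wilcoxon signed-rank with Holm correction, Mann-Whitney with
    Cliff's delta, Benjamini-Hochberg adjustment), and a synthetic multimodal
    overnight-recording generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
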