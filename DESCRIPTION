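Package: fnirspain
Title: Simulation, Preprocessing, Decoding and Explanation of fNIRS Pain Responses Under Analgesia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying drug-modulated nociceptive
    decoding from functional near-infrared spectroscopy (fNIRS) recordings.
    Simulates multichannel fNIRS sessions with event-related hemodynamic
    responses, physiological noise and motion artifacts; preprocesses raw
    intensity through optical density conversion, wavelet and PCA motion
    correction, zero-phase Butterworth band-pass filtering, the modified
    Beer-Lambert law and short-separation channel regression; epochs trials
    into labelled arrays with augmentation; trains a one-dimensional
    convolutional pain/non-pain decoder with transfer of the convolutional
    stack to post-drug conditions; attributes decoder decisions to cortical
    regions of interest with a DeepLIFT-rescale Shapley estimator; and
    statistically compares run-level performances with Kruskal-Wallis,
    Bonferroni-corrected rank post hocs and a repeated-measures ANOVA after
    Box-Cox transformation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
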