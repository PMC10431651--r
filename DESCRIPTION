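Package: nirsfeed
Title: fNIRS Neurofeedback Signal Computation and Short-Channel-Corrected Activation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-wave functional near-infrared spectroscopy
    (fNIRS) neurofeedback studies targeting the dorsolateral prefrontal
    cortex. Implements the online feedback chain (causal Butterworth
    band-pass, 2-s moving average, per-trial baseline subtraction, bounded
    gauge mapping), offline preprocessing (optical density, zero-phase
    band-pass under two filter settings, polyphase resampling to 4 Hz,
    modified Beer-Lambert law), per-channel GLM fitting by autoregressive
    iteratively reweighted least squares with short-channel nuisance
    regression, best-k trial selection, Bonferroni-corrected
    activated-channel counting per region of interest, responder and
    concordance classification, block averaging, and group chi-square
    statistics. Includes a synthetic fNIRS generator with known ground truth
    (canonical hemodynamic response, shared scalp physiology, Mayer-wave,
    respiratory and cardiac oscillations) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
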