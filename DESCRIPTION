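Package: avfppg
Title: Bilateral Photoplethysmography Analysis for Arteriovenous Fistula
    Stenosis Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades arteriovenous fistula (AVF) stenosis into three
    degree-of-stenosis (DOS) classes from two-channel (left/right thumb)
    photoplethysmography (PPG). Implements IIR Butterworth preprocessing,
    pulse landmark detection (foot, systolic peak, dicrotic notch),
    bilateral asynchrony features (foot-time, pulse-transit-time,
    rise-time and amplitude asymmetries), an error-correcting output
    coding one-versus-rest support vector machine with Hamming decoding,
    a Levenberg-Marquardt multilayer perceptron baseline, confusion-matrix
    metrics, leave-one-subject-out cross-validation, and an SNR-controlled
    noise-robustness protocol. Includes a synthetic bilateral-PPG cohort
    generator with DOS-dependent inter-arm asynchrony for end-to-end
    evaluation when clinical recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
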