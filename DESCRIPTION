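Package: eegtranslate
Title: Scalp-to-Intracranial EEG Translation with a Variational
    Conditional GAN and Interictal Discharge Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps multichannel scalp EEG segments to concurrent intracranial
    (foramen ovale) EEG segments with a variational encoder and a
    SPADE-conditioned adversarial generator trained against a per-sensor patch
    discriminator, then detects interictal epileptiform discharges (IEDs) from
    the estimated intracranial signals with a compact convolutional classifier.
    Includes a synthetic concurrent scalp/intracranial cohort simulator,
    preprocessing (zero-phase high-pass and notch filtering, common average
    referencing, fixed-length segmentation), mapping-quality metrics (MSE,
    Pearson correlation, cosine similarity), intra- and inter-subject
    cross-validation protocols with ensemble probability averaging, and
    portable NPZ cohort storage with EDF import.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
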