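Package: esusense
Title: Electrosurgical Cautery State Detection from Current-Sensor Packet Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the state of an electrosurgical generator unit
    (ESU) from non-invasive current-sensor data. Packet streams of 50 ms voltage
    windows (3900 samples at an effective 78 kHz) are represented as a
    SummarizedExperiment-based container; spectral features (FFT magnitude
    spectra downsampled to 200 frequency bands, peak intensity/frequency pairs,
    and five principal components) feed SVM and random-forest classifiers of the
    five cautery states (off, cut-in-air, coagulate-in-air, cut-on-tissue,
    coagulate-on-tissue) and of the generator energy level. Smoothed state
    streams are segmented into energy events (incision start/end timestamps).
    A seeded simulator emulates a two-device, three-power, three-tissue
    acquisition protocol, and a leave-one-group-out cross-validation harness
    reproduces the grouped-fold validation design, including accuracy tables
    and confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), SummarizedExperiment
Imports: methods, stats, utils, jsonlite, e1071, randomForest, S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
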