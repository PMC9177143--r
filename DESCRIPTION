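Package: swcoupling
Title: Slow-Wave and Spindle Coupling Analysis of Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of sleep slow waves and spindles on frontal EEG,
    classification of slow waves into slow and fast "switchers" by their
    down-to-up transition frequency (two-Gaussian intersection threshold),
    assignment of spindle-onset phase on the slow wave via a five-landmark
    phase convention, circular statistics (two-sample Watson U2), overnight
    delta band-power summaries, and the linear mixed-model association
    analyses linking coupling phase to amyloid burden and longitudinal
    memory change. Includes a ground-truthed synthetic sleep-EEG and cohort
    generator so every stage of the pipeline is testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pbkrtest,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
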