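Package: photothreat
Title: Fiber-Photometry Signal Quantification and Defensive-Behavior Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying fiber-photometry calcium signals and scoring
    defensive behavior in threat paradigms. Computes dF/F from dual-channel
    (GCaMP + isosbestic) recordings via local-average downsampling and
    least-squares polynomial detrending, performs isosbestic-based quality
    control, aligns traces to events (looming stimuli, conditioned and
    unconditioned stimuli), z-scores them against pre-event baselines, and
    derives per-trial peak-filtered area-under-curve and time-to-peak metrics.
    Scores freezing, rearing, escape, line-cross and center-time behavior from
    trajectory data. Includes a seedable synthetic-session generator with known
    ground truth so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
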