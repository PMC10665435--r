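Package: erkktr
Title: Single-Cell Erk-KTR Activity Reconstruction from Two-Channel
    Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstructs single-cell Erk1/2 activity from two-channel
    time-lapse fluorescence movies of cells expressing a kinase
    translocation reporter (KTR). Segments nuclei from a nuclear-dye
    channel, defines the cytoplasm of each cell as a fixed-width annular
    ring around its nucleus, tracks cells across frames by minimum-cost
    (Munkres/Hungarian) assignment, extracts cytoplasm-to-nucleus (C/N)
    mean-intensity-ratio traces normalized to the frame just before
    stimulation, fits two piecewise exponential kinetic models (monotone
    approach to equilibrium, and a transient variant that recovers toward
    baseline) per cell, and compares kinetic parameters between
    cell-status groups (young / mid-old / old, defined by doubling time
    and SA-beta-Gal positivity) with an exact one-tailed Mann-Whitney U
    test. A ground-truthed synthetic movie generator emulating the
    acquisition schedule (frames every 15 s for 30 min after serum
    stimulation) makes every stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
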