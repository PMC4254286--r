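Package: beatstab
Title: Tempo and Tempo-Stability Analysis of Beat Onset Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the temporal stability of music recordings from beat
    and barline onset timestamps produced by an external beat tracker. The
    central tendency (tempo location) of an inter-beat-interval series is
    estimated as the mode of an adaptive Gaussian kernel density estimate with
    a diffusion (improved Sheather-Jones) bandwidth, robust to multimodal
    interval distributions arising from tempo changes. Intervals are then
    classified as stable or unstable under a local percentage threshold,
    maximal stable Runs are chained across short Gaps into the longest Stable
    Segment, and nine summary statistics describing tempo and its stability
    are reported. Includes a synthetic onset-series generator with known
    ground truth, batch analysis, threshold-based filtering of summary
    tables, and a command-line interface, supporting playlist curation for
    rhythmic auditory cueing, gait rehabilitation, and exercise applications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
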