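Package: fragtrack
Title: Detection of Stone Fragmentation Events in Ureteroscopy Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects inadvertent kidney-stone fragmentation while dusting
    during ureteroscopy with laser lithotripsy. Implements a three-stage
    video pipeline: per-frame semantic segmentation of the stone, point
    tracking on the stone surface, and hierarchical density-based
    clustering of the tracked point positions, raising a fragmentation
    event when the cluster count rises above its post-initialization
    baseline. Includes a synthetic endoscopy scene simulator with full
    ground truth (masks, point tracks, event intervals), frame-level and
    segment-level evaluation with tolerance-window matching, and a
    command-line interface binding all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
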