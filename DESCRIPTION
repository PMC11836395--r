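Package: shoalwatch
Title: Video-Based Behavioural Welfare Indicators for Tank-Reared Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies group-level behavioural welfare indicators of fish in
    circular rearing tanks from overhead video. A per-pixel median/MAD
    background model segments fish from the static tank scene; connected
    components are labelled, clustered into a main group, and linked across
    frames. From the detections the package computes group cohesion (the ratio
    of the area occupied by the main group to the monitored tank area, with a
    tight/loose/dispersed categorical score), activity (size-weighted mean
    centroid displacement between consecutive frames), enrichment occupation
    (share of fish pixel area under a static enrichment structure), and, for
    novel-object trials, the latency to resume normal swimming under a
    darting-rate rule. An agent-based tank simulator renders synthetic
    overhead clips with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
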