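Package: rgtpipe
Title: Behavioral and Neural Analysis Pipeline for the Rodent Gambling Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rodent gambling task (rGT) experiments
    combining behavior, in vivo extracellular recordings, and qPCR.
    Computes per-block choice preference indices, omission and latency
    summaries, and trial-by-trial response maps; builds event-locked
    peri-event time histograms (PETHs) with Gaussian smoothing and
    baseline Z-scoring; clusters unit response profiles (post/pre
    activity ratios) by average-linkage agglomeration with a gap-based
    dendrogram cut and quantifies per-cluster response magnitude and
    encoding flexibility; and quantifies relative gene expression by the
    delta-Ct method. Includes a seeded synthetic-data generator
    (gambling sessions, inhomogeneous-Poisson spike trains with planted
    cluster structure, replicate Ct tables) so every stage is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
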