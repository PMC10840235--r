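Package: chartlink
Title: Linked Interactive Charts with Native R Event Handling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for building linked interactive charts in which all
    event handling lives in R. Charts are declared with immediate or deferred
    properties, rendered server-side to SVG with stable element identifiers,
    and displayed in a browser; user interactions (click, hover, input change)
    invoke native R callbacks that mutate per-session state and trigger
    re-evaluation and re-rendering of linked charts. Includes pure geometry and
    statistics kernels (scales, ticks, histogram binning, kernel density
    estimation, beeswarm layout, heatmap clustering order), an embedded
    session server with per-client state isolation, and synthetic-data demo
    applications for transcriptomics (MA plot linked to per-sample expression)
    and drug-screen analysis (plates, four-parameter logistic dose-response
    fits, drug sensitivity scores, correlation heatmaps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    httpuv,
    xml2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
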