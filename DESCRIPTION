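Package: synviewr
Title: Headless Pairwise Genome Synteny Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable toolkit for visualizing pairwise genome synteny
    from user-supplied data. Reads and writes simple tab-delimited synteny
    and annotation interchange formats (optionally gzip- or zip-compressed),
    converts BLAST tabular (outfmt 6), lastz/BLASTZ general tabular and GFF3
    output into them, filters conserved regions by arbitrary numeric
    attributes, manages per-genome viewports (zoom, pan, region selection),
    and renders a dual-genome integrated figure -- rulers with tick marks,
    synteny ribbons or lines, and styled annotation tracks -- to
    deterministic SVG or to PNG. A seeded simulator generates synthetic
    synteny datasets with controllable block structure and inversion rates
    for testing and demonstration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    utils,
    grDevices,
    graphics,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    xml2,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
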