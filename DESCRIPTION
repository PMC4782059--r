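Package: esskit
Title: Containerized Packaging, Validation and Preprocessing of EEG Studies
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for packaging EEG studies into portable, self-describing
    containers following the EEG Study Schema convention. Provides a manifest
    data model with a bit-faithful XML reader/writer, a hierarchical event
    descriptor (HED) vocabulary with tag parsing, validation and search, a
    catalog of more than 30 manifest validation checks with safe auto-fixes,
    Level-1 container assembly with tab-separated event-instance files,
    an automated Level-2 preprocessing stage (noisy-channel detection,
    neighbor interpolation, robust average referencing), provenance-chained
    level-derived containers, an HTML study report, and a synthetic-study
    generator for end-to-end testing without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
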