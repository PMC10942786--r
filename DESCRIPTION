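Package: dichoscreen
Title: Dichotomized Expression-Pattern Screening for Autonomic Ganglion
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens single-cell RNA-seq count matrices for genes whose
    expressing-cell fraction is dichotomized across labeled cell groups.
    Every gene is scored against every ordered bipartition of the groups
    (254 comparisons for the eight autonomic groups: four ganglia and four
    pelvic clusters), and the top-scoring genes are mapped onto an
    expression-pattern taxonomy that distinguishes sympathetic,
    parasympathetic, neurotransmitter-linked and pelvic-specific markers.
    Includes the upstream droplet quality control (detected-gene and
    mitochondrial-fraction filters), marker-based neuron selection with a
    bimodal auto-threshold, glial-doublet exclusion, a CellRanger-style
    Matrix Market reader/writer, a synthetic-data generator with planted
    dichotomous genes for end-to-end validation, and a reproducible
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
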