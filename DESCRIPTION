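Package: provflow
Title: Self-Documented Dataset Directories and Two-Phase Analysis Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-based framework for reproducible sequence-analysis
    workflows. Every input and every analysis result is a self-contained
    directory described by a plain-text sample sheet (dataset.tsv) whose
    column headers carry bracketed tags (File, Link, Factor,
    Characteristics). Analysis applications are declarative meta-processes:
    given an input dataset and parameters they first generate standalone
    POSIX shell job scripts, a parameter file and the output dataset
    description (Step 1); the scripts are executed later (Step 2) by a
    local runner or by a bare shell, with no reference back to this
    package. A flat-file registry tracks dataset lineage as a
    parent/child forest, and bundled synthetic-read fixtures plus three
    pure example applications reproduce a toy RNA-seq quality-control,
    counting and group-comparison pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
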