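Package: maex
Title: Multi-Study Microarray Expression Extraction and Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts expression values for a user-defined gene list from
    multiple normalized microarray studies organized as plain-text study
    folders, resolves multi-probe genes by a suffix-priority scheme with a
    highest-control-signal tie-break, detects or honours the log2 scale of
    each study, computes group-versus-control log2 ratios, merges all
    studies into a single annotated table, and combines per-study one-tailed
    t-test p-values across studies with signed Stouffer Z-transform or
    Fisher chi-square methods.  Includes a seeded synthetic study-tree
    generator with known ground truth for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
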