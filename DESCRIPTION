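Package: phylodrift
Title: Phylogenetically Controlled Tests of Drift, Genome Size and
    Transposable-Element Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative tests of the mutational hazard
    hypothesis in metazoan genomes: genome-size estimation by weighted
    regression of C-values on assembly sizes, terminal-branch dN/dS from
    substitution mapping under the YN98 (F3X4) codon model with per-species
    aggregation and quality filters, overall and recent transposable-element
    content from low-coverage read annotations, and phylogenetically
    controlled association tests (Felsenstein independent contrasts and a
    multivariate Brownian coevolution fit with parametric-bootstrap support).
    A synthetic-data module generates every input the pipeline consumes so
    the full analysis runs and is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
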