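Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for restriction-tag digital gene expression (DGE/SAGE)
    libraries: in-silico NlaIII/MmeI digestion of a transcript reference into canonical
    21-bp tags, raw tag quality filtering, one-mismatch tag-to-gene mapping with
    ambiguity exclusion, transcripts-per-million quantification, the Audic-Claverie
    exact test with Benjamini-Hochberg false discovery rate control for pairwise
    library comparisons, expression-pattern classification across developmental
    stages, hypergeometric pathway enrichment, and sequencing-saturation analysis.
    Includes a seeded simulator of tag libraries with known ground truth (planted
    fold changes, sequencing errors, artifact tags) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
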