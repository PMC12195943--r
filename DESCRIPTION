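Package: pepdigest
Title: In Silico Proteolysis and Bioactive Peptide Profiling of Milk Protein Allelic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the enzymatic digestion of milk casein allelic variants
    and profiles the bioactive peptides they release. Provides a declarative
    cleavage-rule engine for multi-enzyme one-pot digestion (complete and
    partial modes), frequency-of-occurrence statistics for bioactive fragments
    (the A parameter and its unweighted sum over activities), score- and
    length-based candidate filtering with a pluggable peptide-score table,
    activity annotation against a peptide-activity database, an allele-by-
    activity bioactivity matrix, protein variant construction from edit lists,
    and a synthetic-data generator with planted ground truth for exact
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
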