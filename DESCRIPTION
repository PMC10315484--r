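Package: transportomeR
Title: Membrane Transporter Inventory Construction and Salt/Symbiosis
    Expression Analysis for Fungal Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a membrane-transporter inventory (transportome) for a
    fungal proteome by combining reciprocal-coverage sequence clustering
    against reference transportomes, homology rescue of non-annotated
    transporters, and keyword/COG screening of functional annotations,
    followed by Transporter Classification (TC) assignment and class,
    substrate and subcellular-location summaries. Downstream, it provides
    FPKM normalisation, a negative-binomial two-group differential
    expression test, and the cross-tabulation, Venn, clustering and
    sample-similarity analyses used to classify transporter genes as salt-
    and/or symbiosis-responsive across a 2 lifestyle x 2 salt x 3 timepoint
    design. A synthetic-data module generates proteomes with planted
    transmembrane transporters, divergent reference orthologs, annotation
    tables and count matrices with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
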