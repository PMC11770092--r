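Package: lepscreen
Title: Discovery and Pan-Cancer Screening of lncRNA-Encoded Microproteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering candidate microproteins encoded by small
    open reading frames on transcripts annotated as long noncoding RNAs, and
    for screening them across tumor proteomics cohorts. Implements ATG-initiated
    small-ORF scanning and candidate database construction, in-silico tryptic
    digestion with peptide-uniqueness classification against a reference
    proteome, missing-value-aware presence and differential-expression
    screening of protein abundance matrices, replicate-consistent interactome
    set algebra, percent-spliced-in quantification of exon-skipping events,
    and a seeded synthetic-data generator with recorded ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, AlternativeSplicing, Software
RoxygenNote: 7.3.3
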