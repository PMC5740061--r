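Package: cdpscreen
Title: Quantitative Analysis of Mammalian-Display Screens of Cystine-Dense Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating and analysing mammalian surface-display
    screens of cystine-dense peptides (CDPs). Extracts cysteine-bounded
    motifs from protein sequences and annotates N-linked glycosylation
    sequons and native-protein context; reconstructs per-peptide surface
    protein-content scores from FACS sort-seq bin read counts combined with
    per-bin cell counts and median fluorescences; scores trypsin resistance
    and classifies surface folding; classifies reversed-phase HPLC peak
    profiles and tests surface/solution folding concordance by label
    permutation; ranks bin enrichment and runs unweighted gene-set
    enrichment analysis; computes wild-type-normalised log2 enrichment
    scores for site-saturation mutagenesis selections; and provides seeded
    generators of synthetic sort-seq, HPLC and selection data with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
biocViews: Sequencing, Proteomics, CellBasedAssays, Preprocessing,
    StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
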