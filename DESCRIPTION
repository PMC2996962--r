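Package: estpipe
Title: EST-to-Genome Alignment Clustering, Alternative Splicing and
    Molecular Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locus-level analysis of expressed sequence tag (EST)
    collections mapped to a reference genome of a related species. Spliced
    EST-to-genome alignments are filtered by identity and coverage, clustered
    by shared splice sites or genomic overlap, and merged into unique
    locus-level clusters. Within clusters the four canonical local
    alternative-splicing patterns (exon skipping, intron retention,
    alternative 5' and 3' splice sites) are detected and classified, with a
    subsampling normalization for EST-depth effects. Tissue specificity of
    EST copy numbers is called by Fisher's exact test, expression profiles
    are correlated across species, CDS coverage of reference transcripts is
    profiled, and pairwise Ka/Ks is estimated by the Nei-Gojobori counting
    method with Jukes-Cantor correction for gene-set comparisons. A
    synthetic genome/EST simulator with machine-readable planted truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
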