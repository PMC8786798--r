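Package: tlpfam
Title: Characterization of Thaumatin-Like Protein Gene Families in Cereal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of thaumatin-like protein (TLP,
    pathogenesis-related-5) gene families: PROSITE-style screening for the thaumatin
    signature motif and conserved cysteine/REDDD residues, physicochemical profiling
    (length, molecular weight, isoelectric point), homeolog grouping and tandem versus
    segmental duplication classification, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction and synonymous-clock divergence times, Tajima's relative-rate
    test, promoter cis-regulatory element scanning with IUPAC-degenerate patterns,
    FPKM-based differential expression and clustering, 2^-ddCt qPCR analytics, and
    duplicate-gene expression-fate calls. A synthetic-data generator with recorded ground
    truth makes every stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    yaml
Config/testthat/edition: 3
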