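Package: phagegcd
Title: Gene Content Dissimilarity and Comparative Genomics of Phage Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of bacteriophage populations:
    grouping of protein sequences into phamilies (phams) by alignment-free
    k-mer similarity, per-genome pham profiles, pairwise gene content
    dissimilarity (GCD), rank-ordered GCD gap profiles and the MaxGCDGap
    statistic, shared-gene-content cluster and singleton assignment with
    fragment-based average nucleotide identity (ANI) subclustering,
    degenerate repressor-binding (stoperator) consensus scanning,
    attachment-site (attP/attB) common-core discovery with tRNA-overlap
    annotation, and a seeded synthetic mosaic-population generator with
    exported ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
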