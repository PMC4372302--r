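Package: silkgland
Title: Comparative Analysis of Wild Silkmoth Silk-Gland Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative silk-gland transcriptomics across wild
    silkmoths (Saturniidae) and Bombyx mori. Characterizes silk proteins
    (isoelectric point of the fibroin N terminus, Kyte-Doolittle hydropathy
    profiles over reference-anchored pairwise alignments, poly-alanine /
    glycine-rich repeat decomposition and GGGX/GGX/GX motif inventories,
    amino-acid composition); estimates dN/dS on coding alignments by
    Nei-Gojobori counting and by one-ratio and free-ratio codon maximum
    likelihood with a likelihood-ratio test; builds neighbor-joining trees,
    computes phylogenetically independent contrasts, and reconciles gene
    trees with a species tree to count duplications and losses; compares
    family-level RPKM expression between colored- and non-colored-cocoon
    groups with a negative-binomial exact test and BH false-discovery
    control; and performs chi-square GO-term enrichment. A synthetic-data
    module generates every input with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    withr,
    Matrix,
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
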