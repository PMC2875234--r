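Package: imprintEvol
Title: Comparative Sequence Divergence of Imprinted Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for comparing the molecular evolution of genomically
    imprinted genes with the genomic background across mammalian species.
    Implements codon-aware pairwise alignment by protein alignment and
    back-translation, Nei-Gojobori counting estimates of synonymous (Ks) and
    nonsynonymous (Ka) substitution rates, silent CpG-to-TpG mutability at
    third codon positions, triangulation of divergence between human and the
    mouse-rat common ancestor from pairwise distances, Goldman-Yang codon
    branch models on the unrooted (human,(mouse,rat),cow) quartet with
    one-ratio versus two-ratios likelihood-ratio tests, SNP density summaries,
    and rank-based group comparisons with paralog enrichment statistics.
    Includes a synthetic-data generator that evolves codon quartets under the
    same substitution model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Phylogenetics, SequenceMatching, Genetics
RoxygenNote: 7.3.3
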