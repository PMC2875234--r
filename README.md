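# imprintEvol

Comparative molecular evolution of genomically imprinted genes.

Imprinted genes are expressed from a single parental allele, so selection
sees them as functionally haploid: deleterious mutations on the active copy
are exposed immediately while the silenced copy can drift.  Whether this
makes imprinted genes — and maternally versus paternally expressed ones in
particular — diverge differently from the biallelic genomic background is a
quantitative question about coding-sequence evolution across mammals.
`imprintEvol` provides the full analysis pipeline for human / mouse / rat /
cow ortholog comparisons:

* **Codon-aware alignment** — longest-ORF extraction, protein-level global
  alignment (Needleman–Wunsch, affine gaps, BLOSUM62) and back-translation,
  so alignment gaps can never break the reading frame.
* **Pairwise divergence statistics** — percent identity (protein and cDNA),
  indel events, Nei–Gojobori Ka/Ks with Jukes–Cantor correction
  (d = −¾ log(1 − 4p/3)) and pathway averaging, silent CpG→TpG mutability at
  third codon positions, and SNP density per kb of coding sequence.
* **Ancestor triangulation** — divergence between human and the unsampled
  mouse–rat common ancestor from the three pairwise values under distance
  additivity, d(hs, anc) = (d_hs,mm + d_hs,rn − d_mm,rn)/2, with the
  applicability gate (rodents must be mutually closer than either is to
  human) recorded per gene.
* **Codon branch models** — Goldman–Yang style 61-state likelihood on the
  unrooted quartet (human,(mouse,rat)#1,cow); one-ratio vs two-ratios fits
  with a free ω on the rodent-ancestor branch; likelihood-ratio test with
  the 2ΔlnL ≥ 2.71 decision rule; Ks ∈ {0} ∪ (2.5, ∞) saturation filters.
* **Group statistics** — summaries and Mann–Whitney comparisons by
  imprinting class (maternal / paternal / background), paralog selection and
  χ² enrichment, SNP-depletion reports.
* **Synthetic data** — a generator that evolves codon quartets under the
  same substitution model the likelihood uses, then runs the *real* pipeline
  on them, for end-to-end validation with known ground truth.

File formats are deliberately plain: FASTA with `gene|species` headers and
TSV tables in HomoloGene / BioMart export style (see `?readGenePairTable`).
Database Ks values recorded as `-1` are treated as discarded, never as
numbers.

## Worked example

The package ships a six-gene toy dataset (two genes per group, 30 codons),
regenerable with `fixtureToyDataset()`:

```r
library(imprintEvol)

toy    <- system.file("extdata", "toy", package = "imprintEvol")
cds    <- readCdsFasta(file.path(toy, "sequences.fa"))
snps   <- readSnpTable(file.path(toy, "snps.tsv"))
groups <- readGroupFile(file.path(toy, "groups.tsv"))

pairs <- data.frame(gene_id  = rep(unique(S4Vectors::mcols(cds)$gene_id), each = 3),
                    species_a = c("human", "human", "mouse"),
                    species_b = c("mouse", "rat",   "rat"))
div <- divergenceTable(cds, pairs = pairs, snps = snps)
head(div[, c("gene_id", "species_a", "species_b", "protein_identity",
             "cdna_identity", "ka", "ks", "ka_ks")], 3)
#>   gene_id species_a species_b protein_identity cdna_identity     ka    ks  ka_ks
#> 1    g001     human     mouse             70.0          77.8 0.1507 0.704 0.2140
#> 2    g001     human       rat             66.7          77.8 0.1700 0.599 0.2840
#> 3    g001     mouse     rat               93.3          90.0 0.0314 0.351 0.0896
```

The three pairwise rows per gene show the expected mammalian pattern: the
two rodents are far closer to each other (93% protein identity, Ks 0.35)
than either is to human (Ks 0.6–0.7), and Ka/Ks ≪ 1 throughout indicates
purifying selection.  Triangulating each gene onto the human ↔ rodent
ancestor path:

```r
tri <- triangulateTable(div)
tri[1:3, c("gene_id", "protein_identity", "cdna_identity", "ka", "ks", "ka_ks")]
#>   gene_id protein_identity cdna_identity     ka    ks  ka_ks
#> 1    g001             71.7          82.8 0.1446 0.476 0.304
#> 2    g002             88.3          92.2 0.0509 0.213 0.239
#> 3    g003             90.0          88.9 0.0468 0.430 0.109
```

i.e. for gene `g001` the protein identity between human and the mouse–rat
common ancestor is estimated at 71.7% and the ancestral-path Ka/Ks at 0.30.
Finally, the branch-model test asks whether the rodent-ancestor branch has
its own ω:

```r
g1 <- as.character(cds)[S4Vectors::mcols(cds)$gene_id == "g001"]
names(g1) <- S4Vectors::mcols(cds)$species[S4Vectors::mcols(cds)$gene_id == "g001"]
qa <- alignQuartet(g1, geneId = "g001")
lrt(fitBranchModel(qa, "one_ratio"), fitBranchModel(qa, "two_ratios"))
#> LRT: 2*dlnL = 0.5662 (threshold 2.71) -> not significant, foreground omega elevated
```

At 30 codons there is (correctly) no evidence for a branch-specific ω.
`summarizeGroups`, `compareGroups`, `paralogEnrichment` and
`snpDepletionReport` then contrast the imprinting classes; see the methods
vignette (`vignettes/imprintEvol-methods.Rmd`) for the models, conventions
and their rationale.

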