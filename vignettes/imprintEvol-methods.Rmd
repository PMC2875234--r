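---
title: "Methods: measuring the divergence of imprinted genes"
author: "imprintEvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the divergence of imprinted genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintEvol)
```

# The scientific question

Genomically imprinted genes are expressed from only one parental allele.
Their functional haploidy changes how natural selection can act on them:
deleterious mutations on the active allele are exposed immediately, while the
silenced allele can drift.  A long-standing question is whether imprinted
genes — and in particular maternally versus paternally expressed ones —
diverge differently from the biallelic genomic background across mammals.
This package provides the comparative-genomics machinery to ask that question
quantitatively: pairwise divergence statistics between orthologous coding
sequences of human, mouse, rat and cow; a triangulation of divergence onto
the unsampled mouse–rat common ancestor; codon branch models that isolate the
rodent-ancestor lineage; and group-level statistics contrasting maternally
expressed, paternally expressed and background genes, including their
paralogs and SNP load.

Because the original ortholog databases (HomoloGene-style extracts,
BioMart-style paralog lists, dbSNP-derived counts) are living resources that
cannot be redistributed, every analysis stage is exercised end to end on
synthetic data with controlled ground truth, generated by the package itself.

# Pairwise divergence

## Codon-aware alignment

Coding sequences are compared through their proteins: the longest
ATG-initiated open reading frame is extracted (`longestOrf`), translated
(`translateCds`, standard genetic code, ambiguous codons to `X`), globally
aligned at the protein level (`alignProteins`: Needleman–Wunsch with affine
gaps, BLOSUM62, gap open 10, gap extend 0.5 — the pairwise step of a
ClustalW-style aligner, computed by `Biostrings::pairwiseAlignment`) and
back-translated (`backtranslate`), replacing each residue by its source codon
and each gap by `---`.  Gap runs in the resulting codon alignment are
therefore always multiples of three and can never shift the reading frame.
The alignment parameters are conventional defaults, not estimates; they are
configurable, and the test suite verifies score optimality against exhaustive
enumeration on short sequences rather than any particular parameter choice.

Quartet alignments for the branch models are built by star alignment to a
designated reference (human by default): pairwise protein alignments against
the reference are merged under a "once a gap, always a gap" rule on the
reference row.  This is adequate for four closely related sequences and for
the indel-free synthetic data; it is not a progressive multiple aligner.

## Identity and gaps

`percentIdentity` divides identical non-gap columns by the *total* number of
alignment columns, so gap columns count as mismatches.  Databases differ in
this convention and the source extracts do not document theirs; counting gap
columns in the denominator keeps the identity and the gap statistics coherent
(a large insertion lowers identity and raises the gap count together).  The
alternative (`denominator = "ungapped"`) is available.  `countGaps` counts
*indel events* (maximal gap runs), matching the biological reading of
insertions or deletions of amino-acid stretches; gap-column counting is
available as an option.

## Nei–Gojobori Ka/Ks

`neiGojobori` implements the counting estimator.  Per codon, each of the
three positions contributes a synonymous-site fraction equal to the
proportion of its single-base changes that preserve the amino acid, computed
over the changes that do not create a stop codon (stop-producing changes are
excluded from numerator and denominator, so every position contributes
exactly one site and S + N = 3 per codon).  Observed differences between
codon pairs are averaged over all minimal mutational pathways, excluding
pathways that pass through a stop codon; if every pathway is blocked (never
the case for sense codons under the standard code) all pathways are used
with stop-crossing steps scored as nonsynonymous.  Sites are averaged over
the two sequences.  The Jukes–Cantor correction
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$ is applied to $p_S = S_d/S$ and
$p_N = N_d/N$; when either proportion reaches 3/4 the correction diverges
and the result is flagged `saturated`.  Note that on very short alignments
$p_S$ can legitimately exceed 1 (differences are integers, sites are
fractions), which is another route into saturation.  Codon columns containing
gaps or ambiguity are skipped.  The whole 61 × 61 site/pathway table is
verified against an independent enumeration oracle in the acceptance suite.

## Silent CpG mutability

An elevated rate of CpG→TpG transitions is the signature of deamination of
methylated cytosines, a mechanism that could mimic selection-driven
divergence in methylation-rich imprinted loci.  `silentCpgMutability` scans
codon-boundary dinucleotides (third position of codon *i*, first position of
codon *i*+1).  A site is a conserved CpG context when both sequences carry
CpG; it is a CpG–TpG mismatch when one sequence carries CpG, the other TpG,
*and* substituting T for C at that third position leaves the encoded amino
acid unchanged — restricting the count to silent changes isolates mutation
pressure from selection.  Because the ancestral state of a pairwise
comparison is unknown the count is direction-agnostic.  The primary index is
the mismatch fraction n(CpG–TpG) / (n(CpG–CpG) + n(CpG–TpG)), which is a
proportion in [0, 1]; the raw ratio n(CpG–TpG)/n(CpG–CpG) is also returned
since "ratio" admits both readings.  Sites touching an alignment gap are
skipped.

## SNP density

`snpDensity` is SNPs per kb of coding sequence; `snpDepletionReport` compares
per-group medians by rank-sum test.  A depletion of coding SNPs in a group is
read as ongoing purifying selection.

# Triangulating the rodent ancestor

High mouse–rat conservation combined with high human–rodent divergence
implies that most changes predate the mouse–rat split.  To quantify
divergence *between human and the mouse–rat common ancestor*, the three
pairwise values (human–mouse, human–rat, mouse–rat) are combined under
distance additivity on the three-taxon star:

$$d(\mathrm{hs}, \mathrm{anc}) =
  \frac{d_{hs,mm} + d_{hs,rn} - d_{mm,rn}}{2}.$$

For identities the values are first converted to divergences
$d = 100 - \mathrm{id}$ and back.  The estimate is only meaningful when the
two rodents are closer to each other than either is to human; otherwise
(alignment artefacts, exon-usage changes) the gene is flagged *inapplicable*
— a recorded status, not an error, so genome-wide exclusion counts can be
reported.  The same algebra with the inequality reversed applies to Ka and
Ks rates, and a triangulated Ka/Ks is formed from the two triangulated
rates.  On noise-free additive inputs the recovery is exact to machine
precision, which the acceptance suite asserts; on estimated distances the
triangulated value is an estimate like any other and can, for example,
exceed either human–rodent rate.

# Codon branch models

## Model

The branch models work on the fixed unrooted quartet
`(human,(mouse,rat)#1,cow)`, with the internal branch leading to the
mouse–rat ancestor as the *foreground* branch.  Substitution follows a
Goldman–Yang style 61-state Markov process: rate zero between codons more
than one nucleotide apart, a factor $\kappa$ for transitions, a factor
$\omega$ (Ka/Ks) for nonsynonymous changes, and the target-codon equilibrium
frequency.  The generator is scaled so branch lengths are expected
substitutions per codon.  Codon frequencies default to uniform over the 61
sense codons; empirical F1x4-style frequencies can be supplied via the
`freqs` argument.  The *one-ratio* model shares one $\omega$ across all five
branches; the *two-ratios* model frees $\omega$ on the foreground branch.

The log-likelihood is computed by Felsenstein pruning over the two internal
nodes, with site patterns compressed, and is verified against an exhaustive
sum over all 61 × 61 internal-state pairs in the acceptance suite (agreement
to 1e-8).  Gap- or ambiguity-containing codon columns are excluded; fits
require at least 10 usable columns.

## Optimisation

`fitBranchModel` maximises the likelihood with L-BFGS-B on log-transformed
parameters (branch lengths in [1e-6, 20], $\kappa$ in [0.05, 99], $\omega$
in [1e-4, 10], convergence on a relative tolerance of about 1e-7 on lnL).
The single default start is data-driven: pairwise codon distances are
triangulated onto the topology and $\kappa = 2$, $\omega = 0.2$ seed the
rate parameters.  On this 7–8 parameter unimodal-in-practice problem the
data-driven start makes random multi-starts redundant, and the calibration
experiments (hundreds of fits) dominate the package's runtime, so one start
is the default; `nStarts` adds seeded random restarts for difficult data.
Branch lengths are converted to per-branch Ka and Ks by splitting the
substitution flux into its synonymous and nonsynonymous components under the
fitted model and dividing by the corresponding site fractions at
$\omega = 1$ (mutational opportunity), the convention used by codeml-style
software.

## The likelihood-ratio test and its calibration

`lrt` computes $2(\ln L_2 - \ln L_1)$, clipped at zero (the models are
nested, so negative values can only be numerical), and declares the
foreground ratio different when the statistic reaches 2.71, reporting
whether the fitted foreground $\omega$ is elevated or reduced.  2.71 is the
5% point of the half-and-half mixture of a point mass at zero and
$\chi^2_1$ — the boundary convention conventionally quoted with branch-model
LRTs — and is used here as the fixed decision rule.

One calibration subtlety deserves to be explicit.  In the two-ratios model
the null hypothesis ($\omega_{fg} = \omega_{bg}$) is *interior* to the
parameter space, so the LRT statistic is asymptotically $\chi^2_1$, and a
two-sided decision at 2.71 has true size near 10%, not 5%.  The 2.71
threshold is exactly the one-sided 5% point: the decision that is calibrated
at 5% under the null is the *directional* one — significant *and* foreground
$\omega$ elevated (or, symmetrically, reduced).  The package therefore keeps
the printed decision rule in `lrt` and calibrates the directional rejection
rate in `lrtNullExperiment`; the acceptance suite checks that this rate is
0.05 ± 0.02 over 200 null simulations.

Genes with pairwise Ks = 0 (no synonymous signal) or Ks > 2.5 (saturation)
are excluded from rate analyses by `saturationFilter`.

# Group statistics

Per-group summaries (`summarizeGroups`) report mean, sample standard
deviation and median of identities, Ka/Ks, Ks, Ka, gap counts and SNP
density for maternal, paternal, background and the pooled imprinted group;
records whose Ks carries the database discard sentinel (−1) contribute to
identity columns only.  When a gene has several homologs for a species pair
the one with the highest protein identity represents it
(`selectBestHomolog`, ties broken lexicographically); the rank-1
(evolutionarily most recent) paralog represents a gene's paralogs
(`selectRepresentativeParalog`).

Group comparisons (`compareGroups`) use the two-sided Mann–Whitney rank-sum
test — exact when the smaller group has at most 8 observations and there are
no ties, normal approximation with tie correction otherwise.  The source
analyses report threshold-style p-values without naming the test; the
rank-based choice makes no distributional assumption on identities or
ratios, and a one-sided alternative is available.  Paralog enrichment
(`paralogEnrichment`) is a Pearson chi-square on the 2 × 2 counts without
continuity correction (immaterial at the observed margins, but declared),
with row percentages reported to two decimals.  No multiple-testing
correction is applied, mirroring the raw-threshold reporting style of the
analyses this package reproduces.

# The synthetic-data generator

`simulateGeneTables` generates every input the pipeline consumes.  Each
gene's codon quartet is evolved along the fixed tree by sampling from the
*same* scaled rate matrix the likelihood uses (shared core, so simulation
and inference cannot drift apart; an independently coded Gillespie
simulator cross-checks the transition sampling in the test suite).  Pair
records are then computed by running the real alignment and divergence
stages on the simulated sequences — never by faking summary numbers.
Paralog tables, SNP counts and group labels are drawn from per-group
distributions.

Defaults are chosen to emulate the observed study conditions: 26 maternally
and 27 paternally expressed genes; per-group $\omega$ of 0.161 / 0.136 /
0.129; $\kappa = 2$; branch lengths (human 0.35, cow 0.35, mouse 0.10, rat
0.12, ancestor 0.15 substitutions per codon) that reproduce human–mouse Ks
near 0.65 and mouse–rat Ks near 0.2; SNP rates of 2.4 per kb (imprinted)
versus 3.6 (background); paralog probabilities 0.607 versus 0.482 with
representative-paralog identities 47.1 ± 15.2 versus 56.9 ± 22.7 percent.
Two deliberate departures from the emulated study: the genome-wide
background is scaled from ~16,600 genes to 120 (a desk-scale background
that still dwarfs the imprinted groups), and genes default to 150 codons.
SNP tables use their own annotation-scale coding lengths (lognormal, median
about 1.4 kb) rather than the short simulated quartets, so per-kb densities
are not over-discretised by small denominators.
CpG enrichment of the root sequence (`cpgBias`) biases third-position C and
first-position G codons to create codon-boundary CpG contexts with known
expected counts for the mutability statistic.  Whole-codon deletions are
available (`codonDeletionRate`, default 0); there is no sub-codon indel
simulation and no among-site rate heterogeneity.

What passing on synthetic data does and does not show: the generator shares
the inference model's assumptions (independent sites, no rate
heterogeneity, stationary frequencies, frame-safe indels only), so
end-to-end recovery demonstrates internal consistency and correct
implementation, not robustness to the model violations real alignments
carry (alignment error, selection heterogeneity along the gene, CpG
hypermutability itself).

A six-gene, 30-codon toy bundle lives under `inst/extdata/toy`
(regenerated deterministically by `fixtureToyDataset`; seed chosen at
design time so that triangulation is applicable for all six genes).

# Validation experiment sizes

The calibration experiments are sized for a single CPU: omega recovery uses
20 replicates of 500 codons (mean estimate within ±0.05 of truth); null
calibration of the LRT uses 200 replicates of 200 codons; power against a
planted foreground shift ($\omega$ 0.8 vs 0.1) uses 20 replicates of 500
codons; the end-to-end planted-divergence dataset uses the default group
sizes at 150 codons with maternal $\omega$ raised to 0.30 against a 0.10
background, and the end-to-end null check uses twenty 48-gene datasets of
100 codons.  These sizes are the package's own compromise between
Monte-Carlo error and turnaround; all are arguments, not constants.

# Known limitations

* The star quartet alignment is not a progressive multiple aligner; with
  heavy indels a dedicated MSA tool should replace it upstream.
* Pairwise Ka/Ks is counting-based (Nei–Gojobori); maximum-likelihood
  pairwise estimates are intentionally out of scope (the branch models cover
  the likelihood side).
* The codon model has a single $\omega$ per branch — no site or
  branch-site variation.
* `longestOrf` scans forward frames only; inputs are assumed
  mRNA-oriented.
* The triangulation assumes additive distances; systematic
  non-additivity (rate variation across lineages) biases it like any
  distance-based reconstruction.
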