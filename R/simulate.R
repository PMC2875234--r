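## Synthetic-data generator: codon quartets evolved under the same
## Goldman-Yang rate matrix the likelihood uses (shared core, guaranteeing
## generator/inference consistency), plus HomoloGene-like pair tables,
## paralog tables, SNP tables and group files with controlled ground truth.

#' Simulation specification
#'
#' Bundles every knob of the generator with defaults emulating the observed
#' statistical structure of imprinted-vs-background comparisons in
#' human/mouse/rat/cow: group sizes 26 maternal / 27 paternal, omega 0.161 /
#' 0.136 / 0.129 (maternal / paternal / background), branch lengths giving
#' human-mouse Ks around 0.65 and mouse-rat Ks around 0.2, SNP densities 2.4
#' per kb (imprinted) vs 3.6 (background), paralog probabilities 0.607 vs
#' 0.482 with paralog identities 47.1 +/- 15.2 vs 56.9 +/- 22.7 percent.  The
#' genome-wide background is scaled to 120 genes.
#'
#' @param nGenes named integer vector (maternal, paternal, background).
#' @param codons codons per gene.
#' @param treeLengths named branch lengths (substitutions/codon) for
#'   human, cow, mouse, rat, ancestor.
#' @param kappa transition/transversion ratio.
#' @param omega named per-group background omega.
#' @param omegaForeground named per-group omega on the rodent-ancestor
#'   (foreground) branch; defaults to the group's background omega.
#' @param cpgBias multiplicative enrichment of root codons creating CpG
#'   contexts at codon boundaries (1 = no enrichment).
#' @param paralogProb named per-group probability that a gene has paralogs.
#' @param paralogIdentityMean,paralogIdentitySd named per-group protein
#'   identity distribution of the representative paralog (percent).
#' @param pXParalog named per-group probability that the representative
#'   paralog is X-linked.
#' @param snpRate named per-group expected SNPs per kb of coding sequence.
#' @param codonDeletionRate per-codon probability of a whole-codon deletion
#'   in one tip sequence (default 0: no indels).
#' @param seed integer seed; identical seeds give identical outputs.
#' @return list of class \code{"simulationSpec"}.
#' @export
simulationSpec <- function(
    nGenes = c(maternal = 26L, paternal = 27L, background = 120L),
    codons = 150L,
    treeLengths = c(human = 0.35, cow = 0.35, mouse = 0.10, rat = 0.12,
                    ancestor = 0.15),
    kappa = 2,
    omega = c(maternal = 0.161, paternal = 0.136, background = 0.129),
    omegaForeground = NULL,
    cpgBias = 1,
    paralogProb = c(maternal = 0.607, paternal = 0.607, background = 0.482),
    paralogIdentityMean = c(maternal = 47.12, paternal = 47.12,
                            background = 56.85),
    paralogIdentitySd = c(maternal = 15.24, paternal = 15.24,
                          background = 22.73),
    pXParalog = c(maternal = 0.088, paternal = 0.088, background = 0.03),
    snpRate = c(maternal = 2.4, paternal = 2.4, background = 3.6),
    codonDeletionRate = 0,
    seed = 1L) {
  if (is.null(omegaForeground)) omegaForeground <- omega
  spec <- list(nGenes = nGenes, codons = codons, treeLengths = treeLengths,
               kappa = kappa, omega = omega,
               omegaForeground = omegaForeground, cpgBias = cpgBias,
               paralogProb = paralogProb,
               paralogIdentityMean = paralogIdentityMean,
               paralogIdentitySd = paralogIdentitySd,
               pXParalog = pXParalog, snpRate = snpRate,
               codonDeletionRate = codonDeletionRate, seed = as.integer(seed))
  stopifnot(all(spec$treeLengths >= 0), spec$kappa > 0, all(spec$omega > 0),
            all(spec$paralogProb >= 0 & spec$paralogProb <= 1),
            spec$codonDeletionRate >= 0 && spec$codonDeletionRate <= 1)
  class(spec) <- "simulationSpec"
  spec
}

## root codon distribution, optionally enriched for CpG-forming codons
## (third-position C and first-position G), biasing codon-boundary CpGs
.rootFreqs <- function(cpgBias) {
  codons <- senseCodons()
  w <- rep(1, length(codons))
  w[substr(codons, 3, 3) == "C"] <- w[substr(codons, 3, 3) == "C"] * cpgBias
  w[substr(codons, 1, 1) == "G"] <- w[substr(codons, 1, 1) == "G"] * cpgBias
  w / sum(w)
}

## sample child codon states given parent states and a transition matrix
.evolve <- function(states, P) {
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = P[s, ])
  }
  out
}

#' Simulate a codon quartet along the fixed tree
#'
#' Draws a root codon sequence (no stop codons) and evolves it along the
#' unrooted quartet by sampling from the same scaled rate matrix the
#' likelihood uses: background omega on the four terminal branches, the
#' foreground omega on the rodent-ancestor branch.  Uses the current RNG
#' state (seed via \code{set.seed} or \code{\link{simulateGeneTables}}).
#'
#' @param nCodons number of codons.
#' @param treeLengths named branch lengths (substitutions/codon).
#' @param kappa transition/transversion ratio.
#' @param omega background omega.
#' @param omegaForeground foreground (rodent-ancestor) omega.
#' @param cpgBias root CpG enrichment factor.
#' @param codonDeletionRate per-codon whole-codon deletion probability
#'   applied to the mouse tip (default 0).
#' @return list with \code{sequences} (named character: human, mouse, rat,
#'   cow) and \code{truth} (the generating parameters).
#' @export
simulateQuartet <- function(nCodons, treeLengths, kappa, omega,
                            omegaForeground = omega, cpgBias = 1,
                            codonDeletionRate = 0) {
  codons <- senseCodons()
  decBg <- .eigenQ(codonRateMatrix(kappa, omega))
  decFg <- if (omegaForeground == omega) decBg else
    .eigenQ(codonRateMatrix(kappa, omegaForeground))
  root <- sample.int(length(codons), nCodons, replace = TRUE,
                     prob = .rootFreqs(cpgBias))
  b <- treeLengths
  junction <- root
  human <- .evolve(junction, .probMatrix(decBg, b["human"]))
  cow <- .evolve(junction, .probMatrix(decBg, b["cow"]))
  anc <- .evolve(junction, .probMatrix(decFg, b["ancestor"]))
  mouse <- .evolve(anc, .probMatrix(decBg, b["mouse"]))
  rat <- .evolve(anc, .probMatrix(decBg, b["rat"]))
  toSeq <- function(idx) paste(codons[idx], collapse = "")
  seqs <- c(human = toSeq(human), mouse = toSeq(mouse), rat = toSeq(rat),
            cow = toSeq(cow))
  if (codonDeletionRate > 0) {
    del <- stats::runif(nCodons) < codonDeletionRate
    if (any(del) && sum(!del) >= 10) {
      seqs["mouse"] <- paste(codons[mouse][!del], collapse = "")
    }
  }
  list(sequences = seqs,
       truth = list(treeLengths = b, kappa = kappa, omega = omega,
                    omegaForeground = omegaForeground, rootStates = root))
}

#' Simulate all pipeline input tables
#'
#' For every gene, evolves a quartet under its group's parameters and runs
#' the real alignment and divergence stages (protein alignment,
#' back-translation, percent identities, Nei-Gojobori Ka/Ks) to produce
#' HomoloGene-like gene-pair records for the human-mouse, human-rat and
#' mouse-rat pairs; paralog and SNP tables are drawn from the spec
#' distributions and group labels attached.  Deterministic given the spec
#' seed.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{sequences} (named character vector,
#'   \code{gene|species}), \code{pairs}, \code{paralogs}, \code{snps},
#'   \code{groups} (data.frames in the reader layouts) and \code{truth}.
#' @export
simulateGeneTables <- function(spec) {
  stopifnot(inherits(spec, "simulationSpec"))
  .withSeed(spec$seed, function() .simulateGeneTablesImpl(spec))
}

.simulateGeneTablesImpl <- function(spec) {
  groups <- rep(names(spec$nGenes), spec$nGenes)
  ids <- sprintf("g%03d", seq_along(groups))
  allSeqs <- character(0)
  pairRows <- list(); paralogRows <- list(); snpRows <- list()
  truth <- list()
  pairsOf <- rbind(c("human", "mouse"), c("human", "rat"), c("mouse", "rat"))
  for (k in seq_along(ids)) {
    g <- ids[k]; grp <- groups[k]
    sim <- simulateQuartet(spec$codons, spec$treeLengths, spec$kappa,
                           spec$omega[[grp]], spec$omegaForeground[[grp]],
                           spec$cpgBias, spec$codonDeletionRate)
    truth[[g]] <- sim$truth
    sq <- sim$sequences
    names(sq) <- paste(g, names(sq), sep = "|")
    allSeqs <- c(allSeqs, sq)
    for (r in seq_len(nrow(pairsOf))) {
      sa <- pairsOf[r, 1]; sb <- pairsOf[r, 2]
      bca <- buildCodonAlignment(sim$sequences[[sa]], sim$sequences[[sb]],
                                 geneId = g, species = c(sa, sb))
      kk <- neiGojobori(bca$codon)
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        gene_id = g, species_a = sa, species_b = sb,
        protein_identity = percentIdentity(bca$protein),
        cdna_identity = percentIdentity(bca$codon),
        gap_count = countGaps(bca$protein),
        ka = kk@Ka, ks = kk@Ks, ks_discarded = FALSE,
        ka_ks = kk@kaKs, stringsAsFactors = FALSE)
    }
    ## paralog structure
    if (stats::runif(1) < spec$paralogProb[[grp]]) {
      nPar <- 1L + stats::rpois(1, 1)
      idn <- pmin(pmax(stats::rnorm(
        nPar, spec$paralogIdentityMean[[grp]],
        spec$paralogIdentitySd[[grp]]), 5), 100)
      onX <- stats::runif(nPar) < spec$pXParalog[[grp]]
      chrom <- ifelse(onX, "X", as.character(sample.int(22, nPar,
                                                        replace = TRUE)))
      paralogRows[[length(paralogRows) + 1L]] <- data.frame(
        gene_id = g, paralog_id = sprintf("%s_p%d", g, seq_len(nPar)),
        rank = seq_len(nPar), paralog_chromosome = chrom,
        protein_identity = sort(idn, decreasing = TRUE),
        stringsAsFactors = FALSE)
    }
    ## SNP tables describe annotation-scale coding lengths (median ~1.4 kb),
    ## not the short simulated quartets, so densities are not over-discretised
    lenCodons <- min(max(round(stats::rlnorm(1, log(480), 0.4)), 120), 2000)
    len <- 3L * lenCodons
    snpRows[[length(snpRows) + 1L]] <- data.frame(
      gene_id = g, coding_length_bp = len,
      snp_count = stats::rpois(1, spec$snpRate[[grp]] * len / 1000))
  }
  paralogs <- if (length(paralogRows)) do.call(rbind, paralogRows) else
    data.frame(gene_id = character(0), paralog_id = character(0),
               rank = integer(0), paralog_chromosome = character(0),
               protein_identity = numeric(0))
  groupsDf <- data.frame(gene_id = ids, group = groups,
                         has_paralog = ids %in% paralogs$gene_id,
                         stringsAsFactors = FALSE)
  list(sequences = allSeqs,
       pairs = do.call(rbind, pairRows),
       paralogs = paralogs,
       snps = do.call(rbind, snpRows),
       groups = groupsDf,
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes the FASTA and the four TSV tables of a
#' \code{\link{simulateGeneTables}} result into a directory; byte-identical
#' for identical specs.
#'
#' @param sim result of \code{\link{simulateGeneTables}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "sequences.fa"),
    pairs = file.path(dir, "pairs.tsv"),
    paralogs = file.path(dir, "paralogs.tsv"),
    snps = file.path(dir, "snps.tsv"),
    groups = file.path(dir, "groups.tsv"))
  writeCdsFasta(sim$sequences, paths["fasta"])
  writeGenePairTable(sim$pairs, paths["pairs"])
  writeParalogTable(sim$paralogs, paths["paralogs"])
  writeSnpTable(sim$snps, paths["snps"])
  writeGroupFile(sim$groups, paths["groups"])
  invisible(paths)
}

#' Tiny deterministic toy dataset
#'
#' Six genes (two per group) of 30 codons each, generated from a fixed seed;
#' the bundled copy under \code{inst/extdata/toy} is byte-identical to the
#' output of this function and is used by documentation and smoke tests.
#' Constructed so that triangulation is applicable for all six genes.
#'
#' @param dir if non-NULL, also write the dataset there.
#' @return The \code{\link{simulateGeneTables}} result list.
#' @export
fixtureToyDataset <- function(dir = NULL) {
  spec <- simulationSpec(
    nGenes = c(maternal = 2L, paternal = 2L, background = 2L),
    codons = 30L, seed = 6L)
  sim <- simulateGeneTables(spec)
  if (!is.null(dir)) writeSimulatedData(sim, dir)
  sim
}
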