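## Per-gene-pair divergence statistics computed on codon/protein alignments:
## percent identity, indel-event counts, Nei-Gojobori Ka/Ks with Jukes-Cantor
## correction, silent CpG->TpG mutability at third codon positions, and SNP
## density.

.alnPair <- function(alignment) {
  rows <- if (methods::is(alignment, "ProteinAlignment") ||
              methods::is(alignment, "CodonAlignment")) {
    alignment@rows
  } else {
    alignment
  }
  if (length(rows) != 2) stop("pairwise statistic needs exactly two rows")
  rows
}

#' Percent identity of a pairwise alignment
#'
#' 100 x (identical non-gap columns) / denominator.  By default the
#' denominator is the total number of alignment columns, so gap columns count
#' as mismatches; set \code{denominator = "ungapped"} to divide by gap-free
#' columns only.
#'
#' @param alignment a \linkS4class{ProteinAlignment},
#'   \linkS4class{CodonAlignment} or 2-vector of aligned strings.
#' @param denominator \code{"all_columns"} (default) or \code{"ungapped"}.
#' @return Percent identity in [0, 100]; symmetric in the two rows.
#' @export
percentIdentity <- function(alignment,
                            denominator = c("all_columns", "ungapped")) {
  denominator <- match.arg(denominator)
  rows <- .alnPair(alignment)
  a <- strsplit(rows[1], "")[[1]]
  b <- strsplit(rows[2], "")[[1]]
  nongap <- a != "-" & b != "-"
  ident <- sum(nongap & a == b)
  denom <- if (denominator == "all_columns") length(a) else sum(nongap)
  if (denom == 0) stop("empty alignment")
  100 * ident / denom
}

#' Number of indel events in an alignment
#'
#' Counts maximal gap runs (insertion/deletion events) over all rows, not gap
#' columns; a single 3-residue deletion counts once.
#'
#' @param alignment alignment object or character vector of aligned rows.
#' @param unit \code{"events"} (default) or \code{"columns"}.
#' @return Non-negative integer.
#' @export
countGaps <- function(alignment, unit = c("events", "columns")) {
  unit <- match.arg(unit)
  rows <- if (methods::is(alignment, "ProteinAlignment") ||
              methods::is(alignment, "CodonAlignment")) alignment@rows else alignment
  runs <- regmatches(rows, gregexpr("-+", rows))
  if (unit == "events") {
    sum(lengths(runs))
  } else {
    sum(nchar(unlist(runs)))
  }
}

#' Nei-Gojobori Ka/Ks estimation on a pairwise codon alignment
#'
#' Counting method: per-codon synonymous site fractions from the standard
#' genetic code (averaged over the two sequences), observed differences
#' averaged over all minimal mutational pathways with pathways through stop
#' codons excluded, and the Jukes-Cantor correction
#' \eqn{d = -3/4 \log(1 - 4p/3)} applied to pS and pN.  Codon columns
#' containing a gap or \code{N} are skipped.  When pS or pN reaches 3/4 the
#' correction diverges and the result is flagged saturated.
#'
#' @param ca a \linkS4class{CodonAlignment} with two rows (or a 2-vector of
#'   aligned DNA strings).
#' @return A \linkS4class{KaKsResult}.
#' @export
neiGojobori <- function(ca) {
  rows <- .alnPair(ca)
  n <- nchar(rows[1])
  if (n != nchar(rows[2]) || n %% 3 != 0) stop("invalid codon alignment")
  starts <- seq(1, n, 3)
  codA <- substring(rows[1], starts, starts + 2)
  codB <- substring(rows[2], starts, starts + 2)
  codons <- senseCodons()
  usable <- codA %in% codons & codB %in% codons
  ## gap- or N-containing columns are skipped; anything else unexpected left
  ## in a sense-codon alphabet would be a data error upstream
  codA <- codA[usable]; codB <- codB[usable]
  if (length(codA) == 0) stop("no comparable codon columns")
  sites <- ngSiteCounts()
  S <- (sum(sites[codA]) + sum(sites[codB])) / 2
  N <- 3 * length(codA) - S
  pc <- ngPairCounts()
  Sd <- sum(pc$sd[cbind(codA, codB)])
  Nd <- sum(pc$nd[cbind(codA, codB)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- is.na(Ks) || is.na(Ka)
  kaKs <- if (!saturated && Ks > 0) Ka / Ks else NA_real_
  methods::new("KaKsResult", S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
               Ka = Ka, Ks = Ks, kaKs = kaKs, saturated = saturated,
               codons = length(codA))
}

#' Silent CpG mutability of a pairwise codon alignment
#'
#' Examines every codon-boundary dinucleotide (third position of codon i plus
#' first position of codon i+1) in both sequences.  A site counts as CpG-CpG
#' when both sequences carry CpG; it counts as CpG-TpG when one sequence
#' carries CpG, the other TpG, and replacing the C by T at that third codon
#' position leaves the encoded amino acid unchanged (a silent deamination
#' signature).  Sites touching an alignment gap are skipped.
#'
#' The mutability index is n_CpG-TpG / (n_CpG-CpG + n_CpG-TpG), i.e. the
#' TpG-mismatch fraction of all silent third-position CpG contexts; the raw
#' ratio n_CpG-TpG / n_CpG-CpG is also reported.
#'
#' @param ca a \linkS4class{CodonAlignment} with two rows.
#' @return list with \code{n_cpg_cpg}, \code{n_cpg_tpg},
#'   \code{mutability_index} (NA when no context observed) and \code{ratio}
#'   (NA when no conserved CpG observed).
#' @export
silentCpgMutability <- function(ca) {
  rows <- .alnPair(ca)
  n <- nchar(rows[1])
  if (n %% 3 != 0) stop("invalid codon alignment")
  a <- strsplit(rows[1], "")[[1]]
  b <- strsplit(rows[2], "")[[1]]
  nCodon <- n / 3
  cpgCpg <- 0L; cpgTpg <- 0L
  silentCT <- function(chars, codStart) {
    cod <- paste(chars[codStart:(codStart + 2)], collapse = "")
    if (grepl("[^ACGT]", cod)) return(FALSE)
    alt <- cod
    substr(alt, 3, 3) <- "T"
    !.isStopCodon(alt) && .codonAA(alt) == .codonAA(cod)
  }
  for (i in seq_len(nCodon - 1)) {
    p3 <- 3 * i          # third position of codon i
    p1 <- 3 * i + 1      # first position of codon i+1
    codStart <- p3 - 2
    quad <- c(a[codStart:p1], b[codStart:p1])
    if (any(quad == "-") || any(!quad %in% c("A", "C", "G", "T"))) next
    dinA <- paste0(a[p3], a[p1])
    dinB <- paste0(b[p3], b[p1])
    if (dinA == "CG" && dinB == "CG") {
      cpgCpg <- cpgCpg + 1L
    } else if (dinA == "CG" && dinB == "TG") {
      if (silentCT(a, codStart)) cpgTpg <- cpgTpg + 1L
    } else if (dinA == "TG" && dinB == "CG") {
      if (silentCT(b, codStart)) cpgTpg <- cpgTpg + 1L
    }
  }
  tot <- cpgCpg + cpgTpg
  list(n_cpg_cpg = cpgCpg, n_cpg_tpg = cpgTpg,
       mutability_index = if (tot > 0) cpgTpg / tot else NA_real_,
       ratio = if (cpgCpg > 0) cpgTpg / cpgCpg else NA_real_)
}

#' SNP density per kb of coding sequence
#'
#' @param codingLengthBp positive coding-sequence length(s) in bp.
#' @param snpCount non-negative SNP count(s).
#' @return SNPs per kb (vectorised).
#' @export
snpDensity <- function(codingLengthBp, snpCount) {
  if (any(codingLengthBp <= 0)) stop("coding length must be positive")
  if (any(snpCount < 0)) stop("negative SNP count")
  snpCount / (codingLengthBp / 1000)
}

#' Per-gene-pair divergence table
#'
#' Runs the full pairwise stage for a set of coding sequences: codon-aware
#' alignment, identities at protein and cDNA level, indel events,
#' Nei-Gojobori Ka/Ks and silent CpG mutability, optionally joined with SNP
#' densities.
#'
#' @param cds a \link[Biostrings]{DNAStringSet} as returned by
#'   \code{\link{readCdsFasta}} (mcols \code{gene_id}, \code{species}).
#' @param pairs data.frame with columns \code{gene_id}, \code{species_a},
#'   \code{species_b} selecting which pairs to align; default all species
#'   pairs within each gene.
#' @param snps optional SNP data.frame (from \code{\link{readSnpTable}}).
#' @param ... passed to \code{\link{buildCodonAlignment}}.
#' @return data.frame, one row per gene pair, in gene-pair-table layout
#'   (see \code{\link{readGenePairTable}}) plus CpG columns.
#' @export
divergenceTable <- function(cds, pairs = NULL, snps = NULL, ...) {
  mc <- S4Vectors::mcols(cds)
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(split(as.data.frame(mc), mc$gene_id),
      function(d) {
        if (nrow(d) < 2) return(NULL)
        cmb <- utils::combn(sort(d$species), 2)
        data.frame(gene_id = d$gene_id[1], species_a = cmb[1, ],
                   species_b = cmb[2, ])
      }))
    rownames(pairs) <- NULL
  }
  seqOf <- function(g, s) {
    i <- which(mc$gene_id == g & mc$species == s)
    if (length(i) != 1) stop("need exactly one sequence for ", g, "/", s)
    as.character(cds[[i]])
  }
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    g <- pairs$gene_id[r]; sa <- pairs$species_a[r]; sb <- pairs$species_b[r]
    bca <- buildCodonAlignment(seqOf(g, sa), seqOf(g, sb), geneId = g,
                               species = c(sa, sb), ...)
    kk <- neiGojobori(bca$codon)
    cpg <- silentCpgMutability(bca$codon)
    data.frame(gene_id = g, species_a = sa, species_b = sb,
               protein_identity = percentIdentity(bca$protein),
               cdna_identity = percentIdentity(bca$codon),
               gap_count = countGaps(bca$protein),
               ka = kk@Ka, ks = kk@Ks, ka_ks = kk@kaKs,
               ks_discarded = FALSE,
               n_cpg_cpg = cpg$n_cpg_cpg, n_cpg_tpg = cpg$n_cpg_tpg,
               cpg_mutability = cpg$mutability_index)
  })
  res <- do.call(rbind, out)
  if (!is.null(snps)) {
    res$snp_density <- snps$snp_density[match(res$gene_id, snps$gene_id)]
  }
  res
}
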