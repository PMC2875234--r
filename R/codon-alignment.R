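## Codon-aware alignment: the transAlign-style procedure of extracting the
## longest open reading frame, aligning at the protein level and
## back-translating to DNA so that gaps can never shift the reading frame.

#' Longest open reading frame
#'
#' Scans the three forward frames for ATG-initiated, stop-terminated open
#' reading frames and returns the longest one with the stop codon trimmed.
#' Ties are broken by the leftmost start position.
#'
#' @param dna character string over \code{A,C,G,T,N} (length >= 3).
#' @return The ORF sequence (without the stop codon).
#' @export
longestOrf <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) < 3 || grepl("[^ACGTN]", dna)) {
    stop("input must be a DNA string over {A,C,G,T,N} of length >= 3")
  }
  best <- NULL; bestLen <- -1L; bestStart <- Inf
  n <- nchar(dna)
  for (frame in 0:2) {
    starts <- seq(1 + frame, n - 2, by = 3)
    if (length(starts) == 0) next
    cods <- substring(dna, starts, starts + 2)
    isStart <- cods == "ATG"
    isStop <- cods %in% c("TAA", "TAG", "TGA")
    open <- NA_integer_
    for (k in seq_along(cods)) {
      if (is.na(open) && isStart[k]) open <- k
      if (!is.na(open) && isStop[k]) {
        len <- 3L * (k - open)
        startPos <- starts[open]
        if (len > bestLen || (len == bestLen && startPos < bestStart)) {
          best <- substr(dna, startPos, starts[k] - 1L)
          bestLen <- len
          bestStart <- startPos
        }
        open <- NA_integer_
      }
    }
  }
  if (is.null(best)) stop("no open reading frame found")
  best
}

#' Translate a coding sequence
#'
#' Standard genetic code; codons containing ambiguity characters translate to
#' \code{X}.  The sequence must be in frame (length a multiple of three, no
#' internal stop).
#'
#' @param cds character string over \code{A,C,G,T,N}.
#' @return Amino-acid string.
#' @export
translateCds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("coding sequence length not a multiple of 3")
  if (!.frameOk(cds)) stop("coding sequence fails frame validation")
  n <- nchar(cds)
  aa <- Biostrings::GENETIC_CODE[substring(cds, seq(1, n, 3), seq(3, n, 3))]
  aa[is.na(aa)] <- "X"  # ambiguous codons
  paste(aa, collapse = "")
}

#' Global protein alignment
#'
#' Optimal Needleman-Wunsch global alignment with affine gap penalties under a
#' named substitution matrix (the pairwise step that a progressive aligner
#' such as ClustalW performs for two sequences), computed by
#' \code{\link[Biostrings]{pairwiseAlignment}}.
#'
#' @param p1,p2 amino-acid strings.
#' @param geneId gene identifier attached to the result.
#' @param species character vector of length 2 naming the rows.
#' @param matrixName substitution matrix (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend affine gap penalties (positive costs; a gap of
#'   length L costs \code{gapOpen + L * gapExtend}).
#' @return A \linkS4class{ProteinAlignment}.
#' @export
alignProteins <- function(p1, p2, geneId = "gene",
                          species = c("a", "b"),
                          matrixName = "BLOSUM62",
                          gapOpen = 10, gapExtend = 0.5) {
  if (nchar(p1) == 0 || nchar(p2) == 0) stop("empty protein sequence")
  key <- paste0("submat_", matrixName)
  mat <- .codonCache[[key]]
  if (is.null(mat)) {
    mat <- tryCatch(
      get(data(list = matrixName, package = "Biostrings",
               envir = environment())),
      warning = function(w) stop("unknown substitution matrix: ", matrixName),
      error = function(e) stop("unknown substitution matrix: ", matrixName))
    .codonCache[[key]] <- mat
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2), type = "global",
    substitutionMatrix = mat, gapOpening = gapOpen, gapExtension = gapExtend)
  methods::new("ProteinAlignment", geneId = geneId, species = species,
               rows = c(as.character(Biostrings::alignedPattern(aln)),
                        as.character(Biostrings::alignedSubject(aln))),
               score = Biostrings::score(aln))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue is replaced by its source codon and each gap by \code{---},
#' so gap runs are always multiples of three and removing the gaps recovers
#' the input coding sequences exactly.
#'
#' @param pa a \linkS4class{ProteinAlignment}.
#' @param cds named character vector of the ungapped coding sequences, one per
#'   alignment row, in row order; each must translate to the corresponding
#'   ungapped protein row.
#' @return A \linkS4class{CodonAlignment}.
#' @export
backtranslate <- function(pa, cds) {
  stopifnot(methods::is(pa, "ProteinAlignment"))
  if (length(cds) != length(pa@rows)) {
    stop("need one coding sequence per alignment row")
  }
  rows <- character(length(pa@rows))
  for (k in seq_along(pa@rows)) {
    prot <- gsub("-", "", pa@rows[k], fixed = TRUE)
    if (!identical(translateCds(cds[[k]]), prot)) {
      stop("coding sequence for row ", k, " (", pa@species[k],
           ") does not translate to its protein row")
    }
    n <- nchar(cds[[k]])
    codons <- substring(cds[[k]], seq(1, n, 3), seq(3, n, 3))
    chars <- strsplit(pa@rows[k], "")[[1]]
    out <- character(length(chars))
    ci <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        ci <- ci + 1L
        out[i] <- codons[ci]
      }
    }
    rows[k] <- paste(out, collapse = "")
  }
  methods::new("CodonAlignment", geneId = pa@geneId, species = pa@species,
               rows = rows)
}

#' Pairwise codon alignment of two coding sequences
#'
#' Convenience wrapper chaining \code{\link{translateCds}},
#' \code{\link{alignProteins}} and \code{\link{backtranslate}}.
#'
#' @inheritParams alignProteins
#' @param cdsA,cdsB in-frame coding sequences.
#' @return list with elements \code{protein} (\linkS4class{ProteinAlignment})
#'   and \code{codon} (\linkS4class{CodonAlignment}).
#' @export
buildCodonAlignment <- function(cdsA, cdsB, geneId = "gene",
                                species = c("a", "b"), ...) {
  pa <- alignProteins(translateCds(cdsA), translateCds(cdsB),
                      geneId = geneId, species = species, ...)
  list(protein = pa, codon = backtranslate(pa, c(cdsA, cdsB)))
}

## Star alignment of several coding sequences to a designated reference
## (default human): each non-reference sequence is aligned pairwise to the
## reference at the protein level and the reference-row gap patterns are
## merged ("once a gap, always a gap" relative to the reference).  Adequate
## for the fixed 4-taxon quartet; not a progressive multiple aligner.

#' Star codon alignment of a sequence quartet
#'
#' @param cds named character vector of in-frame coding sequences (names are
#'   species); must include \code{reference}.
#' @param geneId gene identifier.
#' @param reference species used as the star centre (default \code{"human"}).
#' @param ... passed to \code{\link{alignProteins}}.
#' @return A \linkS4class{CodonAlignment} with one row per input sequence,
#'   reference first.
#' @export
alignQuartet <- function(cds, geneId = "gene", reference = "human", ...) {
  if (!reference %in% names(cds)) stop("reference species missing: ", reference)
  others <- setdiff(names(cds), reference)
  prots <- vapply(cds, translateCds, character(1))
  nref <- nchar(prots[[reference]])
  ## per-slot insert lengths: slot p (0..nref) sits before reference residue p+1
  ins <- matrix(0L, nrow = length(others), ncol = nref + 1,
                dimnames = list(others, NULL))
  alns <- list()
  for (sp in others) {
    pa <- alignProteins(prots[[reference]], prots[[sp]], geneId = geneId,
                        species = c(reference, sp), ...)
    refRow <- strsplit(pa@rows[1], "")[[1]]
    slot <- cumsum(refRow != "-")           # residue index each column belongs after
    gapCols <- refRow == "-"
    if (any(gapCols)) {
      tab <- table(slot[gapCols])
      ins[sp, as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    alns[[sp]] <- pa
  }
  mergedIns <- apply(ins, 2, max)
  ## build merged rows residue-slot by residue-slot
  buildRow <- function(residues, myIns, perSlotChunks) {
    out <- character(0)
    for (p in 0:nref) {
      chunk <- perSlotChunks[[p + 1]]
      pad <- mergedIns[p + 1] - nchar(chunk)
      out <- c(out, chunk, strrep("-", pad))
      if (p < nref) out <- c(out, residues[p + 1])
    }
    paste(out, collapse = "")
  }
  refResidues <- strsplit(prots[[reference]], "")[[1]]
  refChunks <- as.list(rep("", nref + 1))
  mergedRows <- stats::setNames(character(length(cds)), c(reference, others))
  mergedRows[reference] <- buildRow(refResidues, 0L, refChunks)
  for (sp in others) {
    pa <- alns[[sp]]
    refRow <- strsplit(pa@rows[1], "")[[1]]
    spRow <- strsplit(pa@rows[2], "")[[1]]
    slot <- cumsum(refRow != "-")
    chunks <- as.list(rep("", nref + 1))
    resid <- character(nref)
    for (i in seq_along(refRow)) {
      if (refRow[i] == "-") {
        s <- slot[i] + 1L
        chunks[[s]] <- paste0(chunks[[s]], spRow[i])
      } else {
        resid[slot[i]] <- spRow[i]
      }
    }
    mergedRows[sp] <- buildRow(resid, 0L, chunks)
  }
  pa <- methods::new("ProteinAlignment", geneId = geneId,
                     species = names(mergedRows),
                     rows = unname(mergedRows), score = NA_real_)
  backtranslate(pa, cds[names(mergedRows)])
}
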