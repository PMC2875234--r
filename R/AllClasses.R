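## Central S4 containers.  Alignments carry their rows as plain character
## vectors (one string per species); divergence statistics and model fits are
## small value objects with validity checks.

#' ProteinAlignment class
#'
#' A gap-aware global protein alignment of two or more sequences for one gene.
#' Rows are equal-length strings over the amino-acid alphabet plus \code{-};
#' no column may be all gaps.
#'
#' @slot geneId gene identifier.
#' @slot species character vector naming each row's species.
#' @slot rows aligned sequences, one per species.
#' @slot score alignment score in substitution-matrix units (\code{NA} for
#'   alignments not produced by a scoring alignment, e.g. merged star rows).
#' @export
setClass("ProteinAlignment",
  representation(geneId = "character", species = "character",
                 rows = "character", score = "numeric"))

setValidity("ProteinAlignment", function(object) {
  if (length(object@rows) < 2) return("need at least two rows")
  if (length(object@rows) != length(object@species))
    return("species and rows lengths differ")
  if (length(unique(nchar(object@rows))) != 1) return("rows of unequal length")
  m <- do.call(rbind, strsplit(object@rows, ""))
  if (any(colSums(m == "-") == nrow(m))) return("all-gap column")
  TRUE
})

#' CodonAlignment class
#'
#' A frameshift-free codon alignment derived from a protein alignment by
#' back-translation: rows are equal-length strings over \code{A,C,G,T,-},
#' every gap run has length a multiple of three, and removing gaps recovers
#' the original coding sequences.
#'
#' @slot geneId gene identifier.
#' @slot species character vector naming each row's species.
#' @slot rows aligned coding sequences, one per species.
#' @export
setClass("CodonAlignment",
  representation(geneId = "character", species = "character",
                 rows = "character"))

setValidity("CodonAlignment", function(object) {
  if (length(object@rows) < 2) return("need at least two rows")
  if (length(object@rows) != length(object@species))
    return("species and rows lengths differ")
  w <- unique(nchar(object@rows))
  if (length(w) != 1) return("rows of unequal length")
  if (w %% 3 != 0) return("alignment width not a multiple of 3")
  if (any(grepl("[^ACGTN-]", object@rows))) return("invalid characters")
  runs <- regmatches(object@rows, gregexpr("-+", object@rows))
  if (any(unlist(lapply(runs, nchar)) %% 3 != 0))
    return("gap run length not a multiple of 3")
  TRUE
})

#' KaKsResult class
#'
#' Nei-Gojobori counting estimates for one pairwise codon alignment:
#' synonymous (S) and nonsynonymous (N) site totals, observed difference
#' counts (Sd, Nd), proportions pS/pN, Jukes-Cantor corrected rates Ks/Ka,
#' their ratio, and a saturation flag (set when pS or pN >= 3/4, where the
#' correction diverges).
#'
#' @slot S,N synonymous / nonsynonymous sites (averaged over both sequences).
#' @slot Sd,Nd pathway-averaged synonymous / nonsynonymous differences.
#' @slot pS,pN proportions of differences per site.
#' @slot Ka,Ks corrected rates; \code{NA} when saturated.
#' @slot kaKs Ka/Ks; \code{NA} when Ks is 0, missing or saturated.
#' @slot saturated logical saturation flag.
#' @slot codons number of comparable (gap- and N-free) codon columns.
#' @export
setClass("KaKsResult",
  representation(S = "numeric", N = "numeric", Sd = "numeric", Nd = "numeric",
                 pS = "numeric", pN = "numeric", Ka = "numeric", Ks = "numeric",
                 kaKs = "numeric", saturated = "logical", codons = "integer"))

setValidity("KaKsResult", function(object) {
  if (object@S < 0 || object@N < 0) return("negative site counts")
  ## pS = Sd/S can exceed 1 on very short alignments (fractional sites);
  ## the Jukes-Cantor correction is then undefined and the result saturated
  if (!is.na(object@pS) && object@pS < 0) return("negative pS")
  if (!is.na(object@pN) && object@pN < 0) return("negative pN")
  if (abs(object@S + object@N - 3 * object@codons) > 1e-9)
    return("S + N must equal 3 x compared codons")
  TRUE
})

#' QuartetTree class
#'
#' The fixed unrooted 4-taxon tree (human,(mouse,rat),cow) used by the codon
#' branch models.  Five branches: the four terminal branches and the internal
#' branch leading to the mouse-rat common ancestor, which is the foreground
#' branch of the two-ratios model.
#'
#' @slot lengths named numeric of 5 branch lengths (expected substitutions
#'   per codon): \code{human}, \code{cow}, \code{mouse}, \code{rat},
#'   \code{ancestor}.
#' @slot foreground name of the foreground branch (always \code{"ancestor"}).
#' @export
setClass("QuartetTree",
  representation(lengths = "numeric", foreground = "character"))

.QUARTET_BRANCHES <- c("human", "cow", "mouse", "rat", "ancestor")

setValidity("QuartetTree", function(object) {
  if (!identical(sort(names(object@lengths)), sort(.QUARTET_BRANCHES)))
    return("branch lengths must be named human, cow, mouse, rat, ancestor")
  if (any(object@lengths < 0)) return("negative branch length")
  if (!identical(object@foreground, "ancestor"))
    return("foreground branch is fixed to the rodent-ancestor branch")
  TRUE
})

#' BranchModelFit class
#'
#' Maximum-likelihood fit of a codon branch model on the quartet.
#'
#' @slot model \code{"one_ratio"} or \code{"two_ratios"}.
#' @slot lnL maximised log-likelihood.
#' @slot kappa fitted transition/transversion ratio.
#' @slot omegaBackground fitted background Ka/Ks.
#' @slot omegaForeground fitted foreground (rodent-ancestor) Ka/Ks; equals
#'   \code{omegaBackground} under the one-ratio model.
#' @slot tree fitted \linkS4class{QuartetTree}.
#' @slot converged optimiser convergence flag.
#' @slot kaPerBranch,ksPerBranch branch lengths converted to nonsynonymous /
#'   synonymous substitutions per site under the fitted model.
#' @slot codons number of usable codon columns.
#' @export
setClass("BranchModelFit",
  representation(model = "character", lnL = "numeric", kappa = "numeric",
                 omegaBackground = "numeric", omegaForeground = "numeric",
                 tree = "QuartetTree", converged = "logical",
                 kaPerBranch = "numeric", ksPerBranch = "numeric",
                 codons = "integer"))

setValidity("BranchModelFit", function(object) {
  if (!object@model %in% c("one_ratio", "two_ratios")) return("unknown model")
  if (object@kappa <= 0) return("kappa must be positive")
  if (object@omegaBackground <= 0 || object@omegaForeground <= 0)
    return("omega must be positive")
  TRUE
})

#' LrtResult class
#'
#' Likelihood-ratio comparison of the one-ratio and two-ratios branch models.
#' The statistic 2(lnL2 - lnL1) is clipped at zero; following the decision
#' rule used with codeml branch models, the foreground ratio is accepted as
#' different when the statistic reaches 2.71 (the 5\% point of the
#' half-and-half mixture of a point mass at zero and chi-squared with one
#' degree of freedom).
#'
#' @slot statistic clipped LRT statistic.
#' @slot significant logical decision at the 2.71 threshold.
#' @slot direction \code{"elevated"} or \code{"reduced"} foreground omega.
#' @slot threshold critical value used.
#' @export
setClass("LrtResult",
  representation(statistic = "numeric", significant = "logical",
                 direction = "character", threshold = "numeric"))

setValidity("LrtResult", function(object) {
  if (object@statistic < 0) return("statistic must be clipped at 0")
  if (!object@direction %in% c("elevated", "reduced", "equal"))
    return("unknown direction")
  TRUE
})

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @param object an imprintEvol S4 object.
#' @export
setGeneric("geneId", function(object) standardGeneric("geneId"))

#' Accessors for alignment and result objects
#'
#' \code{geneId}, \code{speciesNames} and \code{alignmentRows} extract the
#' gene identifier, the species labels and the aligned rows (named by
#' species).
#'
#' @name accessors
#' @aliases geneId speciesNames alignmentRows
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(object) standardGeneric("alignmentRows"))

for (cls in c("ProteinAlignment", "CodonAlignment")) {
  setMethod("geneId", cls, function(object) object@geneId)
  setMethod("speciesNames", cls, function(object) object@species)
  setMethod("alignmentRows", cls, function(object) {
    stats::setNames(object@rows, object@species)
  })
}

#' @describeIn accessors log-likelihood of a branch-model fit.
#' @export
setMethod("logLik", "BranchModelFit", function(object, ...) object@lnL)

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment of %s (%s), width %d, score %s\n",
              object@geneId, paste(object@species, collapse = "/"),
              nchar(object@rows[1]),
              format(object@score)))
})

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment of %s (%s), %d codon columns\n",
              object@geneId, paste(object@species, collapse = "/"),
              nchar(object@rows[1]) / 3))
})

setMethod("show", "KaKsResult", function(object) {
  cat(sprintf(paste0("KaKsResult: %d codons, S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
                     "  Ks=%s Ka=%s Ka/Ks=%s%s\n"),
              object@codons, object@S, object@N, object@Sd, object@Nd,
              format(object@Ks, digits = 4), format(object@Ka, digits = 4),
              format(object@kaKs, digits = 4),
              if (object@saturated) " [saturated]" else ""))
})

setMethod("show", "QuartetTree", function(object) {
  cat("QuartetTree (human,(mouse,rat)#1,cow); branch lengths:\n")
  print(round(object@lengths[.QUARTET_BRANCHES], 4))
})

setMethod("show", "BranchModelFit", function(object) {
  cat(sprintf(paste0("BranchModelFit [%s]: lnL=%.4f kappa=%.3f ",
                     "omega(bg)=%.4f omega(fg)=%.4f%s\n"),
              object@model, object@lnL, object@kappa, object@omegaBackground,
              object@omegaForeground,
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "LrtResult", function(object) {
  cat(sprintf("LRT: 2*dlnL = %.4f (threshold %.2f) -> %s, foreground omega %s\n",
              object@statistic, object@threshold,
              if (object@significant) "significant" else "not significant",
              object@direction))
})
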