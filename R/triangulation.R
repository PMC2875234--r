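## Triangulation of the human <-> mouse-rat-common-ancestor divergence from
## the three pairwise quantities (human-mouse, human-rat, mouse-rat).  Under
## distance additivity on the 3-taxon star, the path length from human to the
## rodent ancestor is (d_hs_mm + d_hs_rn - d_mm_rn) / 2.

#' Triangulate identity to the rodent ancestor
#'
#' Converts percent identities to divergences d = 100 - identity, places the
#' ancestor at the additive branch point and converts back.  The estimate is
#' applicable only when the rodents are more similar to each other than
#' either is to human (\code{mm_rn > hs_mm} and \code{mm_rn > hs_rn});
#' otherwise it is flagged inapplicable with a reason, never an error.
#'
#' @param hsMm,hsRn,mmRn pairwise percent identities (vectorised).
#' @return data.frame with \code{hs_rodent}, \code{applicable},
#'   \code{reason}.
#' @export
triangulateIdentity <- function(hsMm, hsRn, mmRn) {
  if (any(c(hsMm, hsRn, mmRn) < 0 | c(hsMm, hsRn, mmRn) > 100, na.rm = TRUE)) {
    stop("identities must lie in [0, 100]")
  }
  d <- ((100 - hsMm) + (100 - hsRn) - (100 - mmRn)) / 2
  est <- 100 - d
  applicable <- !is.na(hsMm) & !is.na(hsRn) & !is.na(mmRn) &
    mmRn > hsMm & mmRn > hsRn
  data.frame(
    hs_rodent = ifelse(applicable, est, NA_real_),
    applicable = applicable,
    reason = ifelse(applicable, "",
                    "rodent-rodent identity not higher than human-rodent"),
    stringsAsFactors = FALSE)
}

#' Triangulate a substitution rate to the rodent ancestor
#'
#' Additive estimate \code{(K_hs_mm + K_hs_rn - K_mm_rn) / 2}; inapplicable
#' when the rate between the two rodents exceeds either human-rodent rate.
#'
#' @param hsMm,hsRn,mmRn pairwise rates (Ka or Ks; vectorised, >= 0).
#' @return data.frame with \code{hs_rodent}, \code{applicable},
#'   \code{reason}.
#' @export
triangulateRate <- function(hsMm, hsRn, mmRn) {
  if (any(c(hsMm, hsRn, mmRn) < 0, na.rm = TRUE)) {
    stop("rates must be non-negative")
  }
  est <- (hsMm + hsRn - mmRn) / 2
  applicable <- !is.na(hsMm) & !is.na(hsRn) & !is.na(mmRn) &
    mmRn <= hsMm & mmRn <= hsRn
  data.frame(
    hs_rodent = ifelse(applicable, est, NA_real_),
    applicable = applicable,
    reason = ifelse(applicable, "",
                    "rodent-rodent rate higher than human-rodent"),
    stringsAsFactors = FALSE)
}

#' Per-gene triangulation table
#'
#' For every gene with all three species pairs (human-mouse, human-rat,
#' mouse-rat) present, triangulates protein identity, cDNA identity, Ka and
#' Ks to the rodent ancestor and forms Ka/Ks from the triangulated rates.
#' Genes lacking a pair are skipped with a logged reason; counts of
#' applicable and inapplicable genes per quantity are attached as the
#' \code{"counts"} attribute.
#'
#' @param pairs gene-pair data.frame (layout of
#'   \code{\link{readGenePairTable}}).
#' @return data.frame, one row per usable gene, columns
#'   \code{<quantity>} and \code{<quantity>_applicable} for each of
#'   \code{protein_identity}, \code{cdna_identity}, \code{ka}, \code{ks},
#'   plus \code{ka_ks}.
#' @export
triangulateTable <- function(pairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = ":")
  pairs$pair <- key(pairs$species_a, pairs$species_b)
  need <- c("human:mouse", "human:rat", "mouse:rat")
  byGene <- split(pairs, pairs$gene_id)
  skipped <- 0L
  rows <- lapply(byGene, function(d) {
    if (!all(need %in% d$pair)) {
      .logmsg("triangulateTable: skipping gene %s (missing %s pair)",
              d$gene_id[1], setdiff(need, d$pair)[1])
      skipped <<- skipped + 1L
      return(NULL)
    }
    get1 <- function(p, col) d[[col]][match(p, d$pair)]
    prot <- triangulateIdentity(get1(need[1], "protein_identity"),
                                get1(need[2], "protein_identity"),
                                get1(need[3], "protein_identity"))
    cdna <- triangulateIdentity(get1(need[1], "cdna_identity"),
                                get1(need[2], "cdna_identity"),
                                get1(need[3], "cdna_identity"))
    ka <- triangulateRate(get1(need[1], "ka"), get1(need[2], "ka"),
                          get1(need[3], "ka"))
    ksIn <- lapply(need, function(p) {
      v <- get1(p, "ks")
      disc <- get1(p, "ks_discarded")
      if (!is.null(disc) && isTRUE(disc)) NA_real_ else v
    })
    ks <- triangulateRate(ksIn[[1]], ksIn[[2]], ksIn[[3]])
    kaks <- if (ka$applicable && ks$applicable && !is.na(ks$hs_rodent) &&
                ks$hs_rodent > 0) ka$hs_rodent / ks$hs_rodent else NA_real_
    data.frame(gene_id = d$gene_id[1],
               protein_identity = prot$hs_rodent,
               protein_identity_applicable = prot$applicable,
               cdna_identity = cdna$hs_rodent,
               cdna_identity_applicable = cdna$applicable,
               ka = ka$hs_rodent, ka_applicable = ka$applicable,
               ks = ks$hs_rodent, ks_applicable = ks$applicable,
               ka_ks = kaks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  qty <- c("protein_identity", "cdna_identity", "ka", "ks")
  counts <- vapply(qty, function(q) {
    c(applicable = sum(out[[paste0(q, "_applicable")]]),
      inapplicable = sum(!out[[paste0(q, "_applicable")]]))
  }, numeric(2))
  attr(out, "counts") <- counts
  attr(out, "skipped") <- skipped
  out
}
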