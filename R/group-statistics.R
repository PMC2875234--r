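## Group-level analyses: representative homolog/paralog selection, per-group
## summary tables, rank-based comparisons, paralog enrichment and SNP-density
## reports.

#' Select the best homolog among several candidates
#'
#' When a gene has more than one homolog for a species pair, the record with
#' the highest protein identity is kept; exact ties are broken by the
#' lexicographically lowest gene id (then species, then row order), so the
#' choice is deterministic.
#'
#' @param candidates data.frame of gene-pair records.
#' @return Single-row data.frame.
#' @export
selectBestHomolog <- function(candidates) {
  if (nrow(candidates) == 0) stop("no candidate records")
  ord <- order(-candidates$protein_identity, candidates$gene_id,
               candidates$species_b)
  candidates[ord[1], , drop = FALSE]
}

#' Select the representative paralog
#'
#' The rank-1 (evolutionarily most recent) paralog represents the gene.
#'
#' @param records paralog data.frame for one gene.
#' @return Single-row data.frame, or \code{NULL} when the gene has no
#'   paralogs; duplicated rank 1 is a validation error.
#' @export
selectRepresentativeParalog <- function(records) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  hit <- which(records$rank == 1L)
  if (length(hit) > 1) stop("duplicate rank-1 paralog for gene ",
                            records$gene_id[1])
  if (length(hit) == 0) stop("no rank-1 paralog for gene ",
                             records$gene_id[1])
  records[hit, , drop = FALSE]
}

.summaryStats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(c(mean = NA_real_, sd = NA_real_, median = NA_real_, n = 0))
  }
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    median = stats::median(x), n = length(x))
}

#' Per-group summary table
#'
#' Summarises gene-pair records by gene group (mean, sample sd with n-1
#' denominator, median) for protein identity, cDNA identity, Ka/Ks, Ks, Ka
#' and gap counts, plus SNP density when provided.  Records whose Ks was
#' discarded (sentinel) are excluded from the Ks and Ka/Ks columns only.  An \code{imprinted} row
#' (maternal plus paternal) is included.
#'
#' @param records gene-pair data.frame (one record per gene; use
#'   \code{\link{selectBestHomolog}} first if needed).
#' @param groups group data.frame from \code{\link{readGroupFile}}.
#' @param snps optional SNP data.frame from \code{\link{readSnpTable}}.
#' @return data.frame, one row per group x statistic layout: columns
#'   \code{group}, \code{n_genes}, then \code{<var>_mean}, \code{<var>_sd},
#'   \code{<var>_median}.
#' @export
summarizeGroups <- function(records, groups, snps = NULL) {
  df <- merge(records, groups[, c("gene_id", "group")], by = "gene_id")
  if (!is.null(snps)) {
    df$snp_density <- snps$snp_density[match(df$gene_id, snps$gene_id)]
  }
  if (!"ks_discarded" %in% names(df)) df$ks_discarded <- FALSE
  grpSets <- c(split(df, df$group),
               list(imprinted = df[df$group %in% c("maternal", "paternal"), ,
                                   drop = FALSE]))
  vars <- c("protein_identity", "cdna_identity", "ka_ks", "ks", "ka",
            "gap_count", if (!is.null(snps)) "snp_density")
  rows <- lapply(names(grpSets), function(gname) {
    d <- grpSets[[gname]]
    out <- data.frame(group = gname, n_genes = nrow(d))
    for (v in vars) {
      x <- d[[v]]
      ## the Ks discard sentinel removes records from Ks and Ka/Ks analyses
      ## only; Ka itself remains reportable
      if (v %in% c("ka_ks", "ks")) x[d$ks_discarded] <- NA
      st <- .summaryStats(x)
      out[[paste0(v, "_mean")]] <- st["mean"]
      out[[paste0(v, "_sd")]] <- st["sd"]
      out[[paste0(v, "_median")]] <- st["median"]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rank-based comparison of two groups
#'
#' Two-sided Mann-Whitney rank-sum test: exact when the smaller sample has at
#' most 8 observations and there are no ties, normal approximation with tie
#' correction otherwise.  A one-sided alternative is available.
#'
#' @param valuesA,valuesB numeric vectors (NAs dropped).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"} (alternative on A relative to B).
#' @return list with \code{p_value}, \code{statistic} (W) and
#'   \code{direction} (sign of median(A) - median(B)).
#' @export
compareGroups <- function(valuesA, valuesB, alternative = "two.sided") {
  a <- valuesA[!is.na(valuesA)]
  b <- valuesB[!is.na(valuesB)]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  useExact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = useExact,
                       correct = TRUE))
  md <- stats::median(a) - stats::median(b)
  p <- wt$p.value
  if (is.na(p)) p <- 1  # zero-variance case: all observations tied
  list(p_value = p, statistic = unname(wt$statistic),
       direction = if (md > 0) "greater" else if (md < 0) "less" else "equal")
}

#' Paralog enrichment chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) on a 2x2 table of
#' counts, e.g. genes with/without a paralog in the imprinted group versus
#' the autosomal background.  Row proportions are reported as percentages
#' rounded to two decimals.
#'
#' @param counts 2x2 matrix or 4-vector (row-major: a11, a12, a21, a22);
#'   column 1 is the "with" count, columns sum to the row totals.
#' @return list with \code{counts}, \code{chi_square}, \code{p_value},
#'   \code{proportions} (percent with, per row, 2 decimals).
#' @export
paralogEnrichment <- function(counts) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 2, byrow = TRUE)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0),
            all(counts == round(counts)))
  exp <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi <- sum((counts - exp)^2 / exp)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(counts = counts, chi_square = chi, p_value = p,
       proportions = round(100 * counts[, 1] / rowSums(counts), 2))
}

#' SNP-density depletion report
#'
#' Per-group median SNP densities plus the rank-sum comparison of each group
#' against the background.
#'
#' @param snps SNP data.frame from \code{\link{readSnpTable}}.
#' @param groups group data.frame from \code{\link{readGroupFile}}.
#' @return list with \code{medians} (named numeric) and \code{p_values}
#'   (each non-background group vs background).
#' @export
snpDepletionReport <- function(snps, groups) {
  df <- merge(snps, groups[, c("gene_id", "group")], by = "gene_id")
  df$grp2 <- ifelse(df$group %in% c("maternal", "paternal"), "imprinted",
                    df$group)
  sets <- split(df$snp_density, df$grp2)
  medians <- vapply(sets, stats::median, numeric(1))
  others <- setdiff(names(sets), "background")
  pvals <- vapply(others, function(g) {
    compareGroups(sets[[g]], sets$background)$p_value
  }, numeric(1))
  list(medians = medians, p_values = pvals)
}
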