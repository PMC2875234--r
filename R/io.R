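## Readers and writers for the tabular inputs of the pipeline: coding-sequence
## FASTA, HomoloGene-style ortholog pair tables, Ensembl-BioMart-style paralog
## tables, SNP tables and the gene-group file.  All tables are TSV with a
## header, UTF-8, '.' decimal, missing values written as "NA".

DEFAULT_SPECIES <- c("human", "mouse", "rat", "cow", "chimpanzee", "dog",
                     "chicken")

.logmsg <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

#' Read coding sequences from FASTA
#'
#' Headers follow the convention \code{gene_id<sep>species}.  Sequences are
#' upper-cased; characters outside \code{A,C,G,T,N} are rejected.
#'
#' @param path FASTA file.
#' @param sep separator between gene id and species in the header
#'   (default \code{"|"}).
#' @param species allowed species names.
#' @return A \link[Biostrings]{DNAStringSet} whose \code{mcols} carry
#'   \code{gene_id}, \code{species} and \code{frame_validated} (length a
#'   multiple of three and no internal in-frame stop codon).
#' @export
readCdsFasta <- function(path, sep = "|", species = DEFAULT_SPECIES) {
  if (!file.exists(path)) stop("file not found: ", path)
  ## read as raw strings first: DNAStringSet input would silently drop
  ## characters outside the IUPAC alphabet instead of rejecting them
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA input: ", path)
  hdr <- strsplit(names(seqs), sep, fixed = TRUE)
  bad <- vapply(hdr, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed FASTA header (expected 'gene_id", sep, "species'): ",
         names(seqs)[which(bad)[1]])
  }
  gene <- vapply(hdr, `[[`, character(1), 1L)
  sp <- vapply(hdr, `[[`, character(1), 2L)
  unknown <- !sp %in% species
  if (any(unknown)) {
    stop("unknown species in FASTA header: ", sp[which(unknown)[1]])
  }
  chr <- toupper(as.character(seqs))
  if (any(grepl("[^ACGTN]", chr))) {
    stop("sequence characters outside {A,C,G,T,N} in record ",
         names(seqs)[which(grepl("[^ACGTN]", chr))[1]])
  }
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(seqs)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gene, species = sp,
    frame_validated = vapply(chr, .frameOk, logical(1), USE.NAMES = FALSE))
  out
}

## frame validity: positive length multiple of 3, no internal in-frame stop
.frameOk <- function(dna) {
  n <- nchar(dna)
  if (n == 0 || n %% 3 != 0) return(FALSE)
  cods <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  internal <- cods[-length(cods)]
  !any(.isStopCodon(internal), na.rm = TRUE)
}

#' Write coding sequences to FASTA
#'
#' @param seqs named character vector or DNAStringSet; names are
#'   \code{gene_id<sep>species} headers.
#' @param path output file.
#' @export
writeCdsFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

.readTsv <- function(path, required, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE, colClasses = colClasses)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df
}

.checkPercent <- function(x, what, path) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop("validation error in ", path, ": ", what, " outside [0,100] at row ",
         bad[1])
  }
}

#' Read a HomoloGene-style ortholog pair table
#'
#' Expected columns: \code{gene_id}, \code{species_a}, \code{species_b},
#' \code{protein_identity}, \code{cdna_identity}, \code{gap_count},
#' \code{ka}, \code{ks}.  Rows with the sentinel \code{ks = -1} are retained
#' but flagged \code{ks_discarded}; their Ks is set to \code{NA} so the
#' sentinel is never used numerically.  \code{ka_ks} is defined only when Ks
#' is present and positive.
#'
#' @param path TSV file.
#' @return data.frame of gene-pair records with columns as above plus
#'   \code{ks_discarded} and \code{ka_ks}.
#' @export
readGenePairTable <- function(path) {
  df <- .readTsv(path, c("gene_id", "species_a", "species_b",
                         "protein_identity", "cdna_identity", "gap_count",
                         "ka", "ks"))
  .checkPercent(df$protein_identity, "protein_identity", path)
  .checkPercent(df$cdna_identity, "cdna_identity", path)
  if (any(!is.na(df$gap_count) & df$gap_count < 0)) {
    stop("validation error in ", path, ": negative gap_count")
  }
  df$ks_discarded <- !is.na(df$ks) & df$ks == -1
  df$ks[df$ks_discarded] <- NA_real_
  if (any(!is.na(df$ks) & df$ks < 0)) {
    stop("validation error in ", path, ": negative ks (other than sentinel -1)")
  }
  df$ka_ks <- ifelse(!is.na(df$ka) & !is.na(df$ks) & df$ks > 0,
                     df$ka / df$ks, NA_real_)
  df
}

#' @rdname readGenePairTable
#' @param records data.frame as returned by \code{readGenePairTable} (or
#'   produced by \code{\link{simulateGeneTables}}).
#' @export
writeGenePairTable <- function(records, path) {
  out <- records
  out$ka_ks <- NULL
  out$ks[!is.na(out$ks_discarded) & out$ks_discarded] <- -1
  out$ks_discarded <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an Ensembl-BioMart-style paralog table
#'
#' Expected columns: \code{gene_id}, \code{paralog_id}, \code{rank},
#' \code{paralog_chromosome}, \code{protein_identity}.  Rank 1 is the
#' evolutionarily most recent paralog; rows are re-sorted by gene and rank and
#' the rank-1 row is flagged as the representative.  Duplicate ranks within a
#' gene are a validation error.
#'
#' @param path TSV file.
#' @return data.frame with extra columns \code{representative},
#'   \code{n_paralogs} and \code{on_x} (\code{paralog_chromosome == "X"}).
#' @export
readParalogTable <- function(path) {
  df <- .readTsv(path, c("gene_id", "paralog_id", "rank",
                         "paralog_chromosome", "protein_identity"),
                 colClasses = c(paralog_chromosome = "character"))
  .checkPercent(df$protein_identity, "protein_identity", path)
  if (any(df$rank < 1 | df$rank != round(df$rank))) {
    stop("validation error in ", path, ": rank must be a positive integer")
  }
  dup <- stats::aggregate(rank ~ gene_id, df, function(r) anyDuplicated(r) > 0)
  if (any(dup$rank)) {
    stop("validation error in ", path, ": duplicate paralog rank for gene ",
         dup$gene_id[dup$rank][1])
  }
  df <- df[order(df$gene_id, df$rank), , drop = FALSE]
  rownames(df) <- NULL
  cnt <- table(df$gene_id)
  df$n_paralogs <- as.integer(cnt[df$gene_id])
  df$representative <- df$rank == 1L
  df$on_x <- df$paralog_chromosome == "X"
  df
}

#' @rdname readParalogTable
#' @param records paralog data.frame.
#' @export
writeParalogTable <- function(records, path) {
  keep <- c("gene_id", "paralog_id", "rank", "paralog_chromosome",
            "protein_identity")
  utils::write.table(records[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a SNP table
#'
#' Expected columns: \code{gene_id}, \code{coding_length_bp},
#' \code{snp_count}.
#'
#' @param path TSV file.
#' @return data.frame with an added \code{snp_density} column (SNPs per kb of
#'   coding sequence).
#' @export
readSnpTable <- function(path) {
  df <- .readTsv(path, c("gene_id", "coding_length_bp", "snp_count"))
  if (any(df$coding_length_bp <= 0)) {
    stop("validation error in ", path, ": coding_length_bp must be positive")
  }
  if (any(df$snp_count < 0)) {
    stop("validation error in ", path, ": negative snp_count")
  }
  df$snp_density <- snpDensity(df$coding_length_bp, df$snp_count)
  df
}

#' @rdname readSnpTable
#' @param records SNP data.frame.
#' @export
writeSnpTable <- function(records, path) {
  keep <- c("gene_id", "coding_length_bp", "snp_count")
  utils::write.table(records[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read the gene-group file
#'
#' Assigns each gene to exactly one of \code{maternal}, \code{paternal} or
#' \code{background} and records whether it has a paralog.  A gene appearing
#' twice is an error.  The union of maternal and paternal genes is the
#' imprinted set.
#'
#' @param path TSV file with columns \code{gene_id}, \code{group},
#'   \code{has_paralog}.
#' @return data.frame with an added logical \code{imprinted} column.
#' @export
readGroupFile <- function(path) {
  df <- .readTsv(path, c("gene_id", "group", "has_paralog"))
  if (anyDuplicated(df$gene_id)) {
    stop("validation error in ", path, ": gene assigned to more than one group: ",
         df$gene_id[duplicated(df$gene_id)][1])
  }
  ok <- df$group %in% c("maternal", "paternal", "background")
  if (!all(ok)) {
    stop("validation error in ", path, ": unknown group '",
         df$group[!ok][1], "'")
  }
  df$has_paralog <- as.logical(df$has_paralog)
  df$imprinted <- df$group %in% c("maternal", "paternal")
  df
}

#' @rdname readGroupFile
#' @param records group data.frame.
#' @export
writeGroupFile <- function(records, path) {
  keep <- c("gene_id", "group", "has_paralog")
  utils::write.table(records[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
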