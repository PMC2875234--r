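test_that("FASTA reader parses gene|species headers and validates sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|human", "ATGAAA", ">g1|mouse", "atggaa"), fa)
  cds <- readCdsFasta(fa)
  expect_length(cds, 2)
  mc <- S4Vectors::mcols(cds)
  expect_identical(mc$gene_id, c("g1", "g1"))
  expect_identical(mc$species, c("human", "mouse"))
  expect_identical(as.character(cds[[2]]), "ATGGAA")  # upper-cased
  expect_true(all(mc$frame_validated))

  writeLines(c(">g1", "ATGAAA"), fa)
  expect_error(readCdsFasta(fa), "malformed")
  writeLines(c(">g1|human", "ATGQAA"), fa)
  expect_error(readCdsFasta(fa), "outside")
  writeLines(character(0), fa)
  expect_error(readCdsFasta(fa), "empty")
})

test_that("frame validation flags out-of-frame and internal-stop sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|human", "ATGAAAA",       # not a multiple of 3
               ">g2|human", "ATGTAAGGG"), fa) # internal stop
  cds <- readCdsFasta(fa)
  expect_false(any(S4Vectors::mcols(cds)$frame_validated))
})

test_that("gene-pair reader handles the Ks sentinel and derives Ka/Ks", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("g1", "g2", "g3"),
                   species_a = "human", species_b = "mouse",
                   protein_identity = c(90, 85, 80),
                   cdna_identity = c(88, 84, 79),
                   gap_count = c(0L, 1L, 2L),
                   ka = c(0.1, 0.2, 0.05), ks = c(0.5, -1, 0))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- readGenePairTable(tsv)
  expect_false(rec$ks_discarded[1])
  expect_equal(rec$ka_ks[1], 0.2)
  # sentinel -1 mapped to discarded, never used numerically
  expect_true(rec$ks_discarded[2])
  expect_true(is.na(rec$ks[2]))
  expect_true(all(is.na(rec$ks) | rec$ks >= 0))
  # ks = 0: kept for identity analyses, Ka/Ks undefined
  expect_false(rec$ks_discarded[3])
  expect_true(is.na(rec$ka_ks[3]))

  df$protein_identity[2] <- 105
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGenePairTable(tsv), "row 2")
})

test_that("paralog reader sorts by rank and flags the representative", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = "g1", paralog_id = c("p2", "p1", "p3"),
                   rank = c(2L, 1L, 3L),
                   paralog_chromosome = c("7", "X", "2"),
                   protein_identity = c(40, 60, 30))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- readParalogTable(tsv)
  expect_identical(rec$rank, c(1L, 2L, 3L))
  expect_identical(rec$representative, c(TRUE, FALSE, FALSE))
  expect_identical(rec$on_x, c(TRUE, FALSE, FALSE))
  expect_identical(unique(rec$n_paralogs), 3L)

  df$rank <- c(1L, 1L, 3L)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readParalogTable(tsv), "duplicate")
})

test_that("SNP reader computes density and rejects invalid lengths", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("g1", "g2"), coding_length_bp = c(1000L, 500L),
                   snp_count = c(3L, 3L))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- readSnpTable(tsv)
  expect_equal(rec$snp_density, c(3.0, 6.0))
  df$coding_length_bp[1] <- 0L
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSnpTable(tsv), "positive")
})

test_that("group file enforces one group per gene", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("g1", "g2", "g1"),
                   group = c("maternal", "background", "paternal"),
                   has_paralog = c(TRUE, FALSE, TRUE))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readGroupFile(tsv), "more than one group")
  df <- df[1:2, ]
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- readGroupFile(tsv)
  expect_identical(rec$imprinted, c(TRUE, FALSE))
})

test_that("tables round-trip through write and read", {
  dir <- withr::local_tempdir()
  sim <- simulateGeneTables(simulationSpec(
    nGenes = c(maternal = 2L, paternal = 2L, background = 3L),
    codons = 25L, seed = 11L))
  writeSimulatedData(sim, dir)

  pairs <- readGenePairTable(file.path(dir, "pairs.tsv"))
  common <- c("gene_id", "species_a", "species_b", "protein_identity",
              "cdna_identity", "gap_count", "ka", "ks", "ks_discarded")
  expect_equal(pairs[common], sim$pairs[common], tolerance = 1e-12,
               ignore_attr = TRUE)

  par <- readParalogTable(file.path(dir, "paralogs.tsv"))
  keep <- c("gene_id", "paralog_id", "rank", "paralog_chromosome",
            "protein_identity")
  expect_equal(par[keep], sim$paralogs[order(sim$paralogs$gene_id,
                                             sim$paralogs$rank), keep],
               tolerance = 1e-12, ignore_attr = TRUE)

  snps <- readSnpTable(file.path(dir, "snps.tsv"))
  expect_equal(snps[c("gene_id", "coding_length_bp", "snp_count")],
               sim$snps, tolerance = 1e-12, ignore_attr = TRUE)

  grp <- readGroupFile(file.path(dir, "groups.tsv"))
  expect_equal(grp[c("gene_id", "group", "has_paralog")], sim$groups,
               ignore_attr = TRUE)

  fa <- readCdsFasta(file.path(dir, "sequences.fa"))
  expect_identical(as.character(fa), sim$sequences)
})
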