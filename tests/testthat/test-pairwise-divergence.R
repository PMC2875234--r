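test_that("percentIdentity follows the all-columns convention and is symmetric", {
  expect_equal(percentIdentity(c("MA", "MA")), 100)
  expect_equal(percentIdentity(c("MA", "M-")), 50)             # gap = mismatch
  expect_equal(percentIdentity(c("MA", "M-"), denominator = "ungapped"), 100)
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    a <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE)
    b <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE)
    bad <- a == "-" & b == "-"
    b[bad] <- "A"  # avoid all-gap columns
    ra <- paste(a, collapse = ""); rb <- paste(b, collapse = "")
    direct <- 100 * sum(a == b & a != "-" & b != "-") / n
    expect_equal(percentIdentity(c(ra, rb)), direct)
    expect_equal(percentIdentity(c(rb, ra)), percentIdentity(c(ra, rb)))
  }
})

test_that("countGaps counts indel events, not gap columns", {
  expect_identical(countGaps(c("MAAV", "M--V")), 1L)
  expect_identical(countGaps(c("MAAV", "MAAV")), 0L)
  expect_identical(countGaps(c("MAVA", "M-V-")), 2L)
  expect_identical(countGaps(c("MAAV", "M--V"), unit = "columns"), 2L)
})

test_that("neiGojobori matches its defining examples", {
  same <- neiGojobori(c("ATGGAATTT", "ATGGAATTT"))
  expect_equal(same@Ka, 0)
  expect_equal(same@Ks, 0)
  expect_true(is.na(same@kaKs))
  # one synonymous change (GAA -> GAG); too short for the Jukes-Cantor
  # correction of pS (pS = 1.5), so Ks is saturated here
  r <- neiGojobori(c("ATGGAATTT", "ATGGAGTTT"))
  expect_equal(r@Sd, 1)
  expect_equal(r@Nd, 0)
  expect_equal(r@Ka, 0)
  expect_equal(r@pS, 1.5)
  expect_true(r@saturated)
  # padded with identical codons the same single change gives Ks > 0
  pad <- strrep("CTG", 20)
  r2 <- neiGojobori(c(paste0("ATGGAATTT", pad), paste0("ATGGAGTTT", pad)))
  expect_equal(r2@Sd, 1)
  expect_equal(r2@Nd, 0)
  expect_equal(r2@Ka, 0)
  expect_gt(r2@Ks, 0)
  expect_false(r2@saturated)
})

test_that("neiGojobori site and difference counts equal the enumeration oracle", {
  set.seed(33)
  codons <- senseCodons()
  for (rep in 1:40) {
    ca <- sample(codons, 3, replace = TRUE)
    cb <- sample(codons, 3, replace = TRUE)
    r <- neiGojobori(c(paste(ca, collapse = ""), paste(cb, collapse = "")))
    sOracle <- (sum(vapply(ca, oracleSites, numeric(1))) +
                sum(vapply(cb, oracleSites, numeric(1)))) / 2
    sd <- 0; nd <- 0
    for (k in 1:3) {
      pc <- oraclePathways(ca[k], cb[k])
      sd <- sd + pc["sd"]; nd <- nd + pc["nd"]
    }
    expect_equal(r@S, sOracle, tolerance = 1e-12)
    expect_equal(r@N, 9 - sOracle, tolerance = 1e-12)
    expect_equal(r@Sd, unname(sd), tolerance = 1e-12)
    expect_equal(r@Nd, unname(nd), tolerance = 1e-12)
  }
})

test_that("neiGojobori invariants: S+N budget, row-swap symmetry, gap skipping", {
  set.seed(41)
  for (rep in 1:10) {
    a <- randomCds(15); b <- randomCds(15)
    r <- neiGojobori(c(a, b))
    expect_equal(r@S + r@N, 3 * r@codons, tolerance = 1e-9)
    r2 <- neiGojobori(c(b, a))
    expect_equal(r@S, r2@S); expect_equal(r@Sd, r2@Sd)
    expect_equal(r@Ka, r2@Ka); expect_equal(r@Ks, r2@Ks)
  }
  # gap and N columns are skipped
  g <- neiGojobori(c("ATG---GAANNN", "ATGAAAGAGTTT"))
  expect_identical(g@codons, 2L)
  expect_error(neiGojobori(c("---", "AAA")), "no comparable")
})

test_that("Jukes-Cantor correction is monotone below saturation", {
  p <- seq(0.01, 0.7, by = 0.05)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))  # correction expands observed proportions
})

test_that("silent CpG mutability counts third-position contexts", {
  # Phe codon boundary: TTC|GGG vs TTT|GGG - silent C->T before G
  r <- silentCpgMutability(c("TTCGGG", "TTTGGG"))
  expect_identical(r$n_cpg_tpg, 1L)
  expect_identical(r$n_cpg_cpg, 0L)
  expect_equal(r$mutability_index, 1)
  r2 <- silentCpgMutability(c("TTCGGG", "TTCGGG"))
  expect_identical(r2$n_cpg_cpg, 1L)
  expect_equal(r2$mutability_index, 0)
  # non-silent C->T does not count: TGG(Trp) boundary would change aa?
  # use ACC(Thr)->ACT(Thr) silent vs ATC(Ile)->ATT(Ile) silent control with
  # a non-silent case: TGC(Cys)->TGT(Cys) is silent; take AAC(Asn)->AAT(Asn)
  # silent too -- a genuinely non-silent third-position C->T needs a codon
  # where C at position 3 is not 4- or 2-fold degenerate toward T; ATG/TGG
  # have no C. Use first-position context instead: CGG vs CGG conserved.
  r3 <- silentCpgMutability(c("ACCGGG", "ACCGGG"))
  expect_identical(r3$n_cpg_cpg, 1L)
})

test_that("silent CpG counts equal a position-by-position recount", {
  set.seed(55)
  recount <- function(a, b) {
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    cpg <- 0L; tpg <- 0L
    for (i in seq_len(nchar(a) / 3 - 1)) {
      p3 <- 3 * i; p1 <- p3 + 1
      da <- paste0(ac[p3], ac[p1]); db <- paste0(bc[p3], bc[p1])
      silent <- function(ch) {
        cod <- paste(ch[(p3 - 2):p3], collapse = "")
        alt <- paste0(substr(cod, 1, 2), "T")
        identical(GC_TAB[[alt]], GC_TAB[[cod]]) && GC_TAB[[alt]] != "*"
      }
      if (da == "CG" && db == "CG") cpg <- cpg + 1L
      else if (da == "CG" && db == "TG" && silent(ac)) tpg <- tpg + 1L
      else if (da == "TG" && db == "CG" && silent(bc)) tpg <- tpg + 1L
    }
    list(cpg = cpg, tpg = tpg)
  }
  for (rep in 1:10) {
    a <- randomCds(10); b <- randomCds(10)
    got <- silentCpgMutability(c(a, b))
    want <- recount(a, b)
    expect_identical(got$n_cpg_cpg, want$cpg)
    expect_identical(got$n_cpg_tpg, want$tpg)
  }
})

test_that("snpDensity computes per-kb rates and rejects zero lengths", {
  expect_equal(snpDensity(1000, 2), 2)
  expect_equal(snpDensity(500, 3), 6)
  expect_error(snpDensity(0, 1), "positive")
})

test_that("divergenceTable assembles per-pair records from sequences", {
  sim <- simulateGeneTables(simulationSpec(
    nGenes = c(maternal = 1L, paternal = 1L, background = 1L),
    codons = 40L, seed = 5L))
  dir <- withr::local_tempdir()
  writeSimulatedData(sim, dir)
  cds <- readCdsFasta(file.path(dir, "sequences.fa"))
  snps <- readSnpTable(file.path(dir, "snps.tsv"))
  div <- divergenceTable(cds, snps = snps)
  expect_identical(nrow(div), 3L * 6L)  # all species pairs within each gene
  expect_true(all(div$protein_identity >= 0 & div$protein_identity <= 100))
  expect_true(all(!is.na(div$snp_density)))
  # the human-mouse rows agree with the generator's own pair records
  hm <- div[div$species_a == "human" & div$species_b == "mouse", ]
  simHm <- sim$pairs[sim$pairs$species_a == "human" &
                     sim$pairs$species_b == "mouse", ]
  expect_equal(hm$ka[order(hm$gene_id)], simHm$ka[order(simHm$gene_id)],
               tolerance = 1e-12)
})
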