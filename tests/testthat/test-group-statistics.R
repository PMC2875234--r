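test_that("selectBestHomolog keeps the highest protein identity deterministically", {
  cand <- data.frame(gene_id = c("gB", "gA"), species_a = "human",
                     species_b = "mouse", protein_identity = c(83.1, 91.0))
  expect_identical(selectBestHomolog(cand)$gene_id, "gA")
  expect_identical(selectBestHomolog(cand[1, ])$gene_id, "gB")
  tie <- data.frame(gene_id = c("gB", "gA"), species_a = "human",
                    species_b = "mouse", protein_identity = c(90, 90))
  expect_identical(selectBestHomolog(tie)$gene_id, "gA")
  expect_error(selectBestHomolog(tie[0, ]), "no candidate")
})

test_that("selectRepresentativeParalog picks rank 1 and validates", {
  rec <- data.frame(gene_id = "g1", paralog_id = c("a", "b", "c"),
                    rank = c(2L, 1L, 3L), paralog_chromosome = "1",
                    protein_identity = c(40, 70, 30))
  expect_identical(selectRepresentativeParalog(rec)$paralog_id, "b")
  expect_null(selectRepresentativeParalog(rec[0, ]))
  dup <- rec; dup$rank <- c(1L, 1L, 3L)
  expect_error(selectRepresentativeParalog(dup), "duplicate rank-1")
})

test_that("summarizeGroups computes mean/sd/median per group", {
  recs <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    protein_identity = c(1, 2, 3, 10, 10, 10),
    cdna_identity = 5, ka_ks = 0.1, ks = c(0.5, 0.5, 0.5, 0.4, 0.4, 0.4),
    ka = 0.05, gap_count = 0L,
    ks_discarded = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  groups <- data.frame(gene_id = sprintf("g%d", 1:6),
                       group = rep(c("maternal", "background"), each = 3),
                       has_paralog = FALSE)
  s <- summarizeGroups(recs, groups)
  mat <- s[s$group == "maternal", ]
  expect_equal(mat$protein_identity_mean, 2)
  expect_equal(mat$protein_identity_sd, 1)
  expect_equal(mat$protein_identity_median, 2)
  expect_identical(mat$n_genes, 3L)
  # all-discarded group: Ks and Ka/Ks columns NA, identity and Ka populated
  bg <- s[s$group == "background", ]
  expect_true(is.na(bg$ks_mean))
  expect_true(is.na(bg$ka_ks_mean))
  expect_equal(bg$ka_mean, 0.05)
  expect_equal(bg$protein_identity_mean, 10)
  # imprinted summary row aggregates maternal + paternal
  expect_true("imprinted" %in% s$group)
  expect_identical(s$n_genes[s$group == "imprinted"], 3L)
})

test_that("summary statistics are invariant to record order", {
  set.seed(61)
  recs <- data.frame(gene_id = sprintf("g%d", 1:30),
                     protein_identity = runif(30, 60, 100),
                     cdna_identity = runif(30, 60, 100),
                     ka_ks = runif(30, 0, 0.5), ks = runif(30, 0.1, 1),
                     ka = runif(30, 0, 0.2), gap_count = rpois(30, 1),
                     ks_discarded = FALSE)
  groups <- data.frame(gene_id = sprintf("g%d", 1:30),
                       group = rep(c("maternal", "paternal", "background"),
                                   10), has_paralog = FALSE)
  s1 <- summarizeGroups(recs, groups)
  perm <- sample(30)
  s2 <- summarizeGroups(recs[perm, ], groups)
  expect_equal(s1, s2)
})

test_that("compareGroups matches exact rank-sum enumeration for separated samples", {
  a <- 1:7; b <- 8:14
  got <- compareGroups(a, b)
  # exact two-sided p by enumerating all assignments of ranks to group A
  combos <- utils::combn(14, 7)
  wDist <- apply(combos, 2, function(idx) sum(idx) - 7 * 8 / 2)
  wObs <- sum(seq_len(7)) - 7 * 8 / 2  # complete separation, minimal W
  pExact <- 2 * mean(wDist <= wObs)
  expect_equal(got$p_value, pExact, tolerance = 1e-12)
  expect_identical(got$direction, "less")
})

test_that("compareGroups degenerate and tie behaviour", {
  expect_equal(compareGroups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- compareGroups(c(5, 5, 5, 6), c(5, 5, 5, 6))
  expect_gt(r$p_value, 0.9)
  expect_error(compareGroups(numeric(0), 1:3), "empty")
})

test_that("null p-values are approximately uniform", {
  set.seed(71)
  p <- replicate(500, {
    compareGroups(rnorm(15), rnorm(25))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(mean(p < 0.05), 0.09)  # close to nominal
})

test_that("rejection rate rises with the planted shift", {
  set.seed(73)
  rates <- vapply(c(0, 1.2), function(shift) {
    mean(replicate(60, {
      compareGroups(rnorm(20) + shift, rnorm(30))$p_value < 0.05
    }))
  }, numeric(1))
  expect_lt(rates[1], 0.15)
  expect_gt(rates[2], 0.8)
})

test_that("paralogEnrichment reproduces chi-square closed form and proportions", {
  r <- paralogEnrichment(c(34, 22, 9619, 10331))
  expect_equal(unname(r$proportions), c(60.71, 48.22))
  # closed form Sum (O-E)^2/E
  m <- matrix(c(34, 22, 9619, 10331), 2, 2, byrow = TRUE)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(r$chi_square, sum((m - E)^2 / E), tolerance = 1e-12)
  # and agrees with the standard test without continuity correction
  expect_equal(r$p_value,
               suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value,
               tolerance = 1e-12)
  rX <- paralogEnrichment(c(6, 50, 1035, 18915))
  expect_equal(unname(rX$proportions), c(10.71, 5.19))
  flat <- paralogEnrichment(c(10, 10, 10, 10))
  expect_equal(flat$chi_square, 0)
  expect_equal(flat$p_value, 1)
})

test_that("snpDepletionReport reports medians and rank-sum p-values", {
  snps <- data.frame(gene_id = sprintf("g%d", 1:40),
                     coding_length_bp = 1000L,
                     snp_count = c(rep(2, 10), rep(3, 10), rep(4, 20)))
  snps$snp_density <- snpDensity(snps$coding_length_bp, snps$snp_count)
  groups <- data.frame(gene_id = sprintf("g%d", 1:40),
                       group = c(rep("maternal", 10), rep("paternal", 10),
                                 rep("background", 20)),
                       has_paralog = FALSE)
  rep1 <- snpDepletionReport(snps, groups)
  expect_equal(unname(rep1$medians["imprinted"]), 2.5)
  expect_equal(unname(rep1$medians["background"]), 4)
  expect_lt(rep1$p_values[["imprinted"]], 0.05)
  # identical distributions: p near 1
  snps$snp_count <- 3
  snps$snp_density <- snpDensity(snps$coding_length_bp, snps$snp_count)
  rep2 <- snpDepletionReport(snps, groups)
  expect_gt(rep2$p_values[["imprinted"]], 0.9)
})
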