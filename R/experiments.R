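## Simulation experiments validating the branch-model machinery and the
## end-to-end pipeline: parameter recovery, null calibration of the LRT,
## power against a planted foreground shift, and whole-pipeline group
## comparisons.  Each experiment is seeded and uses the quartet tree
## (human,(mouse,rat)#1,cow) with mammal-scale branch lengths.

.EXPERIMENT_TREE <- c(human = 0.35, cow = 0.35, mouse = 0.10, rat = 0.12,
                      ancestor = 0.15)

#' Omega recovery experiment
#'
#' Simulates quartets under a single omega and refits the one-ratio model,
#' reporting the estimates.
#'
#' @param nReplicates number of simulated quartets.
#' @param nCodons codons per quartet.
#' @param omega generating (and target) omega.
#' @param kappa generating kappa.
#' @param seed integer seed.
#' @return data.frame with columns \code{omega_hat}, \code{kappa_hat},
#'   \code{lnL}, \code{converged}.
#' @export
omegaRecoveryExperiment <- function(nReplicates = 20, nCodons = 500,
                                    omega = 0.2, kappa = 2, seed = 1) {
  .withSeed(seed, function() {
    rows <- lapply(seq_len(nReplicates), function(i) {
      sq <- simulateQuartet(nCodons, .EXPERIMENT_TREE, kappa, omega)
      f <- fitBranchModel(sq$sequences, "one_ratio")
      data.frame(omega_hat = f@omegaBackground, kappa_hat = f@kappa,
                 lnL = f@lnL, converged = f@converged)
    })
    do.call(rbind, rows)
  })
}

#' Null calibration of the branch-model LRT
#'
#' Simulates quartets with a single omega on all branches (the one-ratio
#' null), fits both models and records the LRT statistic and the fitted
#' foreground direction.  Because the tied-omega null is interior to the
#' two-ratios parameter space, the statistic is asymptotically chi-squared
#' with one degree of freedom; the 2.71 threshold is the 5\% point of the
#' one-sided (directional) decision, which \code{directional_rejection}
#' reports (significant and foreground elevated).
#'
#' @inheritParams omegaRecoveryExperiment
#' @param threshold LRT threshold (default 2.71).
#' @return data.frame with \code{statistic}, \code{direction},
#'   \code{significant}, \code{directional_rejection}.
#' @export
lrtNullExperiment <- function(nReplicates = 200, nCodons = 200, omega = 0.2,
                              kappa = 2, seed = 1, threshold = 2.71) {
  .withSeed(seed, function() {
    rows <- lapply(seq_len(nReplicates), function(i) {
      sq <- simulateQuartet(nCodons, .EXPERIMENT_TREE, kappa, omega)
      f1 <- fitBranchModel(sq$sequences, "one_ratio")
      f2 <- fitBranchModel(sq$sequences, "two_ratios")
      r <- lrt(f1, f2, threshold = threshold)
      data.frame(statistic = r@statistic, direction = r@direction,
                 significant = r@significant,
                 directional_rejection = r@significant &
                   r@direction == "elevated")
    })
    do.call(rbind, rows)
  })
}

#' Power of the LRT against a planted foreground shift
#'
#' Simulates quartets whose rodent-ancestor branch evolves under
#' \code{omegaForeground} while all other branches use \code{omegaBackground},
#' then tests with the one-ratio vs two-ratios LRT.
#'
#' @inheritParams omegaRecoveryExperiment
#' @param omegaBackground,omegaForeground generating omegas.
#' @param threshold LRT threshold.
#' @return data.frame with \code{statistic}, \code{significant},
#'   \code{direction}.
#' @export
lrtPowerExperiment <- function(nReplicates = 20, nCodons = 500,
                               omegaBackground = 0.1, omegaForeground = 0.8,
                               kappa = 2, seed = 1, threshold = 2.71) {
  .withSeed(seed, function() {
    rows <- lapply(seq_len(nReplicates), function(i) {
      sq <- simulateQuartet(nCodons, .EXPERIMENT_TREE, kappa,
                            omegaBackground, omegaForeground)
      f1 <- fitBranchModel(sq$sequences, "one_ratio")
      f2 <- fitBranchModel(sq$sequences, "two_ratios")
      r <- lrt(f1, f2, threshold = threshold)
      data.frame(statistic = r@statistic, significant = r@significant,
                 direction = r@direction)
    })
    do.call(rbind, rows)
  })
}

#' End-to-end group comparison on one simulated dataset
#'
#' Runs the full pipeline on a \code{\link{simulateGeneTables}} dataset:
#' per-group summaries of the human-mouse pair records and the rank-sum
#' comparison of the maternal group against the background for cDNA
#' identity, protein identity and Ka/Ks.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with \code{summary} (the \code{\link{summarizeGroups}}
#'   table), \code{p_cdna}, \code{p_protein}, \code{p_kaks} and the maternal
#'   minus background mean differences \code{delta_identity},
#'   \code{delta_kaks}.
#' @export
groupComparisonExperiment <- function(spec) {
  sim <- simulateGeneTables(spec)
  hm <- sim$pairs[sim$pairs$species_a == "human" &
                  sim$pairs$species_b == "mouse", ]
  s <- summarizeGroups(hm, sim$groups, snps = {
    sn <- sim$snps
    sn$snp_density <- snpDensity(sn$coding_length_bp, sn$snp_count)
    sn
  })
  df <- merge(hm, sim$groups[, c("gene_id", "group")], by = "gene_id")
  val <- function(col, grp) df[[col]][df$group == grp]
  list(summary = s,
       p_cdna = compareGroups(val("cdna_identity", "maternal"),
                              val("cdna_identity", "background"))$p_value,
       p_protein = compareGroups(val("protein_identity", "maternal"),
                                 val("protein_identity", "background"))$p_value,
       p_kaks = compareGroups(val("ka_ks", "maternal"),
                              val("ka_ks", "background"))$p_value,
       delta_identity =
         s$cdna_identity_mean[s$group == "maternal"] -
         s$cdna_identity_mean[s$group == "background"],
       delta_kaks =
         s$ka_ks_mean[s$group == "maternal"] -
         s$ka_ks_mean[s$group == "background"])
}
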