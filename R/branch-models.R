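## Codon branch models on the fixed unrooted quartet (human,(mouse,rat)#1,cow):
## Goldman-Yang style 61-state likelihood via Felsenstein pruning, one-ratio
## vs two-ratios maximum-likelihood fits, and the likelihood-ratio test with
## the 2.71 decision threshold.

#' Construct the fixed quartet tree
#'
#' @param lengths named numeric of branch lengths in expected substitutions
#'   per codon (\code{human}, \code{cow}, \code{mouse}, \code{rat},
#'   \code{ancestor}).
#' @return A \linkS4class{QuartetTree}; the rodent-ancestor branch is the
#'   foreground branch.
#' @export
quartetTree <- function(lengths) {
  methods::new("QuartetTree", lengths = lengths[.QUARTET_BRANCHES],
               foreground = "ancestor")
}

#' Parse and validate a marked quartet newick string
#'
#' Accepts a newick tree over tips \{human, mouse, rat, cow\} whose topology
#' matches the fixed unrooted quartet and whose \code{#1} mark (if present)
#' sits on the mouse-rat ancestor clade, e.g.
#' \code{"(human,(mouse,rat)#1,cow);"}.
#'
#' @param text newick string.
#' @return A \linkS4class{QuartetTree} with the parsed branch lengths
#'   (missing lengths default to 0.1).
#' @export
parseQuartetNewick <- function(text) {
  marked <- grepl("#1", text, fixed = TRUE)
  if (marked && !grepl("\\)\\s*(:[0-9.eE+-]+)?\\s*#1", text)) {
    stop("the #1 foreground mark must be attached to an internal clade")
  }
  clean <- gsub("#1", "", text, fixed = TRUE)
  tr <- ape::read.tree(text = clean)
  if (is.null(tr) || length(tr$tip.label) != 4 ||
      !setequal(tr$tip.label, c("human", "mouse", "rat", "cow"))) {
    stop("tree must have exactly the tips human, mouse, rat, cow")
  }
  tr <- ape::unroot(tr)
  ## the single internal edge must separate {mouse, rat} from {human, cow}
  ntip <- 4L
  internal <- tr$edge[tr$edge[, 2] > ntip, , drop = FALSE]
  if (nrow(internal) != 1) stop("tree is not an unrooted quartet")
  innerNode <- internal[1, 2]
  tipsBelow <- tr$tip.label[tr$edge[tr$edge[, 1] == innerNode, 2]]
  if (!setequal(tipsBelow, c("mouse", "rat"))) {
    stop("topology must be (human,(mouse,rat),cow)")
  }
  if (marked) {
    ## mark must precede the clade containing mouse and rat
    cladeRe <- "\\((mouse[^)]*rat|rat[^)]*mouse)[^)]*\\)\\s*(:[0-9.eE+-]+)?\\s*#1"
    if (!grepl(cladeRe, text)) {
      stop("#1 mark is not on the mouse-rat ancestor branch")
    }
  }
  el <- tr$edge.length
  if (is.null(el)) el <- rep(0.1, nrow(tr$edge))
  len <- numeric(0)
  for (k in seq_len(nrow(tr$edge))) {
    child <- tr$edge[k, 2]
    nm <- if (child <= ntip) tr$tip.label[child] else "ancestor"
    len[nm] <- el[k]
  }
  quartetTree(len[.QUARTET_BRANCHES])
}

#' Saturation filter for Ks values
#'
#' Genes with Ks equal to zero or with Ks above 2.5 (saturation) are dropped
#' from rate analyses as unreliable.
#'
#' @param ks numeric vector of Ks values.
#' @return factor with levels \code{keep}, \code{drop_zero},
#'   \code{drop_saturated}.
#' @export
saturationFilter <- function(ks) {
  out <- ifelse(is.na(ks), NA_character_,
                ifelse(ks <= 0, "drop_zero",
                       ifelse(ks > 2.5, "drop_saturated", "keep")))
  factor(out, levels = c("keep", "drop_zero", "drop_saturated"))
}

#' Critical value of the boundary-mixture likelihood-ratio null
#'
#' Critical value at level \code{alpha} of the half-and-half mixture of a
#' point mass at zero and a chi-squared distribution with one degree of
#' freedom, the reference distribution conventionally used with branch-model
#' LRTs; at \code{alpha = 0.05} this is 2.71.
#'
#' @param alpha significance level.
#' @return Numeric critical value.
#' @export
lrtCriticalValue <- function(alpha = 0.05) {
  if (alpha >= 0.5) return(0)
  stats::qchisq(1 - 2 * alpha, df = 1)
}

## convert a 4-row codon alignment to a matrix of sense-codon indices,
## dropping columns with gaps or ambiguity; errors on non-sense codons
.codonIndexMatrix <- function(aln) {
  rows <- if (methods::is(aln, "CodonAlignment")) alignmentRows(aln) else aln
  need <- c("human", "mouse", "rat", "cow")
  if (!all(need %in% names(rows))) {
    stop("quartet alignment must have rows named human, mouse, rat, cow")
  }
  rows <- rows[need]
  n <- nchar(rows[1])
  starts <- seq(1, n, 3)
  codons <- senseCodons()
  m <- vapply(rows, function(r) {
    cods <- substring(r, starts, starts + 2)
    idx <- match(cods, codons)
    amb <- grepl("[-N]", cods)
    stopish <- !amb & is.na(idx)
    if (any(stopish & !cods %in% c("TAA", "TAG", "TGA"))) {
      stop("unexpected codon in alignment: ", cods[which(stopish)[1]])
    }
    if (any(stopish)) stop("stop codon inside aligned coding sequence")
    idx
  }, integer(length(starts)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  keep <- rowSums(is.na(m)) == 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no usable codon columns")
  t(m)  # 4 x ncol, rows human/mouse/rat/cow
}

#' Log-likelihood of a codon branch model on the quartet
#'
#' Felsenstein pruning over the two internal nodes of the unrooted quartet
#' under the Goldman-Yang style codon model: zero rate for multi-nucleotide
#' changes, factor \code{kappa} for transitions, the branch-specific omega
#' for nonsynonymous changes and the target codon frequency, with branch
#' lengths in expected substitutions per codon.  The foreground
#' (rodent-ancestor) branch uses \code{omegaForeground}; all other branches
#' use \code{omegaBackground}.  Codon columns containing gaps or ambiguity
#' are excluded.
#'
#' @param aln a 4-row \linkS4class{CodonAlignment} (rows named human, mouse,
#'   rat, cow) or an equivalent named character vector.
#' @param tree a \linkS4class{QuartetTree}.
#' @param kappa transition/transversion ratio.
#' @param omegaBackground,omegaForeground Ka/Ks ratios.
#' @param freqs codon frequencies (default uniform over the 61 sense codons).
#' @return Log-likelihood (numeric scalar).
#' @export
codonLogLikelihood <- function(aln, tree, kappa, omegaBackground,
                               omegaForeground = omegaBackground,
                               freqs = NULL) {
  m <- .codonIndexMatrix(aln)
  .codonLogLikIdx(m, tree@lengths, kappa, omegaBackground, omegaForeground,
                  freqs)
}

## core likelihood on a precomputed 4 x ncol codon index matrix
.codonLogLikIdx <- function(m, lengths, kappa, omegaBackground,
                            omegaForeground, freqs = NULL,
                            patterns = NULL) {
  nState <- length(senseCodons())
  if (is.null(freqs)) freqs <- rep(1 / nState, nState)
  if (is.null(patterns)) patterns <- .compressPatterns(m)
  decBg <- .eigenQ(codonRateMatrix(kappa, omegaBackground, freqs))
  decFg <- if (omegaForeground == omegaBackground) decBg else
    .eigenQ(codonRateMatrix(kappa, omegaForeground, freqs))
  Ph <- .probMatrix(decBg, lengths["human"])
  Pc <- .probMatrix(decBg, lengths["cow"])
  Pm <- .probMatrix(decBg, lengths["mouse"])
  Pr <- .probMatrix(decBg, lengths["rat"])
  Pi <- .probMatrix(decFg, lengths["ancestor"])
  x <- patterns$states  # 4 x npat (human, mouse, rat, cow)
  ## conditional likelihood at rodent ancestor A, then at junction B
  La <- Pm[, x[2, ], drop = FALSE] * Pr[, x[3, ], drop = FALSE]
  Lb <- Ph[, x[1, ], drop = FALSE] * Pc[, x[4, ], drop = FALSE] * (Pi %*% La)
  site <- as.numeric(freqs %*% Lb)
  sum(patterns$counts * log(site))
}

.compressPatterns <- function(m) {
  key <- apply(m, 2, paste, collapse = ",")
  tab <- table(key)
  states <- vapply(strsplit(names(tab), ","), as.integer,
                   integer(nrow(m)))
  list(states = matrix(states, nrow = nrow(m)), counts = as.numeric(tab))
}

#' Fit a codon branch model by maximum likelihood
#'
#' Maximises the quartet log-likelihood over the five branch lengths, kappa
#' and the omega parameter(s) with L-BFGS-B on log-transformed parameters.
#' The one-ratio model ties the foreground omega to the background; the
#' two-ratios model frees it on the rodent-ancestor branch.  Omegas are
#' bounded to [1e-4, 10].  The default single start is initialised from
#' pairwise Nei-Gojobori distances; additional randomised starts can be
#' requested via \code{nStarts} (seeded, deterministic).
#'
#' @param aln 4-row codon alignment (rows named human, mouse, rat, cow).
#' @param model \code{"one_ratio"} or \code{"two_ratios"}.
#' @param freqs codon frequencies (default uniform).
#' @param nStarts number of optimisation starts (>= 1).
#' @param control passed to \code{\link[stats]{optim}} (\code{factr} etc.).
#' @return A \linkS4class{BranchModelFit}.
#' @export
fitBranchModel <- function(aln, model = c("one_ratio", "two_ratios"),
                           freqs = NULL, nStarts = 1,
                           control = list(factr = 1e9, maxit = 300)) {
  model <- match.arg(model)
  m <- .codonIndexMatrix(aln)
  if (ncol(m) < 10) stop("fewer than 10 usable codon columns")
  patterns <- .compressPatterns(m)
  twoRatio <- model == "two_ratios"

  negLL <- function(par) {
    len <- exp(par[1:5]); names(len) <- .QUARTET_BRANCHES
    kappa <- exp(par[6])
    wBg <- exp(par[7])
    wFg <- if (twoRatio) exp(par[8]) else wBg
    -.codonLogLikIdx(m, len, kappa, wBg, wFg, freqs, patterns)
  }

  ## data-driven start: split pairwise codon distances over the topology
  pdist <- function(i, j) {
    diff <- mean(m[i, ] != m[j, ])
    p <- min(diff, 0.7)
    max(-0.75 * log(1 - 4 * p / 3), 1e-3)
  }
  dHM <- pdist(1, 2); dHR <- pdist(1, 3); dMR <- pdist(2, 3)
  dHC <- pdist(1, 4)
  tAnc <- max((dHM + dHR - dMR) / 2 - dHC / 2, 0.01)
  start0 <- c(log(max(dHC / 2, 0.01)), log(max(dHC / 2, 0.01)),
              log(max(dMR / 2, 0.005)), log(max(dMR / 2, 0.005)),
              log(tAnc), log(2), log(0.2),
              if (twoRatio) log(0.2) else NULL)
  names(start0) <- NULL

  nPar <- length(start0)
  lower <- c(rep(log(1e-6), 5), log(0.05), rep(log(1e-4), nPar - 6))
  upper <- c(rep(log(20), 5), log(99), rep(log(10), nPar - 6))

  starts <- list(start0)
  if (nStarts > 1) {
    rng <- .withSeed(7L, function() {
      lapply(seq_len(nStarts - 1), function(k) {
        start0 + stats::rnorm(nPar, 0, 0.5)
      })
    })
    starts <- c(starts, lapply(rng, pmin, upper))
    starts <- lapply(starts, pmax, lower)
  }

  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negLL, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("branch-model optimisation failed on all starts")
  if (!converged) .logmsg("fitBranchModel: optimiser did not report convergence")

  par <- best$par
  len <- exp(par[1:5]); names(len) <- .QUARTET_BRANCHES
  kappa <- exp(par[6]); wBg <- exp(par[7])
  wFg <- if (twoRatio) exp(par[8]) else wBg
  tree <- quartetTree(len)

  ## convert branch lengths (subs/codon) to Ka and Ks per site, codeml style:
  ## rho_S(omega) = equilibrium synonymous flux fraction under the fitted
  ## model; S/(S+N) = same fraction at omega = 1 (mutational opportunity)
  fracS1 <- .sitesFromModel(kappa, freqs)
  perBranchRates <- function(w) {
    rho <- attr(codonRateMatrix(kappa, w, freqs), "synFlux")
    c(rhoS = rho, fS = fracS1)
  }
  ka <- ks <- stats::setNames(numeric(5), .QUARTET_BRANCHES)
  for (b in .QUARTET_BRANCHES) {
    w <- if (b == "ancestor") wFg else wBg
    pr <- perBranchRates(w)
    ks[b] <- len[b] * pr["rhoS"] / (3 * pr["fS"])
    ka[b] <- len[b] * (1 - pr["rhoS"]) / (3 * (1 - pr["fS"]))
  }

  methods::new("BranchModelFit", model = model, lnL = -best$value,
               kappa = kappa, omegaBackground = wBg, omegaForeground = wFg,
               tree = tree, converged = converged,
               kaPerBranch = ka, ksPerBranch = ks, codons = ncol(m))
}

#' Likelihood-ratio test between the one-ratio and two-ratios fits
#'
#' The statistic 2(lnL_two - lnL_one) is clipped at zero (the models are
#' nested, so small negative values can only be numerical).  The foreground
#' ratio is declared different at the 2.71 threshold; the direction reports
#' whether the fitted foreground omega is elevated or reduced relative to the
#' background.
#'
#' @param one one-ratio \linkS4class{BranchModelFit}.
#' @param two two-ratios \linkS4class{BranchModelFit}.
#' @param threshold critical value (default 2.71).
#' @return An \linkS4class{LrtResult}.
#' @export
lrt <- function(one, two, threshold = 2.71) {
  if (one@model != "one_ratio" || two@model != "two_ratios") {
    stop("lrt expects a one-ratio and a two-ratios fit, in that order")
  }
  stat <- max(0, 2 * (two@lnL - one@lnL))
  dir <- if (two@omegaForeground > two@omegaBackground) "elevated"
         else if (two@omegaForeground < two@omegaBackground) "reduced"
         else "equal"
  methods::new("LrtResult", statistic = stat,
               significant = stat >= threshold,
               direction = dir, threshold = threshold)
}

## run fn with a local RNG seed without disturbing the caller's RNG state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
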