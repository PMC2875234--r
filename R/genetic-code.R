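## Codon-level machinery shared by the Ka/Ks counter, the branch-model
## likelihood and the simulator: the standard genetic code, Nei-Gojobori
## site/pathway tables, and the Goldman-Yang style 61-state rate matrix.

.codonCache <- new.env(parent = emptyenv())

.NUC <- c("A", "C", "G", "T")

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (standard code; stops
#'   \code{TAA}, \code{TAG}, \code{TGA} excluded), in Biostrings
#'   \code{GENETIC_CODE} order.
#' @export
senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

## amino acid encoded by a codon; "*" for stops, "X" if any ambiguity
.codonAA <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.isStopCodon <- function(codon) {
  !is.na(Biostrings::GENETIC_CODE[codon]) & Biostrings::GENETIC_CODE[codon] == "*"
}

.isTransition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

## Per-codon synonymous site fractions, Nei-Gojobori style.  At each of the
## three positions the fraction of single-base changes that are synonymous is
## computed over the changes that do not create a stop codon (stop-producing
## changes are excluded from numerator and denominator), so every position
## contributes exactly one site and S + N = 3 per codon.
ngSiteCounts <- function() {
  if (!is.null(.codonCache$ngSites)) return(.codonCache$ngSites)
  codons <- senseCodons()
  s <- vapply(codons, function(cod) {
    bases <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      alts <- setdiff(.NUC, bases[p])
      neigh <- vapply(alts, function(b) {
        x <- bases; x[p] <- b; paste(x, collapse = "")
      }, character(1))
      keep <- !.isStopCodon(neigh)
      if (!any(keep)) next
      syn <- sum(.codonAA(neigh[keep]) == .codonAA(cod))
      tot <- tot + syn / sum(keep)
    }
    tot
  }, numeric(1))
  names(s) <- codons
  .codonCache$ngSites <- s
  s
}

## Average synonymous / nonsynonymous difference counts over all minimal
## mutational pathways between two codons.  Pathways visiting a stop codon are
## excluded; if every pathway is blocked (never the case for sense codons under
## the standard code, but guarded), all pathways are used with stop-crossing
## steps scored as nonsynonymous.
.pathwayCounts <- function(c1, c2) {
  aaTab <- Biostrings::GENETIC_CODE
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  diffPos <- which(b1 != b2)
  nd <- length(diffPos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(diffPos) else {
    ## all orderings of the differing positions
    idx <- seq_len(nd)
    ords <- if (nd == 2L) list(idx, rev(idx)) else {
      out <- list()
      for (i in idx) for (j in setdiff(idx, i)) {
        out[[length(out) + 1L]] <- c(i, j, setdiff(idx, c(i, j)))
      }
      out
    }
    lapply(ords, function(o) diffPos[o])
  }
  walk <- function(order, allowStops) {
    cur <- b1; syn <- 0; non <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b2[p]
      aaFrom <- aaTab[[paste(cur, collapse = "")]]
      aaTo <- aaTab[[paste(nxt, collapse = "")]]
      if (!allowStops && (aaFrom == "*" || aaTo == "*")) return(NULL)
      if (aaFrom == aaTo) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allowStops = FALSE))
  if (length(res) == 0L) res <- lapply(perms, walk, allowStops = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

## 61 x 61 matrices of pathway-averaged synonymous (sd) and nonsynonymous (nd)
## difference counts, cached on first use.
ngPairCounts <- function() {
  if (!is.null(.codonCache$ngPairs)) return(.codonCache$ngPairs)
  codons <- senseCodons()
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pc <- .pathwayCounts(codons[i], codons[j])
      sd[i, j] <- sd[j, i] <- pc["sd"]
      nd[i, j] <- nd[j, i] <- pc["nd"]
    }
  }
  .codonCache$ngPairs <- list(sd = sd, nd = nd)
  .codonCache$ngPairs
}

## Sparse description of the single-nucleotide neighbour structure among sense
## codons: ordered pairs (i, j) one base apart, with transition and synonymous
## flags.  Drives both the rate matrix and the simulator.
.singleDiffTable <- function() {
  if (!is.null(.codonCache$sdt)) return(.codonCache$sdt)
  codons <- senseCodons()
  n <- length(codons)
  bases <- do.call(rbind, strsplit(codons, ""))
  aa <- .codonAA(codons)
  ii <- jj <- integer(0); ts <- syn <- logical(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(bases[i, ] != bases[j, ])
      if (length(d) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, .isTransition(bases[i, d], bases[j, d]))
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  .codonCache$sdt <- data.frame(i = ii, j = jj, ts = ts, syn = syn)
  .codonCache$sdt
}

#' Goldman-Yang style codon instantaneous rate matrix
#'
#' Builds the 61-state Markov generator with rate zero between codons more
#' than one nucleotide apart, a factor \code{kappa} for transitions, a factor
#' \code{omega} for nonsynonymous changes and the target-codon equilibrium
#' frequency, scaled so that the expected number of substitutions per codon
#' per unit time equals one (branch lengths are therefore in expected
#' substitutions per codon).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (Ka/Ks, > 0).
#' @param freqs equilibrium codon frequencies over the 61 sense codons;
#'   default uniform.
#' @return A 61 x 61 generator matrix with row names the sense codons,
#'   attribute \code{"synFlux"} giving the equilibrium fraction of
#'   substitutions that are synonymous.
#' @export
codonRateMatrix <- function(kappa, omega, freqs = NULL) {
  stopifnot(kappa > 0, omega > 0)
  codons <- senseCodons()
  n <- length(codons)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  stopifnot(length(freqs) == n, all(freqs >= 0))
  freqs <- freqs / sum(freqs)
  sdt <- .singleDiffTable()
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  rate <- freqs[sdt$j] * ifelse(sdt$ts, kappa, 1) * ifelse(sdt$syn, 1, omega)
  Q[cbind(sdt$i, sdt$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  synFlux <- sum((freqs[sdt$i] * rate)[sdt$syn]) / scale
  attr(Q, "synFlux") <- synFlux
  attr(Q, "freqs") <- freqs
  Q
}

## Spectral decomposition of a reversible codon generator; P(t) is then a
## cheap reconstruction per branch length.  Reversibility lets us symmetrise
## with sqrt(pi) and use the stable symmetric eigensolver.
.eigenQ <- function(Q) {
  freqs <- attr(Q, "freqs")
  d <- sqrt(freqs)
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors / d, Uinv = t(e$vectors) * rep(d, each = nrow(Q)) ,
       lambda = e$values, freqs = freqs)
}

.probMatrix <- function(dec, t) {
  P <- (dec$U * rep(exp(dec$lambda * t), each = length(dec$lambda))) %*% dec$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

## Mutational-opportunity site proportions (codeml-style, omega = 1):
## the fraction of the equilibrium substitution flux that is synonymous when
## selection is off; used to convert branch lengths into Ka and Ks.
.sitesFromModel <- function(kappa, freqs = NULL) {
  Q1 <- codonRateMatrix(kappa, 1, freqs)
  attr(Q1, "synFlux")
}
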