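# Independent brute-force oracles, coded directly from first principles and
# kept free of the package's internal tables.

GC_TAB <- Biostrings::GENETIC_CODE
ORACLE_NUC <- c("A", "C", "G", "T")
ORACLE_SENSE <- names(GC_TAB)[GC_TAB != "*"]

oracleIsStop <- function(cod) GC_TAB[[cod]] == "*"

# synonymous site count of one codon: per position, fraction of the
# single-base changes (excluding changes that create a stop codon) that
# preserve the amino acid
oracleSites <- function(cod) {
  b <- strsplit(cod, "")[[1]]
  s <- 0
  for (p in 1:3) {
    neigh <- vapply(setdiff(ORACLE_NUC, b[p]), function(x) {
      y <- b; y[p] <- x; paste(y, collapse = "")
    }, character(1))
    neigh <- neigh[!vapply(neigh, oracleIsStop, logical(1))]
    if (length(neigh) == 0) next
    s <- s + mean(vapply(neigh, function(n) GC_TAB[[n]] == GC_TAB[[cod]],
                         logical(1)))
  }
  s
}

# pathway-averaged synonymous/nonsynonymous differences between two codons:
# enumerate every ordering of the differing positions recursively, drop
# orderings that visit a stop codon, average the per-step classifications
oraclePathways <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, syn, non, blocked) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(syn, non, blocked)
      return(invisible(NULL))
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- b2[p]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      stepBlocked <- blocked || oracleIsStop(to)
      stepSyn <- !oracleIsStop(to) && !oracleIsStop(from) &&
        GC_TAB[[from]] == GC_TAB[[to]]
      recurse(nxt, setdiff(remaining, p),
              syn + as.integer(stepSyn),
              non + as.integer(!stepSyn), stepBlocked)
    }
  }
  recurse(b1, dpos, 0L, 0L, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# exhaustive global-alignment optimum with affine gaps: enumerate all global
# alignments of two short sequences recursively and score each as
# sum(substitution) - sum(gapOpen + len * gapExt) over maximal gap runs
oracleAlignScore <- function(p1, p2, mat, gapOpen = 10, gapExt = 0.5) {
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, state) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1, j + 1, score + mat[a[i], b[j]], "m")
    }
    if (i <= length(a)) {  # gap in b
      pen <- gapExt + if (state == "gb") 0 else gapOpen
      recurse(i + 1, j, score - pen, "gb")
    }
    if (j <= length(b)) {  # gap in a
      pen <- gapExt + if (state == "ga") 0 else gapOpen
      recurse(i, j + 1, score - pen, "ga")
    }
  }
  recurse(1, 1, 0, "m")
  best
}

# exhaustive quartet likelihood: explicit sum over all 61 x 61 internal-node
# state pairs, with transition probabilities from an independently built
# generator exponentiated by scaling-and-squaring (Matrix::expm)
oracleQuartetLik <- function(seqs, lengths, kappa, wBg, wFg, freqs = NULL) {
  n <- length(ORACLE_SENSE)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  isTs <- function(x, y) paste0(sort(c(x, y)), collapse = "") %in% c("AG", "CT")
  Qof <- function(w) {
    Q <- matrix(0, n, n, dimnames = list(ORACLE_SENSE, ORACLE_SENSE))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      bi <- strsplit(ORACLE_SENSE[i], "")[[1]]
      bj <- strsplit(ORACLE_SENSE[j], "")[[1]]
      d <- which(bi != bj)
      if (length(d) != 1) next
      r <- freqs[j]
      if (isTs(bi[d], bj[d])) r <- r * kappa
      if (GC_TAB[[ORACLE_SENSE[i]]] != GC_TAB[[ORACLE_SENSE[j]]]) r <- r * w
      Q[i, j] <- r
    }
    diag(Q) <- -rowSums(Q)
    Q / sum(freqs * rowSums(-Q * diag(n)))  # scale: expected subs/codon = 1
  }
  Pof <- function(w, t) as.matrix(Matrix::expm(Qof(w) * t))
  Ph <- Pof(wBg, lengths[["human"]]); Pc <- Pof(wBg, lengths[["cow"]])
  Pm <- Pof(wBg, lengths[["mouse"]]); Pr <- Pof(wBg, lengths[["rat"]])
  Pi <- Pof(wFg, lengths[["ancestor"]])
  codIdx <- function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    match(cods, ORACLE_SENSE)
  }
  xh <- codIdx(seqs[["human"]]); xm <- codIdx(seqs[["mouse"]])
  xr <- codIdx(seqs[["rat"]]); xc <- codIdx(seqs[["cow"]])
  lnL <- 0
  for (col in seq_along(xh)) {
    tot <- 0
    for (bState in seq_len(n)) {
      inner <- 0
      for (aState in seq_len(n)) {
        inner <- inner + Pi[bState, aState] * Pm[aState, xm[col]] *
          Pr[aState, xr[col]]
      }
      tot <- tot + freqs[bState] * Ph[bState, xh[col]] *
        Pc[bState, xc[col]] * inner
    }
    lnL <- lnL + log(tot)
  }
  lnL
}

# Gillespie-style simulation of one branch: exponential waiting times with
# total rate -Q[i,i], jump probabilities Q[i,j]/-Q[i,i]
gillespieEvolve <- function(startIdx, Q, t) {
  state <- startIdx
  time <- 0
  repeat {
    rate <- -Q[state, state]
    if (rate <= 0) return(state)
    time <- time + stats::rexp(1, rate)
    if (time > t) return(state)
    probs <- Q[state, ]
    probs[state] <- 0
    state <- sample.int(ncol(Q), 1, prob = probs / sum(probs))
  }
}

# random in-frame stop-free coding sequence
randomCds <- function(nCodons) {
  paste(sample(ORACLE_SENSE, nCodons, replace = TRUE), collapse = "")
}
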