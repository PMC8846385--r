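# Independent brute-force oracles. Deliberately naive implementations that
# share no code with the package internals; used to pin down the fast paths.

# literal per-position running-sum enrichment score for one sample
oracleSsgseaSample <- function(values, geneIds, setGenes, alpha,
                               statistic = c("sum", "range")) {
  statistic <- match.arg(statistic)
  n <- length(values)
  r <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  inSet <- geneIds %in% setGenes
  sumW <- sum(r[ord][inSet[ord]]^alpha)
  nOut <- sum(!inSet)
  running <- 0
  path <- numeric(n)
  for (pos in seq_len(n)) {
    g <- ord[pos]
    running <- running +
      if (inSet[g]) r[g]^alpha / sumW else -1 / nOut
    path[pos] <- running
  }
  if (statistic == "sum") sum(path) else max(path) - min(path)
}

# consensus matrix recomputed from stored per-rep assignments
oracleConsensus <- function(draws, repLabels, sampleIds) {
  n <- length(sampleIds)
  coClust <- coSamp <- matrix(0, n, n, dimnames = list(sampleIds, sampleIds))
  for (r in seq_along(draws)) {
    ids <- sampleIds[draws[[r]]]
    lab <- repLabels[[r]]
    for (i in ids) for (j in ids) {
      coSamp[i, j] <- coSamp[i, j] + 1
      if (lab[[i]] == lab[[j]]) coClust[i, j] <- coClust[i, j] + 1
    }
  }
  out <- matrix(0, n, n, dimnames = dimnames(coSamp))
  out[coSamp > 0] <- coClust[coSamp > 0] / coSamp[coSamp > 0]
  diag(out) <- 1
  out
}

# two-group log-rank by explicit hypergeometric O-E summation over the
# pooled event-time grid; returns the standardized statistic for group2
oracleLogrankZ <- function(time, event, inGroup2) {
  times <- sort(unique(time[event == 1]))
  oMinusE <- 0; v <- 0
  for (t in times) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n2 <- sum(atRisk & inGroup2)
    d <- sum(time == t & event == 1)
    d2 <- sum(time == t & event == 1 & inGroup2)
    oMinusE <- oMinusE + (d2 - d * n2 / n)
    if (n > 1)
      v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  list(oMinusE = oMinusE, var = v,
       z = if (v > 0) oMinusE / sqrt(v) else 0,
       chisq = if (v > 0) oMinusE^2 / v else 0)
}

# adjusted Rand index by explicit pair counting
oracleAri <- function(a, b) {
  n <- length(a)
  ss <- sd2 <- ds <- dd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sameA <- a[i] == a[j]; sameB <- b[i] == b[j]
    if (sameA && sameB) ss <- ss + 1
    else if (sameA && !sameB) sd2 <- sd2 + 1
    else if (!sameA && sameB) ds <- ds + 1
    else dd <- dd + 1
  }
  # Hubert-Arabie via pair counts
  tot <- ss + sd2 + ds + dd
  exp_ss <- (ss + sd2) * (ss + ds) / tot
  maxi <- ((ss + sd2) + (ss + ds)) / 2
  if (maxi == exp_ss) return(0)
  (ss - exp_ss) / (maxi - exp_ss)
}

# Kruskal-Wallis H by the hand rank formula
oracleKruskalH <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  h
}
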