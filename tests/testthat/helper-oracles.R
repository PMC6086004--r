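## Independent oracles: deliberately naive re-computations (explicit loops,
## closed forms) that share no code path with the package internals.

## step-up BH by its definition: q_(i) = min_{j >= i} p_(j) * m / j, capped
bhStepUpOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  qSorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, sorted[j] * m / j)
    qSorted[i] <- min(best, 1)
  }
  q <- numeric(m)
  q[o] <- qSorted
  q
}

## hypergeometric upper tail P(X >= k) by summing point masses
hyperTailOracle <- function(k, K, N, n) {
  hi <- min(n, K)
  if (k > hi) return(0)
  total <- 0
  for (j in k:hi)
    total <- total + exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  total
}

## median-of-ratios size factors, spelled out gene by gene
morOracle <- function(counts) {
  nG <- nrow(counts); nS <- ncol(counts)
  geo <- numeric(nG)
  for (g in seq_len(nG)) geo[g] <- prod(counts[g, ])^(1 / nS)
  keep <- which(apply(counts, 1, function(x) all(x > 0)))
  sf <- numeric(nS)
  for (s in seq_len(nS)) sf[s] <- median(counts[keep, s] / geo[keep])
  sf
}

## row-by-row consensus predicate, written as plain ifs
consensusOracle <- function(tab, r1Min = 0.30, qMax = 0.05, r2Min = 0) {
  hits <- character()
  for (i in seq_len(nrow(tab))) {
    if (isTRUE(tab$low_expression[i])) next
    if (tab$r_A1[i] >= r1Min && tab$r_B1[i] >= r1Min &&
        tab$q_A1[i] <= qMax && tab$q_B1[i] <= qMax &&
        tab$r_A2[i] >= r2Min && tab$r_B2[i] >= r2Min)
      hits <- c(hits, tab$gene[i])
  }
  hits
}

## a random but internally consistent profile table (q = BH of p per clone)
randomProfileTable <- function(n, seed, lowFrac = 0) {
  set.seed(seed)
  tab <- data.frame(gene = sprintf("g%04d", sample(9999, n)))
  for (ck in c("A1", "A2", "B1", "B2")) {
    fc <- runif(n, 0, 2)
    p <- runif(n)
    tab[[paste0("fc_", ck)]] <- fc
    tab[[paste0("r_", ck)]] <- 1 - fc
    tab[[paste0("p_", ck)]] <- p
    tab[[paste0("q_", ck)]] <- p.adjust(p, "BH")
  }
  tab$low_expression <- runif(n) < lowFrac
  tab
}

## spreadsheet-style ddCt recomputation, one replicate at a time
ddctOracle <- function(ct, gene, refGene, calibrator) {
  tg <- ct[ct$gene == gene, ]
  dct <- numeric(nrow(tg))
  for (i in seq_len(nrow(tg))) {
    ref <- ct$ct[ct$gene == refGene & ct$sample == tg$sample[i]]
    dct[i] <- tg$ct[i] - ref
  }
  calMean <- mean(dct[tg$condition == calibrator])
  rel <- 2^(-(dct - calMean))
  conds <- unique(tg$condition)
  vapply(conds, function(cc) {
    vals <- rel[tg$condition == cc]
    exp(mean(log(vals)))
  }, numeric(1))
}
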