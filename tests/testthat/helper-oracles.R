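# Independent brute-force oracles. These recompute the quantities the
# package estimates via a different route (full enumeration / explicit
# running sums) and must never call the implementation they check.

# Full running-sum GSEA enrichment score: walk the whole ranked list,
# increment by |s|^w / NR at members, decrement by 1/(N - k) otherwise,
# return the extreme deviation (first index on ties).
oracleGseaES <- function(scores, members, weight) {
  N <- length(scores)
  hit <- names(scores) %in% members
  k <- sum(hit)
  w <- abs(scores)^weight
  NR <- sum(w[hit])
  inc <- if (NR > 0) ifelse(hit, w / NR, 0) else ifelse(hit, 1 / k, 0)
  dec <- ifelse(hit, 0, 1 / (N - k))
  running <- cumsum(inc - dec)
  # earliest position wins on (near-)ties of the absolute deviation
  running[which(abs(running) >= max(abs(running)) - 1e-12)[1]]
}

# Two-tailed Fisher p by hypergeometric enumeration over all tables with
# the observed margins (probability-mass rule, with the customary
# relative slack on "not exceeding" the observed probability).
oracleFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kcol <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, kcol - n):min(kcol, m)
  probs <- dhyper(support, m, n, kcol)
  sum(probs[probs <= dhyper(x, m, n, kcol) * (1 + 1e-7)])
}

# Exact two-sided rank-sum p: enumerate every assignment of the pooled
# observations to the first group, with average ranks for ties.
oracleRankSumP <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  sums <- combn(r, m, FUN = sum)
  min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
}

# Exact two-sided signed-rank p: enumerate all 2^n sign assignments of
# the ranked absolute differences.
oracleSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(mask)
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]), numeric(1))
  min(1, 2 * min(mean(sums <= V + 1e-9), mean(sums >= V - 1e-9)))
}

# Log-rank chi-square from first principles: a 2x2 table at every
# distinct event time, O - E with hypergeometric variance.
oracleLogrankChisq <- function(tA, eA, tB, eB) {
  times <- sort(unique(c(tA[eA == 1], tB[eB == 1])))
  O <- E <- V <- 0
  for (s in times) {
    nA <- sum(tA >= s); nB <- sum(tB >= s); N <- nA + nB
    dA <- sum(tA == s & eA == 1); dB <- sum(tB == s & eB == 1)
    d <- dA + dB
    O <- O + dA
    E <- E + d * nA / N
    if (N > 1) V <- V + d * (nA / N) * (nB / N) * (N - d) / (N - 1)
  }
  (O - E)^2 / V
}

# Step-up BH oracle written from the definition (sorted p * n / rank,
# running minimum from the largest p, capped at 1).
oracleBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[ord] * n / seq_len(n)))))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Hand-built cohort rows.
cohortRow <- function(id, genotype, lesionTime, lesionEvent,
                      followupTime = 400, deathEvent = 0) {
  data.frame(subject_id = id, genotype = genotype,
             lesion_time = lesionTime, lesion_event = lesionEvent,
             followup_time = followupTime, death_event = deathEvent,
             stringsAsFactors = FALSE)
}

# Cohort in which every subject of a genotype shares one outcome.
degenerateCohort <- function(n = 10) {
  rbind(
    cohortRow(sprintf("W%02d", 1:n), "WT", 400, 0),
    cohortRow(sprintf("A%02d", 1:n), "SIRT2KO", 400, 0),
    cohortRow(sprintf("B%02d", 1:n), "SOD1KO", 400, 0),
    cohortRow(sprintf("D%02d", 1:n), "DKO", 50, 1))
}

# DEG table with fully specified columns for worked examples.
degTable <- function(gene, log2fc, padj, length = 1000,
                     pvalue = pmin(padj, 1), meanCount = 100) {
  data.frame(gene_id = gene, log2fc = log2fc, pvalue = pvalue,
             padj = padj, mean_count = meanCount,
             transcript_length = length, stringsAsFactors = FALSE)
}
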