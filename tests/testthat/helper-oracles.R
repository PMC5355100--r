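# Independent brute-force oracles; deliberately naive and kept apart from
# the implementation paths they check.

# BH step-up by direct enumeration of the defining minimum
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- seq_len(m)
  adj <- numeric(m)
  for (i in ranks) {
    js <- which(p[o] >= p[o][i])
    adj[o[i]] <- min(1, min(m * p[o][js] / ranks[js]))
  }
  adj
}

# pooled equal-variance two-sample Student t, textbook formula
tTwoSampleOracle <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), df = n1 + n2 - 2)
}

tPairedOracle <- function(x, y) {
  d <- x - y
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * pt(-abs(t), df = length(d) - 1)
}

# upper-tail hypergeometric by summing the mass term by term
hyperOracle <- function(N, K, n, x) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# AUC by exhaustive comparison of every (pos, neg) pair
aucOracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# tiny paired set built by hand: intensities chosen, not simulated
toyPairedSet <- function(tumor, normal, ids = NULL, class = NULL) {
  nPairs <- ncol(tumor)
  if (is.null(ids)) ids <- paste0("probe", seq_len(nrow(tumor)))
  m <- matrix(0, nrow(tumor), 2 * nPairs)
  m[, seq(1, 2 * nPairs, 2)] <- tumor
  m[, seq(2, 2 * nPairs, 2)] <- normal
  pairs <- paste0("pr", seq_len(nPairs))
  colnames(m) <- as.vector(rbind(paste0(pairs, "_T"), paste0(pairs, "_N")))
  rownames(m) <- ids
  PairedExpressionSet(m, pairId = rep(pairs, each = 2),
                      group = rep(c("tumor", "normal"), nPairs),
                      probeClass = class)
}
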