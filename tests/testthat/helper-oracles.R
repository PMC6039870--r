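# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use the most naive formulation of
# each quantity.

# AUC as the fraction of concordant (positive, negative) score pairs,
# counting ties as 1/2 (Mann-Whitney statistic).
oracleAucConcordance <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities <= the observed
# table's probability (with a relative tolerance for float comparison).
oracleFisher2x2 <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  kRange <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(kRange, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, 0)
  pObs <- probs[match(tab[1, 1], kRange)]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Edge-replicated median filter by direct per-pixel window collection
# with clamped indices.
oracleMedianFilter <- function(x, k) {
  h <- (k - 1) / 2
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    ri <- pmin(pmax(i + (-h:h), 1), nrow(x))
    ci <- pmin(pmax(j + (-h:h), 1), ncol(x))
    out[i, j] <- median(x[ri, ci])
  }
  out
}

# Exhaustive best integer shift by directly scanning all offsets and
# computing the Pearson correlation of the overlap.
oracleBestShift <- function(ref, mov, m) {
  best <- c(NA, NA); bestC <- -Inf
  for (dy in -m:m) for (dx in -m:m) {
    ri <- which(seq_len(nrow(ref)) + dy >= 1 & seq_len(nrow(ref)) + dy <= nrow(ref))
    ci <- which(seq_len(ncol(ref)) + dx >= 1 & seq_len(ncol(ref)) + dx <= ncol(ref))
    a <- as.vector(ref[ri, ci]); b <- as.vector(mov[ri + dy, ci + dx])
    if (sd(a) == 0 || sd(b) == 0) next
    cc <- cor(a, b)
    if (cc > bestC + 1e-12) { bestC <- cc; best <- c(dy, dx) }
  }
  best
}

# Spearman coefficient from first principles: Pearson correlation of ranks.
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sample permutation p-value (difference of means, two-sided)
# by enumerating every assignment of the pooled values to the two groups.
oracleTwoSamplePermutation <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  obs <- abs(mean(b) - mean(a))
  idx <- utils::combn(n, length(a))
  stats <- apply(idx, 2, function(ii)
    abs(mean(pool[-ii]) - mean(pool[ii])))
  mean(stats >= obs - 1e-12)
}

# A small scored screen built by hand for I/O tests.
makeTinyScoreTable <- function() {
  data.frame(
    pair_id = rep(c("pA", "pB"), each = 3),
    experiment_id = rep(c("1", "2", NA), 2),
    level = rep(c("replicate", "replicate", "aggregate"), 2),
    bret = c(0.30, 0.32, 0.31, 0.21, 0.19, 0.20),
    control1_bret = 0.01, control2_bret = 0.02,
    c_bret = c(0.28, 0.30, 0.29, 0.005, 0.007, 0.006),
    luc = 0.5, control1_luc = 0.01, control2_luc = 0.02,
    c_luc = c(0.40, 0.42, 0.41, 0.01, 0.012, 0.011),
    cf = 0.2, pir_panl = 0.15, cf_scope = "plate",
    uncorrected = FALSE, stringsAsFactors = FALSE)
}
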