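# Random valid tumor-bed compositions (rows sum to 100) for property tests.
random_compositions <- function(n, max_viable = 95) {
  g <- matrix(rgamma(4 * n, shape = 1), ncol = 4)
  m <- 100 * g / rowSums(g)
  # keep some stroma so stromal typing is defined
  m[, 1] <- pmin(m[, 1], max_viable)
  m <- 100 * m / rowSums(m)
  colnames(m) <- c("viable_pct", "necrosis_pct", "inflammatory_pct", "fibrotic_pct")
  as.data.frame(m)
}

# Exhaustive Youden search: every observed value as threshold, explicit
# counting, first (smallest) maximizer.
youden_bruteforce <- function(values, labels, positive = "good") {
  pos <- labels == positive
  cand <- sort(unique(values))
  best <- NULL
  for (c in cand) {
    sens <- mean(values[pos] > c)
    spec <- mean(values[!pos] <= c)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-9)
      best <- list(cutoff = c, youden = j, sensitivity = sens, specificity = spec)
  }
  best
}

# Hypergeometric enumeration for the two-sided Fisher p-value, written from
# the combinatorial definition (no dhyper).
fisher_bruteforce <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  pmf <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- pmf[match(a, support)]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}
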