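# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and distribution functions) of the implementation:
# everything is built from binomial coefficients, double loops or full
# enumeration.

# P(above-group toxic count >= c) by enumerating every 2x2 table with the
# observed margins. Table layout: a,b = below toxic/non; c,d = above.
oracle_fisher_one_sided <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- c + d; N <- m + n
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  sum(probs[xs >= c])
}

# Two-sided Fisher p for k1/n1 vs k2/n2 by full table enumeration, summing
# tables no more probable than the observed one (classic tie rule).
oracle_fisher_two_sided <- function(k1, n1, k2, n2) {
  m <- k1 + k2; n <- (n1 - k1) + (n2 - k2); k <- n1; N <- m + n
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(N, k)
  p_obs <- probs[xs == k1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Symmetric mean distance to agreement by an explicit O(n^2) double loop.
oracle_mda <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  min_ab <- numeric(nrow(a)); min_ba <- numeric(nrow(b))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    min_ab[i] <- best
  }
  for (j in seq_len(nrow(b))) {
    best <- Inf
    for (i in seq_len(nrow(a)))
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    min_ba[j] <- best
  }
  (mean(min_ab) + mean(min_ba)) / 2
}

# Exact two-sided rank-sum p by enumerating every assignment of ranks to
# the first sample (no ties assumed), with the usual doubled-tail rule.
oracle_wilcoxon_two_sided <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(idx) sum(idx) - m * (m + 1) / 2)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  p <- if (u_obs > m * n / 2) 2 * upper else 2 * lower
  min(1, p)
}

# Strip class/attribute decoration so tables can be compared value-wise.
df_plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

# A tiny hand-built cohort used by several tests.
toy_cohort <- function() {
  as_cohort(data.frame(
    patient_id = c("a", "b", "c"),
    cohort = "PDS",
    dose_gland = c(25.5, 30.25, 0),
    dose_duct_total = c(10.1, NA, 22.75),
    dose_duct_ig = c(12.5, 14, 21),
    proctcae_6mo = c(0L, 2L, NA),
    proctcae_12mo = c(1L, NA, 4L)))
}
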