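#' Pearson chi-squared test on a contingency table of cohort counts
#'
#' Tests independence of a categorical patient characteristic and cohort
#' membership. Yates' continuity correction is applied for 2x2 tables only
#' (when `correct = TRUE`); larger tables use the uncorrected Pearson
#' statistic with `df = (r - 1)(c - 1)`.
#'
#' @param counts r x c matrix of non-negative integer counts, r, c >= 2.
#' @param correct apply Yates' correction to 2x2 tables.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
chisq_test <- function(counts, correct = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2x2 table")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0))
    stop("row margin is zero: ", paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0))
    stop("column margin is zero: ", paste(which(cs == 0), collapse = ", "))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two continuous samples (e.g. planning target volumes or mean
#' doses between cohorts). The exact distribution of the rank-sum statistic
#' is used for combined sample sizes up to 20 without ties; otherwise the
#' normal approximation with midranks, tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples, each with at least one observation.
#' @return list with `statistic` (the Mann-Whitney U of `x`) and `p_value`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    stop("each sample needs at least one observation")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 20 && !ties
  ht <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = !exact)
  list(statistic = unname(ht$statistic), p_value = min(1, ht$p.value),
       exact = exact)
}

#' Compare two proportions by a two-sided Fisher exact test
#'
#' Exact two-sided test for `k1/n1` vs `k2/n2` (e.g. constraint-adherence
#' rates in two cohorts). The two-sided p-value sums the probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table. A chi-squared test with Yates' correction is
#' available as an alternative.
#'
#' @param k1,n1,k2,n2 successes and totals in the two groups, `k <= n`.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @return two-sided p-value.
#' @export
proportion_compare <- function(k1, n1, k2, n2, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  counts <- c(k1, n1, k2, n2)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (k1 > n1 || k2 > n2) stop("k must not exceed n")
  if (n1 + n2 == 0) stop("empty table")
  if (method == "chisq") {
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
    return(chisq_test(tab)$p_value)
  }
  m <- k1 + k2               # total successes
  n <- (n1 - k1) + (n2 - k2) # total failures
  k <- n1                    # group-1 size
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(k1, m, n, k)
  # same tie rule as the classic exact test: include tables whose
  # probability is within relative epsilon of the observed one
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
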