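#' Dose-difference and distance-to-agreement summary for validation pairs
#'
#' Summarizes how well surrogate (atlas-based) mean duct doses track the
#' reference (MRI sialography based) doses: the mean and sample standard
#' deviation (divisor n - 1) of the reference-minus-surrogate dose
#' differences, and the mean of the per-patient mean distance to agreement
#' over pairs where it is available.
#'
#' @param pairs a `validation_pairs` data.frame (or any data.frame with
#'   `dose_ref`, `dose_est` and optionally `mda` columns).
#' @param structure optional filter: keep only rows whose `structure`
#'   column equals this value (`"total"` or `"ig"`).
#' @return an `agreement_summary`: `n`, `mean_diff` (Gy), `sd_diff` (Gy),
#'   `mean_mda` (mm, `NA` when no pair carries an MDA).
#' @export
difference_stats <- function(pairs, structure = NULL) {
  pairs <- as.data.frame(pairs)
  if (!is.null(structure)) {
    if (!"structure" %in% names(pairs))
      stop("pairs have no 'structure' column to filter on")
    pairs <- pairs[pairs$structure == structure, , drop = FALSE]
  }
  diffs <- pairs$dose_ref - pairs$dose_est
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2)
    stop("need at least 2 complete dose pairs (got ", n,
         "): standard deviation undefined")
  mda <- if ("mda" %in% names(pairs)) pairs$mda[!is.na(pairs$mda)] else numeric(0)
  res <- list(n = n,
              mean_diff = mean(diffs),
              sd_diff = stats::sd(diffs),
              mean_mda = if (length(mda)) mean(mda) else NA_real_)
  class(res) <- "agreement_summary"
  res
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Agreement over %d validation pairs\n", x$n))
  cat(sprintf("  dose difference (reference - surrogate): %.2f +/- %.2f Gy\n",
              x$mean_diff, x$sd_diff))
  if (!is.na(x$mean_mda))
    cat(sprintf("  mean distance to agreement: %.2f mm\n", x$mean_mda))
  invisible(x)
}

as_point_matrix <- function(x, arg) {
  x <- as.matrix(x)
  if (ncol(x) != 3)
    stop(arg, " must be an n x 3 matrix of coordinates in mm")
  storage.mode(x) <- "double"
  if (nrow(x) < 1) stop(arg, " must contain at least one point")
  if (!all(is.finite(x))) stop(arg, " contains non-finite coordinates")
  x
}

#' Symmetric mean distance to agreement between two contour point sets
#'
#' For each point of one set, the Euclidean distance to its nearest
#' neighbour in the other set is taken; the mean of those distances is
#' computed in both directions and the two directional means are averaged.
#' This point-cloud definition is this package's operational MDA; treatment
#' planning systems may use surface-based variants.
#'
#' @param a,b contour point sets: n x 3 matrices (or data.frames) of
#'   coordinates in mm.
#' @return mean distance to agreement in mm.
#' @export
mean_distance_to_agreement <- function(a, b) {
  a <- as_point_matrix(a, "a")
  b <- as_point_matrix(b, "b")
  tb <- t(b)
  near_ab <- vapply(seq_len(nrow(a)), function(i)
    sqrt(min(colSums((tb - a[i, ])^2))), numeric(1))
  ta <- t(a)
  near_ba <- vapply(seq_len(nrow(b)), function(j)
    sqrt(min(colSums((ta - b[j, ])^2))), numeric(1))
  (mean(near_ab) + mean(near_ba)) / 2
}
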