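#' Dichotomize a PRO-CTCAE dry-mouth score into a toxicity indicator
#'
#' A score of moderate or worse (2--4) counts as a patient-reported
#' toxicity; none or mild (0--1) counts as no toxicity. Missing scores stay
#' missing.
#'
#' @param score integer vector of PRO-CTCAE scores in 0--4, `NA` allowed.
#' @return integer vector of 0/1 toxicity indicators with `NA` preserved.
#' @export
dichotomize <- function(score) {
  bad <- !is.na(score) & (!score %in% 0:4)
  if (any(bad))
    stop("PRO-CTCAE score out of range 0..4: ",
         paste(unique(score[bad]), collapse = ", "))
  ifelse(is.na(score), NA_integer_, as.integer(score >= 2))
}

#' One-sided Fisher exact test for a dose-group by toxicity table
#'
#' Computes the exact hypergeometric tail probability that, conditional on
#' the table margins, the above-cut-point group contains at least its
#' observed number of toxic patients. The alternative is therefore
#' "toxicity rate is higher above the cut-point".
#'
#' @param table 2x2 matrix of counts with rows = dose group (below, above)
#'   and columns = outcome (toxic, non-toxic); or the count `a` (below
#'   group, toxic) with `b`, `c`, `d` supplied separately.
#' @param b,c,d counts: below/non-toxic, above/toxic, above/non-toxic.
#' @return p-value in (0, 1].
#' @export
fisher_one_sided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n_tot <- sum(counts)
  if (n_tot < 1) stop("empty table")
  m <- a + c          # toxic margin
  n <- b + d          # non-toxic margin
  k <- c + d          # above-group size
  # P(X >= c) for X ~ Hypergeometric(m, n, k)
  stats::phyper(c - 1, m, n, k, lower.tail = FALSE)
}

#' Search for the maximally separating mean-dose cut-point
#'
#' Scans candidate mean-dose thresholds on a regular grid (1 Gy by default)
#' over the observed duct dose range. At each grid value and timepoint,
#' evaluable patients are split into dose `< c` vs `>= c` groups and a
#' one-sided Fisher exact test compares their patient-reported toxicity
#' rates. Grid values where any evaluated timepoint yields a group smaller
#' than `min_group` are excluded; among the rest, the cut-point minimizing
#' the combined criterion across timepoints is selected (ties broken toward
#' the lowest dose, i.e. the most protective constraint).
#'
#' Patients missing the relevant duct dose are dropped entirely; patients
#' missing an outcome at one timepoint are excluded from that timepoint
#' only. A timepoint with fewer than `2 * min_group` evaluable patients can
#' satisfy the group-size constraint nowhere and is dropped from the scan
#' with a diagnostic note.
#'
#' @param cohort a `cohort_table`.
#' @param structure `"ig"` (intraglandular ducts) or `"total"` (total
#'   ducts): which mean duct dose to scan.
#' @param grid_step grid spacing in Gy; candidate cut-points are the
#'   multiples of `grid_step` inside the observed dose range.
#' @param min_group minimum number of evaluable patients required on each
#'   side of the cut-point, at every evaluated timepoint.
#' @param combine how the per-timepoint p-values are combined into the
#'   selection criterion: `"max"` (worst-case across timepoints, default)
#'   or `"product"`.
#' @return a `cutpoint_scan` object: the grid, per-timepoint p-values
#'   (`NA` where the size constraint fails), the combined criterion, the
#'   selected cut-point (`NA` when no grid value is admissible) and the
#'   group composition at the selection.
#' @seealso [rate_table()] for the toxicity-rate summary at a given
#'   cut-point.
#' @export
scan_cutpoints <- function(cohort, structure = c("ig", "total"),
                           grid_step = 1, min_group = 10,
                           combine = c("max", "product")) {
  structure <- match.arg(structure)
  combine <- match.arg(combine)
  stopifnot(inherits(cohort, "cohort_table"), grid_step > 0, min_group >= 1)
  dose_col <- if (structure == "ig") "dose_duct_ig" else "dose_duct_total"
  dat <- as.data.frame(cohort)
  dat <- dat[!is.na(dat[[dose_col]]), , drop = FALSE]
  if (!nrow(dat)) stop("no patients with a ", dose_col, " dose")
  dose <- dat[[dose_col]]

  timepoints <- c("6mo", "12mo")
  score_cols <- c("6mo" = "proctcae_6mo", "12mo" = "proctcae_12mo")
  evaluable <- lapply(score_cols, function(col) which(!is.na(dat[[col]])))
  n_eval <- vapply(evaluable, length, integer(1))
  if (!any(n_eval >= 2 * min_group))
    stop("no timepoint has at least ", 2 * min_group,
         " evaluable patients; cannot satisfy the group-size constraint")
  dropped <- timepoints[n_eval > 0 & n_eval < 2 * min_group]
  eval_tp <- timepoints[n_eval >= 2 * min_group]

  lo <- ceiling(min(dose) / grid_step)
  hi <- floor(max(dose) / grid_step)
  grid <- if (lo > hi) numeric(0) else seq(lo, hi) * grid_step
  diagnostic <- character(0)
  if (length(dropped))
    diagnostic <- c(diagnostic, paste0(
      "timepoint(s) ", paste(dropped, collapse = ", "),
      " dropped: fewer than ", 2 * min_group, " evaluable patients"))

  p_mat <- matrix(NA_real_, length(grid), length(timepoints),
                  dimnames = list(NULL, timepoints))
  ok <- rep(length(grid) > 0, length(grid))
  for (tp in eval_tp) {
    tox <- dichotomize(dat[[score_cols[[tp]]]][evaluable[[tp]]])
    d_tp <- dose[evaluable[[tp]]]
    for (i in seq_along(grid)) {
      below <- d_tp < grid[i]
      n_below <- sum(below); n_above <- sum(!below)
      if (n_below < min_group || n_above < min_group) {
        ok[i] <- FALSE
        next
      }
      p_mat[i, tp] <- fisher_one_sided(
        sum(tox[below]), n_below - sum(tox[below]),
        sum(tox[!below]), n_above - sum(tox[!below]))
    }
  }
  combined <- rep(NA_real_, length(grid))
  if (length(eval_tp)) {
    agg <- if (combine == "max") function(p) max(p) else function(p) prod(p)
    for (i in which(ok))
      combined[i] <- agg(p_mat[i, eval_tp])
  } else {
    ok[] <- FALSE
  }

  selected <- NA_real_
  groups_at_selected <- NULL
  if (any(ok)) {
    best <- min(combined[ok])
    selected <- min(grid[ok & combined <= best])  # lowest-dose tie-break
    groups_at_selected <- lapply(eval_tp, function(tp) {
      tox <- dichotomize(dat[[score_cols[[tp]]]][evaluable[[tp]]])
      d_tp <- dose[evaluable[[tp]]]
      below <- d_tp < selected
      data.frame(timepoint = tp, group = c("below", "above"),
                 n_toxic = c(sum(tox[below]), sum(tox[!below])),
                 n_total = c(sum(below), sum(!below)))
    })
    groups_at_selected <- do.call(rbind, groups_at_selected)
  } else {
    diagnostic <- c(diagnostic, paste0(
      "no grid value keeps both groups at >= ", min_group,
      " evaluable patients at every evaluated timepoint"))
  }

  res <- list(structure = structure, grid = grid,
              p_6mo = p_mat[, "6mo"], p_12mo = p_mat[, "12mo"],
              combined = combined, selected_cutpoint = selected,
              groups_at_selected = groups_at_selected,
              timepoints_evaluated = eval_tp,
              grid_step = grid_step, min_group = min_group,
              combine = combine, n_evaluable = n_eval,
              diagnostic = diagnostic)
  class(res) <- "cutpoint_scan"
  res
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat("Mean-dose cut-point scan (", x$structure, " ducts)\n", sep = "")
  if (length(x$grid))
    cat(sprintf("  grid: %g..%g Gy in %g Gy steps; min group size %d; combine = %s\n",
                min(x$grid), max(x$grid), x$grid_step, x$min_group, x$combine))
  else
    cat("  empty grid: observed dose range contains no candidate cut-point\n")
  if (is.na(x$selected_cutpoint)) {
    cat("  no admissible cut-point\n")
  } else {
    i <- match(x$selected_cutpoint, x$grid)
    cat(sprintf("  selected cut-point: %g Gy (criterion %.3g; p6mo %.3g, p12mo %.3g)\n",
                x$selected_cutpoint, x$combined[i], x$p_6mo[i], x$p_12mo[i]))
  }
  for (d in x$diagnostic) cat("  note: ", d, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cutpoint_scan <- function(object, ...) {
  print(object)
  if (!is.null(object$groups_at_selected)) {
    cat("Groups at the selected cut-point:\n")
    g <- object$groups_at_selected
    g$rate <- round(g$n_toxic / g$n_total, 3)
    print(g, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.cutpoint_scan <- function(object, ...) {
  c(cutpoint_gy = object$selected_cutpoint)
}

#' @export
plot.cutpoint_scan <- function(x, ...) {
  ylim <- c(0, 1)
  graphics::plot(x$grid, x$combined, type = "b", pch = 16, ylim = ylim,
                 xlab = "candidate cut-point (Gy)",
                 ylab = "p-value", main = paste0("Cut-point scan (",
                                                x$structure, " ducts)"), ...)
  graphics::lines(x$grid, x$p_6mo, lty = 2, col = "grey40")
  graphics::lines(x$grid, x$p_12mo, lty = 3, col = "grey40")
  if (!is.na(x$selected_cutpoint))
    graphics::abline(v = x$selected_cutpoint, col = 2, lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3),
                   col = c("black", "grey40", "grey40"),
                   legend = c(paste("combined (", x$combine, ")"),
                              "6 months", "12 months"))
  invisible(x)
}

#' Toxicity-rate table at a given cut-point
#'
#' Splits patients into dose `< cutpoint` vs `>= cutpoint` groups for the
#' chosen duct structure and reports, per timepoint, the toxic/evaluable
#' counts in each group together with each group's mean bilateral parotid
#' gland dose. An empty group yields an undefined (`NA`) rate, never 0.
#'
#' @inheritParams scan_cutpoints
#' @param cutpoint mean-dose threshold in Gy.
#' @return a `rate_table` object.
#' @export
rate_table <- function(cohort, structure = c("ig", "total"), cutpoint) {
  structure <- match.arg(structure)
  stopifnot(inherits(cohort, "cohort_table"), is.finite(cutpoint))
  dose_col <- if (structure == "ig") "dose_duct_ig" else "dose_duct_total"
  dat <- as.data.frame(cohort)
  dat <- dat[!is.na(dat[[dose_col]]), , drop = FALSE]
  below <- dat[[dose_col]] < cutpoint
  gland <- vapply(list(below, !below), function(sel) {
    g <- dat$dose_gland[sel]
    if (!length(g)) NA_real_ else mean(g, na.rm = TRUE)
  }, numeric(1))
  names(gland) <- c("below", "above")
  score_cols <- c("6mo" = "proctcae_6mo", "12mo" = "proctcae_12mo")
  rows <- list()
  for (tp in names(score_cols)) {
    tox <- dichotomize(dat[[score_cols[[tp]]]])
    for (grp in c("below", "above")) {
      sel <- if (grp == "below") below else !below
      t_sel <- tox[sel]
      n_tot <- sum(!is.na(t_sel))
      n_tox <- sum(t_sel, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = tp, group = grp, n_toxic = n_tox, n_total = n_tot,
        rate = if (n_tot > 0) n_tox / n_tot else NA_real_)
    }
  }
  res <- list(structure = structure, cutpoint = cutpoint,
              mean_gland_dose = gland, groups = do.call(rbind, rows))
  class(res) <- "rate_table"
  res
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("Xerostomia rates at %s duct cut-point %g Gy\n",
              x$structure, x$cutpoint))
  cat(sprintf("  mean bilateral gland dose: below %.1f Gy, above %.1f Gy\n",
              x$mean_gland_dose[["below"]], x$mean_gland_dose[["above"]]))
  g <- x$groups
  g$rate <- ifelse(is.na(g$rate), "undefined", sprintf("%.0f%%", 100 * g$rate))
  print(g, row.names = FALSE)
  invisible(x)
}
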