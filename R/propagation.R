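# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fit the Gaussian surrogate-dose error model
#'
#' The surrogate-dose error is modelled as Normal(mu, sigma) where mu and
#' sigma are the mean and sample standard deviation of the
#' reference-minus-surrogate dose differences in a validation set.
#'
#' @inheritParams difference_stats
#' @return an `error_model`: `mu` (Gy), `sigma` (Gy), `n_fit`.
#' @export
fit_error_model <- function(pairs, structure = NULL) {
  s <- difference_stats(pairs, structure = structure)
  error_model(mu = s$mean_diff, sigma = s$sd_diff, n_fit = s$n)
}

#' @rdname fit_error_model
#' @param mu,sigma Gaussian error mean and standard deviation in Gy.
#' @param n_fit number of validation pairs behind the estimate (0 when the
#'   model is specified directly).
#' @export
error_model <- function(mu, sigma, n_fit = 0L) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  res <- list(mu = mu, sigma = sigma, n_fit = as.integer(n_fit))
  class(res) <- "error_model"
  res
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Gaussian dose-error model: mu = %.3g Gy, sigma = %.3g Gy (n = %d)\n",
              x$mu, x$sigma, x$n_fit))
  invisible(x)
}

#' Monte-Carlo propagation of surrogate-dose error through constraint
#' classification
#'
#' Estimates how often surrogate dose estimates classify patients correctly
#' against a mean-dose constraint. In each of `R` replicates an independent
#' error draw `delta ~ Normal(mu, sigma)` is added to every reference dose
#' (`sign = "add"`, the default) to emulate a surrogate estimate; a patient
#' *meets* the constraint when the dose is strictly below it, and meeting
#' the constraint is the positive class. Sensitivity and specificity are
#' pooled over all `R * n` estimates; per-replicate classification counts
#' are kept for dispersion.
#'
#' With `sign = "subtract"` the draw is subtracted instead, matching the
#' convention in which the fitted error is reference minus surrogate.
#'
#' @param true_doses numeric vector of reference mean doses in Gy.
#' @param constraint mean-dose constraint in Gy.
#' @param model an [error_model()].
#' @param R number of replicates.
#' @param seed integer seed; the result is bit-reproducible given the seed.
#' @param sign `"add"` or `"subtract"`: how the error draw enters the
#'   surrogate estimate.
#' @return a `propagation` object with pooled `sensitivity` and
#'   `specificity` (undefined rates reported as `NA` with a diagnostic, not
#'   as 0), total counts, and a per-replicate count table.
#' @seealso [analytic_sens_spec()] for the closed-form limit.
#' @export
propagate <- function(true_doses, constraint, model, R = 100, seed = NULL,
                      sign = c("add", "subtract")) {
  sign <- match.arg(sign)
  stopifnot(inherits(model, "error_model"), length(true_doses) >= 1,
            all(is.finite(true_doses)), is.finite(constraint), R >= 1)
  n <- length(true_doses)
  truth <- true_doses < constraint  # positive class: meets the constraint
  per_rep <- with_seed(seed, {
    t(vapply(seq_len(R), function(r) {
      delta <- stats::rnorm(n, model$mu, model$sigma)
      est <- if (sign == "add") true_doses + delta else true_doses - delta
      pred <- est < constraint
      c(tp = sum(pred & truth), fn = sum(!pred & truth),
        tn = sum(!pred & !truth), fp = sum(pred & !truth))
    }, numeric(4)))
  })
  totals <- colSums(per_rep)
  diagnostic <- character(0)
  sens <- if (sum(truth) == 0) {
    diagnostic <- c(diagnostic,
                    "no patient meets the constraint: sensitivity undefined")
    NA_real_
  } else unname(totals["tp"] / (totals["tp"] + totals["fn"]))
  spec <- if (sum(!truth) == 0) {
    diagnostic <- c(diagnostic,
                    "every patient meets the constraint: specificity undefined")
    NA_real_
  } else unname(totals["tn"] / (totals["tn"] + totals["fp"]))
  res <- list(n_patients = n, replicates = R, total_estimates = R * n,
              constraint = constraint, model = model, sign = sign,
              sensitivity = sens, specificity = spec,
              counts = totals,
              per_replicate = data.frame(replicate = seq_len(R), per_rep),
              seed = seed, diagnostic = diagnostic)
  class(res) <- "propagation"
  res
}

#' @export
print.propagation <- function(x, ...) {
  cat(sprintf("Monte-Carlo error propagation: %d patients x %d replicates = %d estimates\n",
              x$n_patients, x$replicates, x$total_estimates))
  cat(sprintf("  constraint %g Gy; error N(%.3g, %.3g) Gy (%s)\n",
              x$constraint, x$model$mu, x$model$sigma, x$sign))
  cat(sprintf("  sensitivity %s, specificity %s (positive = meets constraint)\n",
              format_rate(x$sensitivity), format_rate(x$specificity)))
  for (d in x$diagnostic) cat("  note: ", d, "\n", sep = "")
  invisible(x)
}

format_rate <- function(p) if (is.na(p)) "undefined" else sprintf("%.1f%%", 100 * p)

#' @export
summary.propagation <- function(object, ...) {
  print(object)
  pr <- object$per_replicate
  sens_r <- pr$tp / (pr$tp + pr$fn)
  spec_r <- pr$tn / (pr$tn + pr$fp)
  cat(sprintf("  per-replicate sensitivity: %.3f (SD %.3f); specificity: %.3f (SD %.3f)\n",
              mean(sens_r, na.rm = TRUE), stats::sd(sens_r),
              mean(spec_r, na.rm = TRUE), stats::sd(spec_r)))
  invisible(object)
}

#' Closed-form sensitivity and specificity of surrogate classification
#'
#' The exact large-replicate limit of [propagate()]: with surrogate
#' estimate `d + delta`, `delta ~ Normal(mu, sigma)`, the probability that a
#' patient with reference dose `d` is predicted to meet constraint `c` is
#' `pnorm((c - d - mu) / sigma)`. Sensitivity is that probability averaged
#' over patients truly meeting the constraint; specificity is the
#' complement averaged over the rest. With `sigma = 0` the indicator limits
#' are used (each patient classified deterministically).
#'
#' @inheritParams propagate
#' @return named numeric vector `c(sensitivity, specificity)`; a rate whose
#'   truth class is empty is `NA` with a warning.
#' @export
analytic_sens_spec <- function(true_doses, constraint, model,
                               sign = c("add", "subtract")) {
  sign <- match.arg(sign)
  stopifnot(inherits(model, "error_model"), length(true_doses) >= 1,
            all(is.finite(true_doses)), is.finite(constraint))
  mu <- if (sign == "add") model$mu else -model$mu
  meets <- true_doses < constraint
  p_pred_meets <- if (model$sigma > 0)
    stats::pnorm((constraint - true_doses - mu) / model$sigma)
  else
    as.numeric(true_doses + mu < constraint)
  sens <- if (any(meets)) mean(p_pred_meets[meets]) else {
    warning("no patient meets the constraint: sensitivity undefined")
    NA_real_
  }
  spec <- if (any(!meets)) mean(1 - p_pred_meets[!meets]) else {
    warning("every patient meets the constraint: specificity undefined")
    NA_real_
  }
  c(sensitivity = sens, specificity = spec)
}
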