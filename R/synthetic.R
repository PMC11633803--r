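#' Configuration for the synthetic duct-sparing cohort generator
#'
#' Defaults emulate the duct-sparing study cohort: 38 patients, bilateral
#' parotid gland mean doses around 27.2 Gy (SD 5.7 Gy), duct doses coupled
#' linearly to the gland dose with additive Gaussian scatter, a logistic
#' dose--toxicity response centred at 14 Gy on the intraglandular duct
#' dose, follow-up completeness of 33/38 at 6 months and 29/38 at 12
#' months, and a surrogate-dose error of Normal(0.96, 2.9) Gy.
#'
#' @param n_patients cohort size.
#' @param gland_dose_mean,gland_dose_sd Gaussian marginal of the bilateral
#'   parotid gland mean dose (Gy); draws are truncated at 0.
#' @param duct_given_gland_slope linear coupling of duct to gland dose.
#' @param duct_dose_sd SD (Gy) of the additive Gaussian scatter around the
#'   linear gland-duct relation.
#' @param toxicity_model `"logistic"` (Bernoulli with probability
#'   `plogis((dose - d50)/steepness)`) or `"step"` (deterministic: toxic
#'   iff dose >= `threshold_d50`). The response is driven by the
#'   intraglandular duct dose.
#' @param threshold_d50 dose (Gy) of 50\% toxicity probability (logistic)
#'   or the hard threshold (step).
#' @param logistic_steepness logistic scale parameter (Gy).
#' @param followup_6mo_prob,followup_12mo_prob probability that a patient
#'   is evaluable (returns a questionnaire) at each timepoint.
#' @param error_mu,error_sigma Gaussian surrogate-dose error (Gy), carried
#'   along for convenience of downstream propagation runs.
#' @param seed integer master seed; every random sub-stream derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 38,
                       gland_dose_mean = 27.2, gland_dose_sd = 5.7,
                       duct_given_gland_slope = 0.5, duct_dose_sd = 4,
                       toxicity_model = c("logistic", "step"),
                       threshold_d50 = 14, logistic_steepness = 2,
                       followup_6mo_prob = 33 / 38,
                       followup_12mo_prob = 29 / 38,
                       error_mu = 0.96, error_sigma = 2.9,
                       seed = 1L) {
  toxicity_model <- match.arg(toxicity_model)
  stopifnot(n_patients >= 1, gland_dose_sd >= 0, duct_dose_sd >= 0,
            logistic_steepness > 0, error_sigma >= 0,
            followup_6mo_prob >= 0, followup_6mo_prob <= 1,
            followup_12mo_prob >= 0, followup_12mo_prob <= 1)
  cfg <- list(n_patients = as.integer(n_patients),
              gland_dose_mean = gland_dose_mean,
              gland_dose_sd = gland_dose_sd,
              duct_given_gland_slope = duct_given_gland_slope,
              duct_dose_sd = duct_dose_sd,
              toxicity_model = toxicity_model,
              threshold_d50 = threshold_d50,
              logistic_steepness = logistic_steepness,
              followup_6mo_prob = followup_6mo_prob,
              followup_12mo_prob = followup_12mo_prob,
              error_mu = error_mu, error_sigma = error_sigma,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

toxicity_prob <- function(dose, cfg) {
  if (cfg$toxicity_model == "step")
    as.numeric(dose >= cfg$threshold_d50)
  else
    stats::plogis((dose - cfg$threshold_d50) / cfg$logistic_steepness)
}

#' Simulate a synthetic duct-sparing cohort
#'
#' Gland doses are Gaussian; each duct dose (total and intraglandular) is
#' linear in the gland dose plus independent Gaussian scatter, truncated at
#' 0 Gy. A latent toxicity indicator is drawn per timepoint from the
#' configured dose--response evaluated on the intraglandular duct dose;
#' toxic patients report a PRO-CTCAE score of 3, non-toxic patients 1, so
#' dichotomization stays on the analysis path while outcomes are
#' deterministic given the latent draw. Each timepoint is observed
#' independently with its follow-up probability; unobserved scores are
#' missing.
#'
#' @param config a [sim_config()].
#' @return a `cohort_table` with `cohort = "SYNTH"`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    gland <- pmax(0, stats::rnorm(n, config$gland_dose_mean,
                                  config$gland_dose_sd))
    duct_ig <- pmax(0, config$duct_given_gland_slope * gland +
                      stats::rnorm(n, 0, config$duct_dose_sd))
    duct_total <- pmax(0, config$duct_given_gland_slope * gland +
                         stats::rnorm(n, 0, config$duct_dose_sd))
    p_tox <- toxicity_prob(duct_ig, config)
    tox_6 <- stats::rbinom(n, 1, p_tox)
    tox_12 <- stats::rbinom(n, 1, p_tox)
    seen_6 <- stats::rbinom(n, 1, config$followup_6mo_prob) == 1
    seen_12 <- stats::rbinom(n, 1, config$followup_12mo_prob) == 1
    score_6 <- ifelse(seen_6, ifelse(tox_6 == 1, 3L, 1L), NA_integer_)
    score_12 <- ifelse(seen_12, ifelse(tox_12 == 1, 3L, 1L), NA_integer_)
    as_cohort(data.frame(
      patient_id = sprintf("S%03d", seq_len(n)),
      cohort = "SYNTH",
      dose_gland = gland,
      dose_duct_total = duct_total,
      dose_duct_ig = duct_ig,
      proctcae_6mo = score_6,
      proctcae_12mo = score_12,
      stringsAsFactors = FALSE),
      provenance = sprintf("simulate_cohort(seed=%d)", config$seed))
  })
}

#' Simulate reference/surrogate dose validation pairs
#'
#' Reference doses are uniform on `ref_dose_range`; the dose difference
#' (reference minus surrogate) is Normal(mu, sigma), so the surrogate dose
#' is `dose_ref - dose_diff`.
#'
#' @param n number of pairs.
#' @param mu,sigma Gaussian dose-difference mean and SD (Gy).
#' @param ref_dose_range length-2 range (Gy) of the uniform reference dose.
#' @param seed integer seed.
#' @param structure structure label for the pairs.
#' @return a `validation_pairs` data.frame (`mda` is missing).
#' @export
simulate_validation_pairs <- function(n, mu, sigma,
                                      ref_dose_range = c(5, 25),
                                      seed = NULL, structure = "total") {
  stopifnot(n >= 1, sigma >= 0, length(ref_dose_range) == 2)
  with_seed(seed, {
    ref <- stats::runif(n, ref_dose_range[1], ref_dose_range[2])
    diff <- stats::rnorm(n, mu, sigma)
    as_validation_pairs(data.frame(
      patient_id = sprintf("V%05d", seq_len(n)),
      structure = structure,
      mda = NA_real_,
      dose_ref = ref,
      dose_est = ref - diff,
      dose_diff = diff,
      stringsAsFactors = FALSE))
  })
}

#' Simulate a pair of contour point sets with a known rigid offset
#'
#' Generates a base point set on a simple shape and a copy rigidly
#' translated by `offset_mm` along an axis perpendicular to the shape's
#' main extent (the y axis for a line, the z axis otherwise). For the
#' straight line the symmetric mean distance to agreement of the pair
#' equals `offset_mm` exactly at any sampling density.
#'
#' @param shape `"line"` (50 mm segment), `"ellipse"` (20 x 10 mm, in the
#'   xy plane) or `"tube"` (radius 5 mm, length 40 mm, points scattered on
#'   the surface).
#' @param offset_mm rigid translation in mm.
#' @param n_points points per set (>= 2).
#' @param seed integer seed (used by `"tube"`, which samples randomly).
#' @return list with elements `a` and `b`, each an n x 3 coordinate matrix.
#' @export
simulate_contour_pair <- function(shape = c("line", "ellipse", "tube"),
                                  offset_mm, n_points, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(n_points >= 2, is.finite(offset_mm))
  base <- with_seed(seed, switch(shape,
    line = cbind(x = seq(0, 50, length.out = n_points), y = 0, z = 0),
    ellipse = {
      t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
      cbind(x = 20 * cos(t), y = 10 * sin(t), z = 0)
    },
    tube = {
      ang <- stats::runif(n_points, 0, 2 * pi)
      cbind(x = stats::runif(n_points, 0, 40),
            y = 5 * cos(ang), z = 5 * sin(ang))
    }))
  shift <- if (shape == "line") c(0, offset_mm, 0) else c(0, 0, offset_mm)
  list(a = base, b = sweep(base, 2, -shift))
}
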