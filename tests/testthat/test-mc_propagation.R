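test_that("the error model is the mean/SD of reference-minus-surrogate doses", {
  t4 <- load_fixture("table4")
  em <- fit_error_model(t4, "total")
  expect_equal(em$mu, 0.9642857, tolerance = 1e-6)
  expect_equal(em$sigma, 2.852423, tolerance = 1e-6)
  expect_equal(em$n_fit, 14L)
  zero <- data.frame(dose_ref = c(5, 9, 14), dose_est = c(5, 9, 14))
  em0 <- fit_error_model(zero)
  expect_equal(c(em0$mu, em0$sigma), c(0, 0))
  expect_error(fit_error_model(zero[1, ]), "at least 2")
  expect_error(error_model(0, -1), "sigma")
})

test_that("the fitted model recovers a known error law from simulated pairs", {
  p <- simulate_validation_pairs(50000, mu = 1.6, sigma = 3.6, seed = 13)
  em <- fit_error_model(p)
  expect_lt(abs(em$mu - 1.6), 3 * 3.6 / sqrt(50000))
  expect_lt(abs(em$sigma - 3.6), 3 * 3.6 / sqrt(2 * 50000))
})

test_that("zero error classifies perfectly; same seed is bit-reproducible", {
  doses <- c(5, 8, 11, 13, 15, 20)
  pr <- propagate(doses, 12, error_model(0, 0), R = 50, seed = 1)
  expect_equal(pr$sensitivity, 1)
  expect_equal(pr$specificity, 1)
  expect_equal(pr$total_estimates, 300)
  em <- error_model(0.96, 2.9)
  p1 <- propagate(doses, 12, em, R = 200, seed = 42)
  p2 <- propagate(doses, 12, em, R = 200, seed = 42)
  expect_identical(p1$per_replicate, p2$per_replicate)
  p3 <- propagate(doses, 12, em, R = 200, seed = 43)
  expect_false(identical(p1$per_replicate, p3$per_replicate))
})

test_that("Monte-Carlo rates converge to the closed-form oracle", {
  t4 <- load_fixture("table4")
  doses <- t4$dose_ref[t4$structure == "total"]
  em <- error_model(0.96, 2.9)
  an <- analytic_sens_spec(doses, 12, em)
  pr <- propagate(doses, 12, em, R = 4000, seed = 99)
  n_pos <- sum(doses < 12) * pr$replicates
  n_neg <- sum(doses >= 12) * pr$replicates
  se_sens <- sqrt(an["sensitivity"] * (1 - an["sensitivity"]) / n_pos)
  se_spec <- sqrt(an["specificity"] * (1 - an["specificity"]) / n_neg)
  expect_lt(abs(pr$sensitivity - an["sensitivity"]), 3 * se_sens)
  expect_lt(abs(pr$specificity - an["specificity"]), 3 * se_spec)
})

test_that("analytic limits: symmetry point, far doses, huge noise, sigma = 0", {
  em <- error_model(1, 2)
  # a dose sitting exactly at constraint - mu is classified at chance level
  expect_equal(unname(suppressWarnings(
    analytic_sens_spec(11, 12, em))["sensitivity"]), 0.5)
  # doses many sigma away from the constraint are always classified right
  far <- analytic_sens_spec(c(1, 30), 12, error_model(0, 1))
  expect_equal(unname(far), c(1, 1), tolerance = 1e-6)
  # with enormous noise the prediction ignores the truth entirely
  huge <- analytic_sens_spec(c(8, 10, 14, 18), 12, error_model(0, 1e7))
  expect_equal(unname(huge), c(0.5, 0.5), tolerance = 1e-5)
  # sigma = 0 degenerates to deterministic indicators
  det0 <- analytic_sens_spec(c(10, 11.5, 14), 12, error_model(1, 0))
  expect_equal(unname(det0), c(0.5, 1))
})

test_that("propagation is invariant to shifting doses and constraint together", {
  doses <- c(6, 9, 12.5, 14, 17)
  em <- error_model(0.5, 2)
  p1 <- propagate(doses, 12, em, R = 300, seed = 8)
  p2 <- propagate(doses + 25, 37, em, R = 300, seed = 8)
  expect_identical(p1$counts, p2$counts)
  a1 <- analytic_sens_spec(doses, 12, em)
  a2 <- analytic_sens_spec(doses + 25, 37, em)
  expect_equal(a1, a2)
})

test_that("one-sided dose configurations give undefined rates, not zeros", {
  em <- error_model(0, 1)
  pr <- propagate(c(20, 25, 30), 12, em, R = 20, seed = 2)
  expect_true(is.na(pr$sensitivity))
  expect_false(is.na(pr$specificity))
  expect_match(pr$diagnostic, "sensitivity undefined", all = FALSE)
  expect_warning(an <- analytic_sens_spec(c(20, 25), 12, em), "undefined")
  expect_true(is.na(an["sensitivity"]))
})

test_that("the subtract sign convention mirrors the error mean", {
  doses <- c(8, 10, 11, 13, 16)
  em <- error_model(1.5, 2)
  a_sub <- analytic_sens_spec(doses, 12, em, sign = "subtract")
  a_neg <- analytic_sens_spec(doses, 12, error_model(-1.5, 2), sign = "add")
  expect_equal(a_sub, a_neg)
  pr <- propagate(doses, 12, em, R = 5000, seed = 3, sign = "subtract")
  expect_lt(abs(pr$sensitivity - a_sub["sensitivity"]), 0.02)
  expect_lt(abs(pr$specificity - a_sub["specificity"]), 0.02)
})
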