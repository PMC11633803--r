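test_that("PRO-CTCAE dichotomization uses the moderate-or-worse threshold", {
  expect_identical(dichotomize(c(0L, 1L, 2L, 3L, 4L)),
                   c(0L, 0L, 1L, 1L, 1L))
  expect_identical(dichotomize(c(NA_integer_, 2L)), c(NA_integer_, 1L))
  expect_error(dichotomize(5L), "out of range")
  expect_error(dichotomize(-1L), "out of range")
})

test_that("one-sided Fisher test equals the hypergeometric tail", {
  # frozen from exhaustive enumeration of the margins (Tables 2-3 counts)
  expect_equal(fisher_one_sided(5, 14, 12, 2), 9.54215e-4, tolerance = 1e-5)
  expect_equal(fisher_one_sided(6, 13, 11, 3), 9.418409e-3, tolerance = 1e-6)
  # with no toxic patient at all, only one table is possible
  expect_equal(fisher_one_sided(0, 10, 0, 12), 1)
  expect_equal(fisher_one_sided(matrix(c(5, 14, 12, 2), 2, byrow = TRUE)),
               fisher_one_sided(5, 14, 12, 2))
  expect_error(fisher_one_sided(0, 0, 0, 0), "empty")
  expect_error(fisher_one_sided(1, -1, 2, 3), "non-negative")
})

test_that("one-sided Fisher test agrees with an independent implementation", {
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    mine <- fisher_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(t(tab), alternative = "less")$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
    expect_gt(mine, 0); expect_lte(mine, 1)
  }
})

test_that("moving an above-group patient from non-toxic to toxic never raises p", {
  set.seed(7)
  for (i in 1:30) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    c0 <- sample(0:10, 1); d0 <- sample(1:10, 1)
    expect_lte(fisher_one_sided(a, b, c0 + 1, d0 - 1),
               fisher_one_sided(a, b, c0, d0) + 1e-12)
  }
})

perfectly_separated_cohort <- function() {
  n <- 15
  as_cohort(data.frame(
    patient_id = sprintf("p%02d", 1:(2 * n)),
    cohort = "SYNTH",
    dose_gland = 27,
    dose_duct_total = c(seq(3, 10, length.out = n), seq(20, 27, length.out = n)),
    dose_duct_ig = c(seq(3, 10, length.out = n), seq(20, 27, length.out = n)),
    proctcae_6mo = rep(c(1L, 3L), each = n),
    proctcae_12mo = rep(c(1L, 3L), each = n)))
}

test_that("a perfectly separated cohort yields a cut-point between the clusters", {
  co <- perfectly_separated_cohort()
  sc <- scan_cutpoints(co, "ig")
  expect_gt(sc$selected_cutpoint, 10)
  expect_lte(sc$selected_cutpoint, 20)
  i <- match(sc$selected_cutpoint, sc$grid)
  # the minimum p attainable for margins 15/15 with 15 toxic
  expect_equal(sc$p_6mo[i], oracle_fisher_one_sided(0, 15, 15, 0))
  expect_equal(sc$combined[i], max(sc$p_6mo[i], sc$p_12mo[i]))
  # lowest admissible perfect cut wins the tie-break
  expect_equal(sc$selected_cutpoint, 11)
})

test_that("the scan is invariant to patient order and equivariant to dose shifts", {
  co <- simulate_cohort(sim_config(n_patients = 120, seed = 31))
  sc <- scan_cutpoints(co, "ig")
  perm <- as.data.frame(co)[sample(nrow(co)), ]
  sc_perm <- scan_cutpoints(as_cohort(perm), "ig")
  expect_equal(sc_perm$selected_cutpoint, sc$selected_cutpoint)
  expect_equal(sc_perm$p_6mo, sc$p_6mo)
  shifted <- as.data.frame(co)
  shifted$dose_duct_ig <- shifted$dose_duct_ig + 7
  sc_shift <- scan_cutpoints(as_cohort(shifted), "ig")
  expect_equal(sc_shift$selected_cutpoint, sc$selected_cutpoint + 7)
  expect_equal(sc_shift$combined, sc$combined)
})

test_that("group sizes at any cut-point sum to the evaluable counts", {
  co <- simulate_cohort(sim_config(n_patients = 80, seed = 12))
  sc <- scan_cutpoints(co, "total")
  g <- sc$groups_at_selected
  for (tp in c("6mo", "12mo")) {
    expect_equal(sum(g$n_total[g$timepoint == tp]),
                 unname(sc$n_evaluable[tp]))
  }
})

test_that("size constraints, timepoint exclusion and degenerate grids are handled", {
  co <- perfectly_separated_cohort()
  # p-values missing where a group falls below the minimum size
  sc <- scan_cutpoints(co, "ig")
  small <- sc$grid < 8 | sc$grid > 22
  expect_true(all(is.na(sc$p_6mo[small])))
  expect_true(all(is.na(sc$combined[small])))
  # 12-month outcomes removed for most patients: timepoint dropped, not fatal
  few12 <- as.data.frame(co)
  few12$proctcae_12mo[1:25] <- NA_integer_
  sc2 <- scan_cutpoints(as_cohort(few12), "ig")
  expect_identical(sc2$timepoints_evaluated, "6mo")
  expect_true(all(is.na(sc2$p_12mo)))
  expect_match(sc2$diagnostic, "12mo", all = FALSE)
  # min_group too large for the cohort: explicit error
  expect_error(scan_cutpoints(co, "ig", min_group = 20), "evaluable")
  # doses clustered between grid points: no candidate, diagnosed not crashed
  tight <- as.data.frame(co)
  tight$dose_duct_ig <- 14.2 + seq(0, 0.4, length.out = nrow(tight))
  sc3 <- scan_cutpoints(as_cohort(tight), "ig")
  expect_true(is.na(sc3$selected_cutpoint))
  expect_length(sc3$grid, 0)
})

test_that("product combination is available and changes only the criterion", {
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 19))
  sc_max <- scan_cutpoints(co, "ig", combine = "max")
  sc_prod <- scan_cutpoints(co, "ig", combine = "product")
  expect_equal(sc_prod$p_6mo, sc_max$p_6mo)
  ok <- !is.na(sc_prod$combined)
  expect_equal(sc_prod$combined[ok],
               (sc_max$p_6mo * sc_max$p_12mo)[ok])
})

test_that("rate_table matches a direct recount and flags empty groups", {
  co <- simulate_cohort(sim_config(n_patients = 90, seed = 23))
  rt <- rate_table(co, "ig", 14)
  dat <- as.data.frame(co)
  for (tp in c("6mo", "12mo")) {
    col <- if (tp == "6mo") "proctcae_6mo" else "proctcae_12mo"
    for (grp in c("below", "above")) {
      sel <- if (grp == "below") dat$dose_duct_ig < 14 else dat$dose_duct_ig >= 14
      scores <- dat[[col]][sel]
      row <- rt$groups[rt$groups$timepoint == tp & rt$groups$group == grp, ]
      expect_equal(row$n_total, sum(!is.na(scores)))
      expect_equal(row$n_toxic, sum(scores >= 2, na.rm = TRUE))
      expect_equal(row$rate, row$n_toxic / row$n_total)
    }
  }
  expect_equal(unname(rt$mean_gland_dose["below"]),
               mean(dat$dose_gland[dat$dose_duct_ig < 14]))
  # nobody above the cut-point: the rate is undefined, not zero
  rt2 <- rate_table(co, "ig", 1000)
  above <- rt2$groups[rt2$groups$group == "above", ]
  expect_true(all(is.na(above$rate)))
  expect_true(all(above$n_total == 0))
})
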