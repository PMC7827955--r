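# MTT assay simulation and apparent-IC50 extraction.

test_that("simulate_mtt viability identities hold", {
  p <- growth_parameters(0.5, 1e5, 5000)
  eff <- drug_effect(0.9, 0.1)
  s <- simulate_mtt(p, eff, doses = c(0, mtt_dose_grid()), day = 4)
  expect_identical(s$viability[s$dose_ug_ml == 0], 1)
  expect_true(all(diff(s$viability) <= 1e-12))  # non-increasing in dose
  expect_warning(s0 <- simulate_mtt(p, eff, mtt_dose_grid(), day = 0),
                 "degenerate")
  expect_equal(s0$viability, rep(1, 9))
})

test_that("simulate_mtt matches the hand-composed closed form", {
  # Emax = 1 at saturating dose: treated well sits frozen at N0
  p <- growth_parameters(0.5, 1e5, 500)
  s <- simulate_mtt(p, drug_effect(1, 1e-9), doses = c(10), day = 4)
  expect_equal(s$viability,
               500 / (500 * 1e5 / (500 + (1e5 - 500) * exp(-0.5 * 4))))
  # general case against the oracle formula
  s2 <- simulate_mtt(growth_parameters(0.4, 8e4, 5000),
                     drug_effect(0.85, 0.2), mtt_dose_grid(), day = 6)
  expect_equal(s2$viability,
               oracle_viability(s2$dose_ug_ml, 6, 0.4, 8e4, 5000, 0.85, 0.2))
})

test_that("apparent_ic50 interpolates, censors, and smooths per contract", {
  exact <- data.frame(dose_ug_ml = c(0.1, 1, 10),
                      viability = c(1.0, 0.5, 0.2))
  res <- apparent_ic50(exact)
  expect_identical(res$ic50, 1)

  high <- data.frame(dose_ug_ml = c(0.1, 1, 10),
                     viability = c(0.99, 0.95, 0.9))
  res2 <- apparent_ic50(high)
  expect_false(res2$reached)
  expect_true(is.na(res2$ic50))

  wiggle <- data.frame(dose_ug_ml = c(0.1, 0.3, 1, 3, 10),
                       viability = c(0.9, 0.95, 0.6, 0.4, 0.35))
  res3 <- apparent_ic50(wiggle)
  expect_match(res3$method, "monotone")
  expect_true(res3$reached)

  expect_error(apparent_ic50(exact[1:2, ]), "3")
})

test_that("apparent_ic50 agrees with bisection on model-generated curves", {
  p <- growth_parameters(0.5, 1e5, 5000)
  half_step <- log10(2) / 2  # half a twofold dilution, in log10 units
  for (ic in c(0.05, 0.2, 0.8)) {
    eff <- drug_effect(1, ic)
    for (day in c(2, 4, 8)) {
      s <- simulate_mtt(p, eff, mtt_dose_grid(), day)
      est <- apparent_ic50(s)
      truth <- oracle_ic50_bisect(day, p$lambda, p$K, p$N0, eff$Emax,
                                  eff$IC50)
      if (est$reached && !is.na(truth))
        expect_lt(abs(log10(est$ic50) - log10(truth)), half_step)
    }
  }
})

test_that("ll4 extraction is close to the interpolation estimate", {
  p <- growth_parameters(0.5, 1e5, 5000)
  s <- simulate_mtt(p, drug_effect(1, 0.2), mtt_dose_grid(), day = 4)
  a <- apparent_ic50(s, method = "interpolation")
  b <- apparent_ic50(s, method = "ll4")
  expect_true(b$reached)
  expect_lt(abs(log10(a$ic50) - log10(b$ic50)), log10(2) / 2)
})

test_that("ic50_vs_time yields the day-resolved curve with propagated NAs", {
  # control must still be growing at day 8 for the downward trend
  # (K/N0 = 200, lambda*8 = 3.2 keeps it far from capacity)
  p <- growth_parameters(0.4, 1e6, 5000)
  curve <- ic50_vs_time(p, drug_effect(1, 0.2))
  expect_identical(curve$day, c(2, 4, 6, 8))
  expect_identical(nrow(curve), 4L)
  reached <- curve$reached
  expect_true(all(diff(curve$ic50_ug_ml[reached]) <= 1e-12))

  none <- ic50_vs_time(p, drug_effect(0, 0.2))
  expect_true(all(!none$reached))
  expect_true(all(is.na(none$ic50_ug_ml)))
})

test_that("apparent IC50 is non-increasing in day and matches per-day bisection", {
  p <- growth_parameters(0.4, 1e6, 5000)
  eff <- drug_effect(0.95, 0.15)
  doses <- 10^seq(-3, 1.5, length.out = 40)  # dense grid: interpolation error small
  curve <- ic50_vs_time(p, eff, doses = doses, days = c(2, 4, 6, 8))
  expect_true(all(diff(curve$ic50_ug_ml) <= 0))
  for (i in seq_len(nrow(curve))) {
    truth <- oracle_ic50_bisect(curve$day[i], p$lambda, p$K, p$N0,
                                eff$Emax, eff$IC50)
    expect_equal(log10(curve$ic50_ug_ml[i]), log10(truth),
                 tolerance = 0.02)
  }
})

test_that("the downward IC50 trend reverses once the control saturates", {
  # with K/N0 = 20 the control nears capacity inside the 8-day window;
  # mildly suppressed wells then catch up and the apparent IC50 ticks up —
  # the non-increasing trend is a pre-saturation property, not a theorem
  p <- growth_parameters(0.5, 1e5, 5000)
  curve <- ic50_vs_time(p, drug_effect(1, 0.2), days = c(2, 6, 8, 14))
  expect_lt(curve$ic50_ug_ml[2], curve$ic50_ug_ml[1])
  expect_gt(curve$ic50_ug_ml[4], curve$ic50_ug_ml[2])
})

test_that("in the net-death regime the apparent IC50 approaches its limit dose", {
  # for Emax > 1 doses above IC50/(Emax-1) kill and doses below grow to K,
  # so the viability crossing converges to that threshold as day grows
  p <- growth_parameters(0.5, 1e5, 5000)
  eff <- drug_effect(1.5, 0.2)
  limit <- eff$IC50 / (eff$Emax - 1)
  days <- c(5, 10, 20, 40, 80)
  ic <- vapply(days, function(d)
    oracle_ic50_bisect(d, p$lambda, p$K, p$N0, eff$Emax, eff$IC50),
    numeric(1))
  gaps <- abs(ic - limit)
  expect_true(all(diff(gaps) < 0))  # distance to the limit shrinks
  expect_lt(gaps[length(gaps)] / limit, 0.25)
})

test_that("with Emax = 1 the long-run viability at saturating dose is N0/K", {
  p <- growth_parameters(0.5, 1e5, 5000)
  s <- simulate_mtt(p, drug_effect(1, 1e-6), doses = c(1), day = 200)
  expect_equal(s$viability, p$N0 / p$K, tolerance = 0.01)
})

test_that("compare_formulations reports exact model-level ratios", {
  p <- growth_parameters(0.5, 1e5, 5000)
  a <- drug_effect(0.8, 0.54)
  same <- compare_formulations(a, a, p)
  expect_true(all(abs(same$by_day$ratio_a_over_b[same$by_day$ic50_a > 0] - 1)
                  < 1e-12, na.rm = TRUE))
  expect_identical(same$model_ic50_fold, 1)
  expect_identical(same$model_emax_fold, 1)

  b <- drug_effect(0.8 * 1.1, 0.54 / 5.4)
  cmp <- compare_formulations(a, b, p)
  expect_equal(cmp$model_ic50_fold, 5.4)
  expect_equal(cmp$model_emax_fold, 1.1)
})

test_that("per-day apparent ratios match bisection-derived values", {
  p <- growth_parameters(0.5, 1e5, 5000)
  a <- drug_effect(0.9, 0.4)
  b <- drug_effect(0.9, 0.2)   # IC50 ratio 2 at shared Emax
  doses <- 10^seq(-3, 1, length.out = 60)
  cmp <- compare_formulations(a, b, p, doses = doses)
  for (i in seq_along(cmp$by_day$day)) {
    d <- cmp$by_day$day[i]
    ra <- oracle_ic50_bisect(d, p$lambda, p$K, p$N0, a$Emax, a$IC50)
    rb <- oracle_ic50_bisect(d, p$lambda, p$K, p$N0, b$Emax, b$IC50)
    expect_equal(cmp$by_day$ratio_a_over_b[i], ra / rb, tolerance = 0.05)
  }
})
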