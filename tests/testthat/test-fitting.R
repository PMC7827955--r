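# Two-step SSR/Nelder-Mead estimation and the bootstrap.

make_noisefree <- function(params = truth_params(),
                           effect = truth_effect(), replicates = 3) {
  generate_growth_dataset(params, effect,
                          design_preset("growth", replicates = replicates),
                          noise_model(sigma = 0))
}

test_that("ssr sums squared residuals over individual replicates", {
  ds <- make_noisefree()
  pred_exact <- unique(as.data.frame(ds)[c("dose_ug_ml", "day", "count")])
  expect_identical(ssr(ds, pred_exact), 0)

  two <- growth_dataset(data.frame(
    cell_line = "x", condition = "drug", dose_ug_ml = c(1, 1),
    day = c(2, 4), replicate = 1:2, count = c(13, 24)))
  pred <- data.frame(dose_ug_ml = c(1, 1), day = c(2, 4), count = c(10, 20))
  expect_identical(ssr(two, pred), 25)  # 3^2 + 4^2

  # brute-force re-summation on a random replicated dataset
  set.seed(11)
  ds2 <- generate_growth_dataset(truth_params(), truth_effect(),
                                 design_preset("growth"),
                                 noise_model(sigma = 0.2), seed = 11)
  p <- truth_params()
  pred2 <- as.data.frame(ds2)[c("dose_ug_ml", "day")]
  pred2$count <- logistic_solution(
    pred2$day, p,
    rate = effective_rate(p, efficacy(pred2$dose_ug_ml, truth_effect())))
  expect_equal(ssr(ds2, pred2), oracle_ssr(ds2$count, pred2$count))

  pred_missing <- pred[pred$day != 4, ]
  expect_error(ssr(two, pred_missing), "day = 4")
})

test_that("ssr is invariant to record order", {
  set.seed(3)
  ds <- generate_growth_dataset(truth_params(), truth_effect(),
                                design_preset("growth"),
                                noise_model(sigma = 0.1), seed = 3)
  pred <- as.data.frame(ds)[c("dose_ug_ml", "day")]
  pred$count <- 1000
  pred <- unique(pred)
  shuffled <- subset_dataset(ds, sample(nrow(ds)))
  expect_equal(ssr(ds, pred), ssr(shuffled, pred))
})

test_that("fit_control recovers truth from noise-free data", {
  p <- growth_parameters(0.55, 8e4, 1000)
  ds <- generate_growth_dataset(p, drug_effect(0, 1),
                                design_preset("growth",
                                              plating_density = 1000),
                                noise_model(sigma = 0))
  fit <- fit_control(ds)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["lambda"]], 0.55, tolerance = 1e-3)
  expect_equal(fit$estimates[["K"]], 8e4, tolerance = 1e-3)

  # optimum beats a log-grid around truth
  grid <- expand.grid(lambda = exp(seq(log(0.55 * 0.5), log(0.55 * 1.5),
                                       length.out = 50)),
                      K = exp(seq(log(8e4 * 0.5), log(8e4 * 1.5),
                                  length.out = 50)))
  ctrl <- control_subset(ds)
  node_ssr <- mapply(function(l, k)
    sum((ctrl$count - logistic_solution(ctrl$day,
                                        growth_parameters(l, k, 1000)))^2),
    grid$lambda, grid$K)
  expect_lte(fit$ssr, min(node_ssr))
})

test_that("fit_control handles degenerate inputs per contract", {
  base <- data.frame(cell_line = "x", condition = "control",
                     dose_ug_ml = 0, day = seq(2, 10, 2), replicate = 1L,
                     count = 0)
  expect_error(fit_control(growth_dataset(base, plating_density = 500)),
               "degenerate")
  sat <- base; sat$count <- 500
  fit <- fit_control(growth_dataset(sat, plating_density = 500))
  expect_equal(fit$estimates[["K"]], 500, tolerance = 0.01)
  expect_match(paste(fit$flags, collapse = " "), "unidentifiable")
  short <- base[1:2, ]; short$count <- c(10, 20)
  expect_error(fit_control(growth_dataset(short, plating_density = 500)),
               "3 distinct days")
})

test_that("fit_treated recovers (Emax, IC50) jointly from noise-free data", {
  p <- truth_params()
  eff <- drug_effect(Emax = 0.8, IC50 = 0.002)
  ds <- generate_growth_dataset(p, eff, design_preset("growth"),
                                noise_model(sigma = 0))
  fit <- fit_treated(ds, p)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["Emax"]], 0.8, tolerance = 0.01)
  expect_equal(fit$estimates[["IC50"]], 0.002, tolerance = 0.01)

  # pooled optimum beats a (Emax, log10 IC50) grid around truth
  trt <- treated_subset(ds)
  grid <- expand.grid(Emax = seq(0, 2, length.out = 50),
                      IC50 = 10^seq(log10(0.002) - 1, log10(0.002) + 1,
                                    length.out = 50))
  node_ssr <- mapply(function(e, ic) {
    r <- effective_rate(p, efficacy(trt$dose_ug_ml, drug_effect(e, ic)))
    sum((trt$count - logistic_solution(trt$day, p, rate = r))^2)
  }, grid$Emax, grid$IC50)
  expect_lte(fit$ssr, min(node_ssr))
})

test_that("fit_treated detects a drug with no effect", {
  p <- truth_params()
  ds <- generate_growth_dataset(p, drug_effect(0, 0.002),
                                design_preset("growth"),
                                noise_model(sigma = 0))
  fit <- fit_treated(ds, p)
  expect_lte(fit$estimates[["Emax"]], 0.01)
  # treated curves equal control curves, so optimum SSR is ~the control SSR
  expect_lte(fit$ssr, 1e-6)
})

test_that("fit_treated flags identifiability and boundary issues", {
  p <- truth_params()
  ds <- generate_growth_dataset(p, truth_effect(),
                                design_preset("growth",
                                              doses = c(0, 5e-3)),
                                noise_model(sigma = 0))
  fit <- fit_treated(ds, p)
  expect_match(paste(fit$flags, collapse = " "), "confounded")
})

test_that("two-step fit is exact at truth and deterministic under perturbation", {
  ds <- make_noisefree()
  p <- truth_params()
  fit <- fit_treated(ds, p)
  expect_equal(fit$estimates[["Emax"]], 0.9, tolerance = 1e-6)
  expect_equal(fit$estimates[["IC50"]], 0.002, tolerance = 1e-6)

  p_pert <- growth_parameters(p$lambda * 1.1, p$K * 1.1, p$N0)
  f1 <- fit_treated(ds, p_pert)
  f2 <- fit_treated(ds, p_pert)
  expect_identical(f1$estimates, f2$estimates)
  expect_false(isTRUE(all.equal(f1$estimates, fit$estimates)))
})

test_that("bootstrap is seed-deterministic and degenerate on noise-free data", {
  ds <- make_noisefree()
  fit <- fit_two_step(ds)
  b1 <- bootstrap_ci(ds, fit, n_boot = 25, seed = 99)
  b2 <- bootstrap_ci(ds, fit, n_boot = 25, seed = 99)
  expect_identical(b1$bootstrap_samples, b2$bootstrap_samples)
  b3 <- bootstrap_ci(ds, fit, n_boot = 25, seed = 100)
  expect_false(identical(b1$bootstrap_samples, b3$bootstrap_samples))

  for (part in c("control", "treated")) {
    rel_width <- (b1[[part]]$ci_upper - b1[[part]]$ci_lower) /
      b1[[part]]$estimates
    expect_true(all(rel_width <= 1e-3))
    expect_true(all(b1[[part]]$ci_lower <= b1[[part]]$estimates + 1e-12))
    expect_true(all(b1[[part]]$ci_upper >= b1[[part]]$estimates - 1e-12))
  }
})

test_that("bootstrap falls back to residual resampling without replicates", {
  ds <- generate_growth_dataset(truth_params(), truth_effect(),
                                design_preset("growth", replicates = 1),
                                noise_model(sigma = 0.05), seed = 21)
  fit <- fit_control(ds)
  b <- bootstrap_ci(ds, fit, n_boot = 30, seed = 5)
  expect_true(is.matrix(b$bootstrap_samples))
  expect_true(all(b$ci_upper > b$ci_lower))
})

test_that("bootstrap_ci validates its preconditions", {
  ds <- make_noisefree()
  fit <- fit_control(ds)
  expect_error(bootstrap_ci(ds, fit, n_boot = 1), "n_boot")
  fit$converged <- FALSE
  expect_error(bootstrap_ci(ds, fit, n_boot = 10), "converged")
})
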