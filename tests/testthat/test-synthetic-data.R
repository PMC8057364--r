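test_that("simulation is reproducible and passes validation untouched", {
  cfg <- scenario_config(n_households = 500, seed = 7)
  s1 <- simulate_households(cfg)
  s2 <- simulate_households(cfg)
  expect_identical(s1$records, s2$records)
  expect_equal(nrow(s1$rejects), 0)
  expect_equal(nrow(s1$records), 500)
  ## a different seed gives different data
  s3 <- simulate_households(cfg, seed = 8)
  expect_false(identical(s1$records$income, s3$records$income))
})

test_that("generated records satisfy the accounting identities", {
  cfg <- scenario_config(n_households = 1000, seed = 3)
  r <- simulate_households(cfg)$records
  expect_true(all(r$expenditure_food <= r$expenditure_total))
  expect_true(all(r$expenditure_total >=
                    rowSums(r[, oop_columns()])))
  expect_true(all(r$income > 0))
  ## configured mixes show up at the configured rates
  expect_equal(mean(r$patient_sex == "male"), 0.74, tolerance = 0.05)
  expect_equal(mean(r$patient_diagnosis == "schizophrenia"), 0.30,
               tolerance = 0.05)
})

test_that("zero OOP scale gives zero incidence at every threshold", {
  cfg <- scenario_config(n_households = 400, seed = 5, oop_scale = 0)
  survey <- annualize(simulate_households(cfg))
  tab <- sensitivity_analysis(survey)
  expect_true(all(tab$incidence_pct == 0))
})

test_that("food share declines in income as the Engel curve dictates", {
  ## the Engel curve governs the share of consumption (total net of
  ## health OOP, which has its own income-independent process)
  cfg <- scenario_config(n_households = 3000, seed = 11)
  r <- simulate_households(cfg)$records
  consumption <- r$expenditure_total - oop_total(r)
  rho <- cor(r$income, r$expenditure_food / consumption,
             method = "spearman")
  expect_lt(rho, -0.2)
  ## a steeper configured elasticity steepens the empirical gradient
  cfg2 <- scenario_config(n_households = 3000, seed = 11,
                          engel = list(baseline = 0.42,
                                       elasticity = 0.20,
                                       noise_sd = 0.08))
  r2 <- simulate_households(cfg2)$records
  rho2 <- cor(r2$income, r2$expenditure_food /
                (r2$expenditure_total - oop_total(r2)),
              method = "spearman")
  expect_lt(rho2, rho)
})

test_that("calibration reaches a mid-range target and honors tol = Inf-like cases", {
  cfg <- scenario_config(seed = 21)
  cal <- calibrate_to_incidence(cfg, target = 0.30, tol = 0.02, n = 4000)
  expect_lte(abs(cal$calibration$achieved - 0.30), 0.02)
  ## a huge tolerance returns the input config after one evaluation
  same <- calibrate_to_incidence(cfg, target = 0.30, tol = 0.99,
                                 n = 1000)
  expect_equal(same$oop_scale, cfg$oop_scale)
  expect_equal(same$calibration$iterations, 0)
  ## target zero is reachable at the knob floor
  zero <- calibrate_to_incidence(cfg, target = 0, tol = 0.001, n = 1000)
  expect_equal(zero$calibration$achieved, 0)
  ## an unreachable bracket errors with diagnostics
  expect_error(
    calibrate_to_incidence(cfg, target = 0.9, tol = 0.001, n = 500,
                           scale_range = c(0, 1e-6)),
    "not bracketed")
})

test_that("ground truth signs match the configured effect directions", {
  cfg <- scenario_config(seed = 13)
  cfg <- calibrate_to_incidence(cfg, 0.348, tol = 0.01, n = 8000)
  gt <- ground_truth(cfg, n = 2e4, seed = 50)
  expect_lt(gt[["income"]], 0)           # more income, lower CHE risk
  expect_gt(gt[["household_size"]], 0)   # larger household, higher risk
  expect_gt(gt[["patient_male"]], 0)
  expect_lt(gt[["patient_employed"]], 0)
  expect_gt(gt[["missed_work_days"]], 0)
})

test_that("a covariate outside the expenditure model has zero effect", {
  cfg <- scenario_config(seed = 17)
  gt <- ground_truth(cfg, effects = "caregiver_education_years",
                     n = 5000, seed = 51)
  expect_identical(unname(gt[1]), 0)
})

test_that("Monte-Carlo ground truth is self-consistent across seeds", {
  cfg <- scenario_config(seed = 19)
  cfg <- calibrate_to_incidence(cfg, 0.348, tol = 0.01, n = 8000)
  g1 <- ground_truth(cfg, effects = "patient_male", n = 3e4, seed = 60)
  g2 <- ground_truth(cfg, effects = "patient_male", n = 3e4, seed = 61)
  se <- sqrt(attr(g1, "mc_se")^2 + attr(g2, "mc_se")^2)
  expect_lt(abs(g1[1] - g2[1]), 3 * se[1])
})

test_that("scenario configs round-trip through YAML", {
  cfg <- scenario_config(n_households = 123, seed = 9,
                         target_incidence = 0.35)
  path <- tempfile(fileext = ".yaml")
  write_scenario(cfg, path)
  back <- read_scenario(path)
  expect_equal(back$n_households, 123L)
  expect_equal(back$target_incidence, 0.35)
  expect_equal(back$oop_model, cfg$oop_model, tolerance = 1e-12)
  ## equivalent simulations from the round-tripped config
  expect_equal(simulate_households(cfg, n = 50)$records,
               simulate_households(back, n = 50)$records,
               tolerance = 1e-9)
})

test_that("the bundled study-scale scenario loads and simulates", {
  cfg <- study_scale_scenario()
  expect_equal(cfg$n_households, 387L)
  expect_equal(cfg$target_incidence, 0.348)
  s <- simulate_households(cfg)
  expect_equal(nrow(s$records), 387)
})
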