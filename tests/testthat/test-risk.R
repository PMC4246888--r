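test_that("ecdf diabetes map honors its boundary and symmetry contracts", {
  map <- build_diabetes_map(sim_config())
  expect_equal(evaluate_diabetes_risk(map, 20), 0)
  expect_equal(evaluate_diabetes_risk(map, 37.5), 0.5)
  expect_lte(evaluate_diabetes_risk(map, 55), 1)
  expect_equal(evaluate_diabetes_risk(map, 55), 1)
  # clamping below/above the reference range
  expect_equal(evaluate_diabetes_risk(map, 10),
               evaluate_diabetes_risk(map, 20))
  expect_equal(evaluate_diabetes_risk(map, 80),
               evaluate_diabetes_risk(map, 55))
})

test_that("ecdf map equals a count-based empirical CDF oracle", {
  cfg <- sim_config()
  map <- build_diabetes_map(cfg, n_grid = 501L)
  grid <- seq(20, 55, length.out = 501)
  ref <- cfg$diabetes_scale * (grid - mean(grid)) / sd(grid)
  bmis <- c(20, 23.7, 31.4, 37.5, 44.9, 52.2, 55)
  x <- cfg$diabetes_scale * (bmis - mean(grid)) / sd(grid)
  expect_equal(evaluate_diabetes_risk(map, bmis), naive_ecdf(ref, x))
})

test_that("both strategies are monotone on a dense grid and stay in [0, 1]", {
  for (strategy in c("ecdf", "anchored_spline")) {
    cfg <- sim_config(diabetes_map_strategy = strategy)
    map <- build_diabetes_map(cfg)
    bmi <- seq(10, 80, length.out = 2000)
    p <- evaluate_diabetes_risk(map, bmi)
    expect_true(all(diff(p) >= 0), info = strategy)
    expect_true(all(p >= 0 & p <= 1), info = strategy)
    # monotone after calibration too
    cal <- calibrate_diabetes_map(map, seq(35, 50, by = 0.1), 0.28)
    pc <- evaluate_diabetes_risk(cal, bmi)
    expect_true(all(diff(pc) >= 0), info = strategy)
    expect_true(all(pc >= 0 & pc <= 1), info = strategy)
  }
})

test_that("anchored spline interpolates its anchors", {
  anchors <- cbind(c(18, 25, 32, 42), c(0.1, 0.25, 0.5, 0.7))
  cfg <- sim_config(diabetes_map_strategy = "anchored_spline",
                    diabetes_anchors = anchors)
  map <- build_diabetes_map(cfg)
  expect_equal(evaluate_diabetes_risk(map, anchors[, 1]), anchors[, 2])
})

test_that("evaluation agrees with a dense tabulation lookup", {
  map <- calibrate_diabetes_map(build_diabetes_map(sim_config()),
                                seq(35, 55, by = 0.05), 0.28)
  grid <- seq(20, 55, length.out = 100000)
  tab <- evaluate_diabetes_risk(map, grid)
  probe <- seq(20, 55, length.out = 997)
  looked_up <- tab[findInterval(probe, grid)]
  direct <- evaluate_diabetes_risk(map, probe)
  # lookup at the grid point just below each probe can differ by at most
  # the largest local increment of the tabulated map
  expect_lte(max(abs(direct - looked_up)), max(abs(diff(tab))) + 1e-12)
  exact <- evaluate_diabetes_risk(map, grid[c(1, 50000, 100000)])
  expect_equal(exact, tab[c(1, 50000, 100000)], tolerance = 1e-12)
})

test_that("calibration hits its target, is idempotent, and fixes nothing it need not", {
  cfg <- sim_config()
  map <- build_diabetes_map(cfg)
  bmis <- small_eligible(seed = 21)$bmi
  cal <- calibrate_diabetes_map(map, bmis, 0.28)
  expect_lt(abs(mean(evaluate_diabetes_risk(cal, bmis)) - 0.28), 1e-3)
  # idempotence
  cal2 <- calibrate_diabetes_map(cal, bmis, 0.28)
  expect_lt(abs(cal2$offset - cal$offset), 1e-6)
  # fixed point: targeting the uncalibrated mean leaves the map unchanged
  m0 <- mean(evaluate_diabetes_risk(map, bmis))
  fix <- calibrate_diabetes_map(map, bmis, m0)
  expect_lt(abs(fix$offset), 1e-6)
  # symmetric BMI set under the ecdf strategy already averages one half
  sym <- c(30, 45)  # equidistant from the 37.5 midpoint
  fix50 <- calibrate_diabetes_map(map, sym, 0.5)
  expect_lt(abs(fix50$offset), 0.01)  # identity up to one ECDF grid step
  expect_error(calibrate_diabetes_map(map, bmis, 0), "target_mean")
})

test_that("adverse-event model calibrates, is monotone in weight, degenerates correctly", {
  eligible <- small_eligible(seed = 22)
  cfg <- small_config()
  model <- build_ae_model(eligible, cfg)
  p <- adverse_event_probability(model, eligible)
  expect_lt(abs(mean(p) - cfg$ae_target_mean), 1e-3)
  expect_true(all(p >= 0 & p <= 1))
  # heavier of two otherwise-identical subjects carries strictly more risk
  two <- tibble::tibble(weight_kg = c(110, 150), is_male = c(FALSE, FALSE))
  p2 <- adverse_event_probability(model, two)
  expect_lt(p2[1], p2[2])
  # males above females at the same weight
  mf <- tibble::tibble(weight_kg = c(120, 120), is_male = c(TRUE, FALSE))
  pmf <- adverse_event_probability(model, mf)
  expect_gt(pmf[1], pmf[2])
  # all coefficients zero: constant at the calibration target
  flat <- build_ae_model(eligible, small_config(ae_weight_coef = 0,
                                                ae_male_coef = 0))
  pf <- adverse_event_probability(flat, eligible)
  expect_equal(unique(round(pf, 12)), round(cfg$ae_target_mean, 12))
})

test_that("risk profiles are bounded and treated risk never exceeds untreated when weight is lost", {
  eligible <- small_eligible(seed = 23)
  cfg <- small_config()
  outcomes <- simulate_outcomes(eligible, cfg, seed = 23)
  models <- build_risk_models(eligible, cfg)
  risks <- compute_risk_profiles(eligible, outcomes, models)
  expect_true(all(as.matrix(risks[, -1]) >= 0 &
                    as.matrix(risks[, -1]) <= 1))
  gained <- outcomes$pewl > 0
  expect_true(all(risks$p_t2dm_treated[gained] <=
                    risks$p_t2dm_untreated[gained]))
})
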