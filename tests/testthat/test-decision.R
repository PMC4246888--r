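test_that("population case probability matches hand evaluation of the printed formula", {
  df <- toy_frame(pred = c(90, 85, 60, 50),
                  p_t = c(0.1, 0.2, 0.45, 0.65),
                  p_u = c(0.3, 0.4, 0.5, 0.7))
  # treated group means (0.1 + 0.2)/2, untreated (0.5 + 0.7)/2, averaged
  expect_equal(population_case_probability(df, 70, "t2dm"), 0.375)
  # weighted variant is the size-weighted population mean
  expect_equal(population_case_probability(df, 70, "t2dm", weighted = TRUE),
               (0.1 + 0.2 + 0.5 + 0.7) / 4)
  # a constant field is returned unchanged for any threshold
  const <- toy_frame(pred = c(90, 60), p_t = c(0.3, 0.3), p_u = c(0.3, 0.3))
  for (tau in c(50, 70, 95)) {
    expect_equal(population_case_probability(const, tau, "t2dm"), 0.3)
  }
  # threshold above every prediction: the mean untreated probability
  expect_equal(population_case_probability(df, 95, "t2dm"),
               mean(c(0.3, 0.4, 0.5, 0.7)))
  # threshold below every prediction: the mean treated probability
  expect_equal(population_case_probability(df, 10, "t2dm"),
               mean(c(0.1, 0.2, 0.45, 0.65)))
  expect_error(population_case_probability(df[0, ], 70), "eligible")
})

test_that("predictions exactly at the threshold count as untreated", {
  df <- toy_frame(pred = c(80, 70, 60), p_t = c(0.1, 0.2, 0.3),
                  p_u = c(0.5, 0.6, 0.7))
  expect_equal(population_case_probability(df, 70, "t2dm"),
               (0.1 + mean(c(0.6, 0.7))) / 2)
  expect_equal(allocate_surgeries(df, 70, 10), 1)
})

test_that("case probability agrees with an independent naive transcription on random cohorts", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    pred <- runif(n, 40, 95)
    p_t <- runif(n)
    p_u <- runif(n)
    df <- toy_frame(pred, p_t, p_u)
    tau <- runif(1, 35, 100)
    expect_equal(population_case_probability(df, tau, "t2dm"),
                 naive_case_probability(pred, p_t, p_u, tau))
  }
})

test_that("surgical allocation ranks, caps and tie-breaks deterministically", {
  df <- toy_frame(pred = c(70, 90, 60, 85, 95), p_t = rep(0.1, 5),
                  p_u = rep(0.2, 5))
  expect_equal(allocate_surgeries(df, 0, 3), c(5, 2, 4))
  expect_length(allocate_surgeries(df, 100, 3), 0)
  ties <- toy_frame(pred = c(80, 80, 70), p_t = rep(0.1, 3),
                    p_u = rep(0.2, 3))
  expect_equal(allocate_surgeries(ties, 75, 1), 1)  # lower id wins the tie
})

test_that("allocation is the mean-prediction-optimal subset (brute force, n <= 12)", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    k <- sample(1:(n - 1), 1)
    df <- toy_frame(pred = round(runif(n, 50, 95), 1), p_t = runif(n),
                    p_u = runif(n))
    chosen <- allocate_surgeries(df, 0, k)
    best <- max(combn(n, k, function(idx) mean(df$predicted_pewl[idx])))
    expect_equal(mean(df$predicted_pewl[df$subject_id %in% chosen]), best)
  }
})

test_that("cases prevented matches hand evaluation under both comparators", {
  df <- toy_frame(pred = c(90, 85, 60, 50),
                  p_t = c(0.1, 0.2, 0.45, 0.65),
                  p_u = c(0.3, 0.4, 0.5, 0.7))
  # treated set at tau = 70, cap 2: subjects 1 and 2
  expect_equal(cases_prevented(df, 70, 2, "t2dm", "untreated_baseline"),
               2 * (mean(c(0.3, 0.4, 0.5, 0.7)) - mean(c(0.1, 0.2))))
  expect_equal(cases_prevented(df, 70, 2, "t2dm", "random_allocation"),
               2 * (mean(c(0.1, 0.2, 0.45, 0.65)) - mean(c(0.1, 0.2))))
  # identical risks: selection confers nothing over random allocation
  same <- toy_frame(pred = c(90, 80, 70), p_t = rep(0.2, 3),
                    p_u = rep(0.5, 3))
  expect_equal(cases_prevented(same, 75, 2, "t2dm", "random_allocation"), 0)
  expect_equal(cases_prevented(same, 75, 2, "t2dm", "untreated_baseline"),
               2 * (0.5 - 0.2))
  expect_error(cases_prevented(df, 99, 2, "t2dm"), "threshold")
})

test_that("threshold sweep covers the grid and equals per-threshold recomputation", {
  cfg <- small_config()
  eligible <- small_eligible(seed = 33)
  outcomes <- simulate_outcomes(eligible, cfg, seed = 33)
  risks <- compute_risk_profiles(eligible, outcomes,
                                 build_risk_models(eligible, cfg))
  df <- decision_frame(outcomes, risks)
  sweep <- threshold_sweep(df, cfg)
  expect_equal(nrow(sweep), 26)
  expect_equal(sweep$tau, 55:80)
  expect_equal(sweep$n_treated + sweep$n_untreated, rep(nrow(df), 26))
  expect_true(all(diff(sweep$n_treated) <= 0))
  # spot-check three thresholds against direct evaluation
  for (tau in c(55, 67, 80)) {
    row <- sweep[sweep$tau == tau, ]
    expect_equal(row$p_case_t2dm,
                 population_case_probability(df, tau, "t2dm"))
    expect_equal(row$n_prevented_t2dm_random_allocation,
                 cases_prevented(df, tau, cfg$n_surgeries, "t2dm",
                                 "random_allocation"))
    expect_equal(row$n_prevented_ae_untreated_baseline,
                 cases_prevented(df, tau, cfg$n_surgeries, "ae",
                                 "untreated_baseline"))
  }
  # collapsed grid gives a single row
  one <- threshold_sweep(df, small_config(tau_min = 70, tau_max = 70))
  expect_equal(nrow(one), 1)
  # a threshold above every prediction is recorded as missing, not fatal
  high <- threshold_sweep(df, small_config(tau_min = 150, tau_max = 151))
  expect_true(all(is.na(high$n_prevented_t2dm_random_allocation)))
})

test_that("null predictor confers no expected selection benefit", {
  cfg <- small_config(predictor_pewl_corr = 0, n_population = 50000)
  vals <- vapply(1:6, function(s) {
    eligible <- filter_eligible(
      simulate_population(sim_config(n_population = 50000, rng_seed = s)))
    outcomes <- simulate_outcomes(eligible, cfg, seed = s)
    risks <- compute_risk_profiles(eligible, outcomes,
                                   build_risk_models(eligible, cfg))
    df <- decision_frame(outcomes, risks)
    cases_prevented(df, 63, cfg$n_surgeries, "t2dm", "random_allocation")
  }, numeric(1))
  # per-seed values are noisy; the mean over seeds should sit near zero,
  # far below the benefit a real predictor delivers (tens of cases)
  expect_lt(abs(mean(vals)), 5)
})

test_that("conditional risk curves track binned means and degenerate correctly", {
  cfg <- sim_config(rng_seed = 51)
  eligible <- filter_eligible(simulate_population(cfg))
  outcomes <- simulate_outcomes(eligible, cfg, seed = 51)
  risks <- compute_risk_profiles(eligible, outcomes,
                                 build_risk_models(eligible, cfg))
  df <- decision_frame(outcomes, risks)
  # decile-binned conditional means as the independent oracle
  dec <- dplyr::mutate(df, bin = dplyr::ntile(.data$predicted_pewl, 10))
  binned <- dplyr::summarise(dplyr::group_by(dec, .data$bin),
                             mid = mean(.data$predicted_pewl),
                             m_t = mean(.data$p_t2dm_treated),
                             m_u = mean(.data$p_t2dm_untreated))
  curves <- conditional_risk_curves(df, grid = binned$mid)
  expect_lt(max(abs(curves$p_t2dm_treated - binned$m_t)), 0.03)
  expect_lt(max(abs(curves$p_t2dm_untreated - binned$m_u)), 0.03)
  # treated risk falls with the prediction under the default negative
  # weight association (better responders end at lower post-surgery BMI)
  expect_lt(utils::tail(curves$p_t2dm_treated, 1),
            curves$p_t2dm_treated[1])
  expect_lt(coef(lm(m_t ~ mid, data = binned))[2], 0)
  # constant risks produce constant curves
  const <- toy_frame(pred = seq(50, 90, length.out = 20),
                     p_t = rep(0.2, 20), p_u = rep(0.4, 20))
  cc <- conditional_risk_curves(const)
  expect_equal(unique(cc$p_t2dm_treated), 0.2)
  expect_equal(unique(cc$p_t2dm_untreated), 0.4)
  # no extrapolation outside the observed range, and a minimum cohort size
  expect_error(conditional_risk_curves(df, grid = c(0, 200)), "range")
  expect_error(conditional_risk_curves(const[1:5, ]), "at least 10")
})
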