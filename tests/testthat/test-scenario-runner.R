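# Scenario engine: counterfactual allocation construction, common random
# numbers, the exchangeability null, and the sensitivity analysis.

test_that("scenario construction reproduces the published counterfactual rows", {
  p <- default_parameter_fixture()
  sq <- p$allocation
  wm <- c(0.312, 0.235, 0.291, 0.162)

  # D: every group receives the status-quo white-male row exactly
  d <- build_scenario_allocation("D", sq)
  for (k in rownames(d)) expect_equal(unname(d[k, ]), wm)

  # C: white rows unchanged, Black rows copied from white gender-wise
  cc <- build_scenario_allocation("C", sq)
  expect_identical(cc["white_male", ], sq["white_male", ])
  expect_identical(cc["white_female", ], sq["white_female", ])
  expect_equal(unname(cc["Black_male", ]), wm)
  expect_equal(unname(cc["Black_female", ]), c(0.055, 0.409, 0.252, 0.283))

  # A and B: mixture marginalisation matches the published reference rows
  # within printed rounding
  ref <- reference_scenario_allocations()
  a <- build_scenario_allocation("A", sq, p$composition)
  expect_true(all(abs(a - ref$A) <= 0.005))
  b <- build_scenario_allocation("B", sq, p$composition)
  expect_true(all(abs(b - ref$B) <= 0.005))

  # status quo is the identity
  expect_equal(build_scenario_allocation("status_quo", sq), sq)
})

test_that("scenario construction is idempotent and validates inputs", {
  p <- default_parameter_fixture()
  d <- build_scenario_allocation("D", p$allocation)
  expect_identical(build_scenario_allocation("D", d), d)
  expect_error(build_scenario_allocation("A", p$allocation),
               "composition")
  expect_error(build_scenario_allocation("B", p$allocation,
                                         list(white_share_men = 0.8,
                                              white_share_women = 0.8)),
               "composition")
})

test_that("constructed rows are exact simplexes when built from exact rows", {
  p <- default_parameter_fixture()
  sq <- p$allocation / rowSums(p$allocation)   # strip printed rounding
  for (nm in scenario_names()) {
    tab <- build_scenario_allocation(nm, sq, p$composition)
    expect_true(all(abs(rowSums(tab) - 1) <= 1e-9))
  }
  # shipped printed rows stay within printed rounding
  expect_true(all(abs(rowSums(p$allocation) - 1) <= 0.005))
})

test_that("common random numbers make scenario C white-invariant bit-for-bit", {
  p <- default_parameter_fixture()
  ex <- run_experiment(tiny_config(), p)
  mp <- ex$mean_prevalence
  w_sq <- mp[mp$scenario == "status_quo" & mp$race == "white", ]
  w_c <- mp[mp$scenario == "C" & mp$race == "white", ]
  expect_identical(w_sq$mean_prevalence, w_c$mean_prevalence)
  # Black trajectories do differ
  b_sq <- mp[mp$scenario == "status_quo" & mp$race == "Black", ]
  b_c <- mp[mp$scenario == "C" & mp$race == "Black", ]
  expect_false(identical(b_sq$mean_prevalence, b_c$mean_prevalence))
})

test_that("paired scenario contrasts have lower variance than unpaired ones", {
  p <- default_parameter_fixture()
  cfg1 <- experiment_config(n_cohorts = 10, cohort_size = 2000, seed = 21,
                            scenarios = c("status_quo", "D"),
                            races = "Black")
  ex1 <- run_experiment(cfg1, p)
  per <- aggregate(prevalence ~ scenario + cohort, data = ex1$prevalence,
                   FUN = mean)
  sq <- per$prevalence[per$scenario == "status_quo"]
  d_paired <- per$prevalence[per$scenario == "D"]
  # an independent replication of scenario D on a different master seed
  cfg2 <- experiment_config(n_cohorts = 10, cohort_size = 2000, seed = 22,
                            scenarios = "D", races = "Black")
  ex2 <- run_experiment(cfg2, p)
  per2 <- aggregate(prevalence ~ cohort, data = ex2$prevalence, FUN = mean)
  expect_lt(var(sq - d_paired), var(sq - per2$prevalence))
})

test_that("an exchangeable population shows no racial gap under scenario B", {
  null_params <- randomized_parameter_fixture(
    fixture_options(seed = 40, gradient_strength = 0, race_effect = 0))
  cfg <- experiment_config(n_cohorts = 6, cohort_size = 4000, seed = 31,
                           scenarios = "B")
  ex <- run_experiment(cfg, null_params)
  per <- aggregate(prevalence ~ race + cohort, data = ex$prevalence,
                   FUN = mean)
  b <- per$prevalence[per$race == "Black"]
  w <- per$prevalence[per$race == "white"]
  gap <- mean(b) - mean(w)
  se <- sqrt(var(b) / length(b) + var(w) / length(w))
  expect_lt(abs(gap), 3 * se)
})

test_that("a single-cohort experiment degenerates to that cohort", {
  p <- default_parameter_fixture()
  cfg <- experiment_config(n_cohorts = 1, cohort_size = 800, seed = 5,
                           scenarios = "status_quo", races = "white")
  ex <- run_experiment(cfg, p)
  expect_equal(ex$mean_prevalence$mean_prevalence,
               ex$prevalence$prevalence[order(ex$prevalence$cycle)])
  ca <- career_averages(ex)
  expect_equal(ca$career_prevalence, mean(ex$prevalence$prevalence))
  expect_true(is.na(ca$sd_cohorts) || ca$sd_cohorts == 0)
})

test_that("sensitivity intervals bracket the base case with the right signs", {
  p <- default_parameter_fixture()
  cfg <- experiment_config(n_cohorts = 2, cohort_size = 1500, seed = 61,
                           scenarios = "status_quo")
  sens <- run_sensitivity(cfg, p, factor = 0.25)
  expect_true(all(sens$low <= sens$base + 1e-12))
  expect_true(all(sens$high >= sens$base - 1e-12))
  expect_setequal(unique(sens$block),
                  c("prescription", "control_by_adherence"))
  # weaker blood-pressure control (-25%) cannot lower prevalence
  ctl <- sens[sens$block == "control_by_adherence", ]
  expect_true(all(ctl$minus >= ctl$base - 1e-12))
})

test_that("a zero-factor sensitivity run collapses to the base value", {
  p <- default_parameter_fixture()
  cfg <- experiment_config(n_cohorts = 1, cohort_size = 600, seed = 71,
                           scenarios = "status_quo", races = "Black")
  sens <- run_sensitivity(cfg, p, factor = 0)
  expect_equal(sens$low, sens$base)
  expect_equal(sens$high, sens$base)
  expect_equal(sens$minus, sens$plus)
})
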