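# Transition engine: risk-equation evaluation, per-step dynamics, cycle
# bookkeeping, and the homogeneous-cohort Markov oracle.

test_that("risk-equation evaluation reproduces hand computations", {
  p <- default_parameter_fixture()
  eq1 <- p$risk_equations$hypertension_5yr

  # intercept-only: every covariate zero (unemployed, BMI 1, age 0)
  w0 <- make_worker(bmi = 1, age = 0L, employment = "unemployed")
  expect_equal(eval_risk_equation(eq1, w0), plogis(-12.07), tolerance = 1e-12)

  # independent hand evaluation: prehypertensive woman aged 40, BMI 27,
  # family history, full-time, neutral work environment, non-smoker
  w <- make_worker(gender = "female", age = 40L, bmi = 27,
                   family_history = TRUE, state = "prehypertensive")
  hand_logit <- -12.07 + 2.497 * log(27) + 1.710 + 0.656 - 0.059 +
    0.024 * 40 + 0.197
  expect_equal(hand_logit, -0.3763, tolerance = 1e-4)
  expect_equal(eval_risk_equation(eq1, w), plogis(hand_logit),
               tolerance = 1e-9)
  expect_equal(eval_risk_equation(eq1, w), 0.407, tolerance = 1e-3)

  # a one-unit increase in job control shifts the logit by exactly -0.347
  w_hi <- make_worker(pwe_control = 1)
  w_lo <- make_worker(pwe_control = 0)
  d <- qlogis(eval_risk_equation(eq1, w_hi)) -
    qlogis(eval_risk_equation(eq1, w_lo))
  expect_equal(d, -0.347, tolerance = 1e-12)
})

test_that("unemployment zeroes the effective work covariates only", {
  p <- default_parameter_fixture()
  eq1 <- p$risk_equations$hypertension_5yr
  w_emp <- make_worker(pwe_demand = 2, pwe_control = -1, pwe_support = 1)
  w_un <- make_worker(pwe_demand = 2, pwe_control = -1, pwe_support = 1,
                      employment = "unemployed")
  # unemployed: profile stored but not exposed; work dummies both zero
  base <- make_worker(bmi = w_un$bmi, employment = "unemployed")
  expect_equal(eval_risk_equation(eq1, w_un), eval_risk_equation(eq1, base))
  expect_false(eval_risk_equation(eq1, w_emp) ==
                 eval_risk_equation(eq1, w_un))
})

test_that("risk evaluation rejects dead workers and non-positive BMI", {
  p <- default_parameter_fixture()
  eq1 <- p$risk_equations$hypertension_5yr
  expect_error(eval_risk_equation(eq1, make_worker(state = "dead")), "dead")
  expect_error(eval_risk_equation(eq1, make_worker(bmi = 0)), "BMI")
  expect_error(annual_onset_probabilities(make_worker(state = "hypertensive"),
                                          p),
               "normotensive")
})

test_that("annual onset probabilities apply the constant-hazard conversion", {
  p <- default_parameter_fixture()
  w <- make_worker(gender = "female", age = 40L, bmi = 27,
                   family_history = TRUE)
  p5 <- eval_risk_equation(p$risk_equations$hypertension_5yr, w)
  ons <- annual_onset_probabilities(w, p)
  expect_equal(ons$p_hyper, 1 - (1 - p5)^(1 / 5), tolerance = 1e-12)

  # prehypertensive workers face a strictly higher hypertension risk than
  # an otherwise identical normotensive worker (the +1.710 coefficient)
  w_pre <- make_worker(state = "prehypertensive")
  w_nor <- make_worker(state = "normotensive")
  expect_gt(annual_onset_probabilities(w_pre, p)$p_hyper,
            annual_onset_probabilities(w_nor, p)$p_hyper)
  expect_equal(annual_onset_probabilities(w_pre, p)$p_prehyp, 0)

  # controlled workers are treated like their normotensive twins
  w_ctl <- make_worker(state = "controlled")
  expect_equal(annual_onset_probabilities(w_ctl, p)$p_hyper,
               annual_onset_probabilities(w_nor, p)$p_hyper)
  expect_equal(annual_onset_probabilities(w_ctl, p)$p_prehyp,
               annual_onset_probabilities(w_nor, p)$p_prehyp)
})

test_that("behavior dynamics follow point-mass and frozen parameterisations", {
  toy <- toy_parameter_fixture()
  w <- make_worker(bmi = 30, smoking = "never", active = FALSE)
  expect_identical(step_behaviors(w, toy)[names(w)], w)

  p1 <- toy
  p1$behavior$smoking$never_to_current <- rep(1, 3)
  expect_identical(step_behaviors(w, p1)$smoking, "current")

  # deterministic drift: inactive, +0.25, zero noise
  p2 <- toy
  p2$behavior$bmi_drift$inactive <- 0.25
  expect_equal(step_behaviors(w, p2)$bmi, 30.25, tolerance = 1e-12)

  # BMI floor prevents log-domain errors
  p3 <- toy
  p3$behavior$bmi_drift$inactive <- -40
  expect_equal(step_behaviors(w, p3)$bmi, 12)
})

test_that("employment dynamics freeze, scar, and stratify by class", {
  toy <- toy_parameter_fixture()
  w <- make_worker()
  expect_identical(step_employment(w, toy), w)

  # long-run unemployment shares follow the class gradient
  p <- default_parameter_fixture()
  mk <- function(cls) {
    w <- make_worker()
    w <- w[rep(1, 4000), ]
    w$occupation <- cls
    w$gender <- "female"
    rownames(w) <- NULL
    w
  }
  set.seed(33)
  top <- mk("health_diagnosing")
  bottom <- mk("aide")
  top_u <- bottom_u <- 0
  for (i in 1:25) {
    top <- step_employment(top, p)
    bottom <- step_employment(bottom, p)
    top_u <- top_u + mean(top$employment == "unemployed")
    bottom_u <- bottom_u + mean(bottom$employment == "unemployed")
  }
  expect_gt(bottom_u, top_u)
  # unemployment history is permanent
  expect_true(all(top$ever_unemployed[top$employment == "unemployed"]))
})

test_that("medication and control dynamics honour the treatment rules", {
  # no prescription -> hypertensive forever, never controlled
  toy0 <- toy_parameter_fixture(bp_state = c(0, 0, 1), prescription = 0,
                                control = 1)
  counts <- run_cohort(300, "white", toy0, seed = 2, n_cycles = 15)
  expect_true(all(counts$hypertensive == 300))
  expect_true(all(counts$controlled == 0))

  # certain prescription and control: controlled after one cycle
  toy1 <- toy_parameter_fixture(bp_state = c(0, 0, 1), prescription = 1,
                                control = 1)
  counts1 <- run_cohort(300, "white", toy1, seed = 2, n_cycles = 3)
  expect_equal(counts1$controlled[counts1$cycle >= 1], rep(300, 3))

  # a medicated worker needs no new prescription draw: control fires even
  # with prescription probability zero
  p <- toy_parameter_fixture(prescription = 0, control = 1)
  w <- make_worker(state = "hypertensive", on_medication = TRUE,
                   adherence = "high")
  out <- step_medication_and_control(w, p)
  expect_identical(out$state, "controlled")
  expect_true(out$on_medication)
  expect_identical(out$adherence, "high")

  expect_error(step_medication_and_control(make_worker(), p), "hypertensive")
})

test_that("adherence is drawn once at initiation and retained", {
  p <- toy_parameter_fixture(prescription = 1, control = 0)
  p$transitions$adherence_init <- c(high = 1, medium = 0, low = 0)
  w <- make_worker(state = "hypertensive")
  w <- w[rep(1, 50), ]; rownames(w) <- NULL
  set.seed(6)
  out <- step_medication_and_control(w, p)
  expect_true(all(out$on_medication))
  expect_true(all(out$adherence == "high"))
  # a second pass never redraws adherence
  p$transitions$adherence_init <- c(high = 0, medium = 0, low = 1)
  out2 <- step_medication_and_control(out, p)
  expect_true(all(out2$adherence == "high"))
})

test_that("mortality risk is ordered by hypertension, gender and parameters", {
  p <- default_parameter_fixture()
  n <- 20000
  mkn <- function(...) {
    w <- make_worker(...)
    w <- w[rep(1, n), ]; w$id <- seq_len(n); rownames(w) <- NULL
    w
  }
  # shared uniforms: the higher-risk twin's death set contains the other's
  p_hr <- p
  p_hr$mortality$cvd$white_male <- rep(0.05, 4)
  set.seed(12); d_norm <- step_mortality(mkn(age = 50L), p_hr)$state == "dead"
  set.seed(12); d_hyp <- step_mortality(mkn(age = 50L, state = "hypertensive"),
                                        p_hr)$state == "dead"
  expect_true(all(d_hyp[d_norm]))
  expect_gt(sum(d_hyp), sum(d_norm))

  # pregnancy-related risk applies to women only
  p_pr <- p
  p_pr$mortality$pregnancy$white <- rep(0.03, 4)
  set.seed(13); d_m <- step_mortality(mkn(age = 30L), p_pr)$state == "dead"
  set.seed(13); d_f <- step_mortality(mkn(age = 30L, gender = "female"),
                                      p_pr)$state == "dead"
  expect_gt(sum(d_f), sum(d_m))
})

test_that("trajectories conserve workers and never take forbidden transitions", {
  p <- default_parameter_fixture()
  set.seed(501)
  cohort <- init_cohort(2500, "Black", p)
  n <- nrow(cohort)
  occupation0 <- cohort$occupation
  dead_prev <- 0
  for (cyc in 1:40) {
    before <- cohort$state
    med_before <- cohort$on_medication
    step <- advance_cycle(cohort, p, cycle = cyc)
    cohort <- step$cohort
    cnt <- step$counts
    # conservation and absorbing death
    expect_identical(cnt$alive + cnt$dead, n)
    expect_gte(cnt$dead, dead_prev)
    dead_prev <- cnt$dead
    after <- cohort$state
    expect_true(all(after[before == "dead"] == "dead"))
    # forbidden: prehypertensive -> normotensive
    expect_false(any(before == "prehypertensive" & after == "normotensive"))
    # forbidden: hypertensive -> normotensive or prehypertensive
    expect_false(any(before == "hypertensive" &
                       after %in% c("normotensive", "prehypertensive")))
    # hypertensive -> controlled only with medication
    h2c <- before == "hypertensive" & after == "controlled"
    expect_true(all(cohort$on_medication[h2c]))
    # medication invariants (among the living; the dead keep their record)
    expect_true(all((cohort$adherence != "none") == cohort$on_medication))
    live_med <- cohort$on_medication & cohort$state != "dead"
    expect_true(all(cohort$state[live_med] %in%
                      c("hypertensive", "controlled")))
    # occupational class is immutable
    expect_identical(cohort$occupation, occupation0)
  }
})

test_that("cohort runs are bit-reproducible from the seed", {
  p <- default_parameter_fixture()
  a <- run_cohort(1500, "white", p, seed = 321, n_cycles = 10)
  b <- run_cohort(1500, "white", p, seed = 321, n_cycles = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("homogeneous-cohort runs match the matrix-power Markov oracle", {
  toys <- list(
    list(crude = c(normo_to_prehyp = 0.06, normo_to_hyper = 0.01,
                   prehyp_to_hyper = 0.05),
         pc = 0.04, rx = 1, q = 0.30, d = 0, bp = c(0.7, 0.2, 0.1)),
    list(crude = c(normo_to_prehyp = 0.05, normo_to_hyper = 0.015,
                   prehyp_to_hyper = 0.06),
         pc = 0.03, rx = 1, q = 0.25, d = 0.01, bp = c(0.6, 0.3, 0.1)),
    list(crude = c(normo_to_prehyp = 0.10, normo_to_hyper = 0.02,
                   prehyp_to_hyper = 0.08),
         pc = 0, rx = 0, q = 0, d = 0, bp = c(0.8, 0.15, 0.05)))
  n <- 4000
  for (i in seq_along(toys)) {
    tt <- toys[[i]]
    params <- toy_parameter_fixture(
      crude = tt$crude, prehyp_to_controlled = tt$pc,
      prescription = tt$rx, control = tt$q, flat_mortality = tt$d,
      bp_state = tt$bp,
      flags = fixture_options(zero_mortality = tt$d == 0,
                              frozen_behaviors = TRUE,
                              frozen_employment = TRUE))
    M <- markov_oracle_matrix(tt$crude[["normo_to_prehyp"]],
                              tt$crude[["normo_to_hyper"]],
                              tt$crude[["prehyp_to_hyper"]],
                              tt$pc, tt$rx, tt$q, tt$d)
    counts <- run_cohort(n, "white", params, seed = 1000 + i)
    for (cyc in c(10L, 40L)) {
      expected <- markov_oracle_dist(M, tt$bp, cyc)
      row <- counts[counts$cycle == cyc, ]
      observed <- as.numeric(row[c("normotensive", "prehypertensive",
                                   "hypertensive", "controlled", "dead")]) / n
      tol <- 3 * sqrt(expected * (1 - expected) / n) + 1e-9
      expect_true(all(abs(observed - expected) <= tol),
                  label = sprintf("toy %d cycle %d within 3 binomial SEs",
                                  i, cyc))
    }
  }
})

test_that("incidence responds monotonically to the work-environment signs", {
  p <- default_parameter_fixture()
  career <- function(params, seed = 777) {
    mean(prevalence_by_cycle(run_cohort(4000, "white", params,
                                        seed = seed))$prevalence)
  }
  base <- career(p)
  shift <- function(dim, delta) {
    q <- p
    q$pwe[[dim]]$mean <- q$pwe[[dim]]$mean + delta
    q
  }
  # more control or support lowers incidence; more demand raises it
  expect_lte(career(shift("control", 1)), base)
  expect_lte(career(shift("support", 1)), base)
  expect_gte(career(shift("demand", 1)), base)
})

test_that("default-fixture prevalence is non-decreasing over the career", {
  p <- default_parameter_fixture()
  prev <- (prevalence_by_cycle(run_cohort(8000, "white", p, seed = 2024))$prevalence +
             prevalence_by_cycle(run_cohort(8000, "Black", p, seed = 2025))$prevalence) / 2
  expect_true(all(diff(prev) > -0.004))
  expect_gt(prev[40], prev[1])
})
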