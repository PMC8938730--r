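# Transition engine: advances a cohort one annual cycle.  Within-cycle
# event order is fixed: mortality draw first, then (for survivors) behavior
# dynamics, employment dynamics, blood-pressure transitions; workers become
# one year older at the end of the cycle.  Health-state transitions are
# evaluated synchronously on the state at the start of the health step, so
# forbidden transitions (prehypertensive -> normotensive, hypertensive ->
# prehypertensive/normotensive, control without medication) are structurally
# impossible.

#' Evaluate a five-year blood-pressure risk equation for workers
#'
#' Computes `intercept + sum(coef * covariate)` and returns the inverse
#' logit.  Covariates are taken from the worker rows: `LogBMI = log(bmi)`;
#' `CurrentSmoker` is 1 only for current smokers (former smokers count as
#' 0); `CurrentlyPrehypertensive` is 1 for workers currently in the
#' prehypertensive state; `WorkFullTime`/`WorkPartTime` are one-hot and both
#' 0 when unemployed; the effective `JobDemand`/`JobControl`/`Support` are 0
#' during unemployed cycles (the stored profile is unchanged).
#'
#' @param eq A risk equation (`intercept` plus the eleven named
#'   coefficients).
#' @param workers Data frame of alive workers (see [init_cohort()]).
#' @return Vector of five-year probabilities.
#' @export
eval_risk_equation <- function(eq, workers) {
  if (any(workers$state == "dead")) {
    stop("risk equations are undefined for dead workers", call. = FALSE)
  }
  if (any(workers$bmi <= 0)) {
    stop("risk equations require a positive BMI", call. = FALSE)
  }
  employed <- workers$employment != "unemployed"
  X <- cbind(
    LogBMI = log(workers$bmi),
    CurrentSmoker = as.numeric(workers$smoking == "current"),
    CurrentlyPrehypertensive = as.numeric(workers$state == "prehypertensive"),
    FamilyHistory = as.numeric(workers$family_history),
    WorkFullTime = as.numeric(workers$employment == "full_time"),
    WorkPartTime = as.numeric(workers$employment == "part_time"),
    JobDemand = ifelse(employed, workers$pwe_demand, 0),
    JobControl = ifelse(employed, workers$pwe_control, 0),
    Support = ifelse(employed, workers$pwe_support, 0),
    Age = as.numeric(workers$age),
    Women = as.numeric(workers$gender == "female"))
  lp <- eq$intercept +
    drop(X[, names(eq$coefficients), drop = FALSE] %*% eq$coefficients)
  stats::plogis(lp)
}

#' Annual onset probabilities of prehypertension and hypertension
#'
#' For normotensive and controlled workers both risk equations are
#' evaluated (controlled workers are treated like normotensive workers, with
#' `CurrentlyPrehypertensive = 0`) and converted to annual probabilities by
#' [deale_5yr_to_annual()].  For prehypertensive workers only the
#' hypertension equation applies and the prehypertension probability is 0.
#' In crude-probability mode (`transitions$use_risk_equations = FALSE`) the
#' fixed annual transition probabilities are used instead.
#'
#' @param workers Data frame of alive workers in the normotensive,
#'   prehypertensive or controlled state.
#' @param params A `segsim_params` object.
#' @return Data frame with columns `p_prehyp` and `p_hyper`.
#' @export
annual_onset_probabilities <- function(workers, params) {
  st <- workers$state
  if (any(st %in% c("hypertensive", "dead"))) {
    stop("onset probabilities are defined only for normotensive, ",
         "prehypertensive and controlled workers", call. = FALSE)
  }
  tr <- params$transitions
  if (isTRUE(tr$use_risk_equations)) {
    p_hyper <- deale_5yr_to_annual(
      eval_risk_equation(params$risk_equations$hypertension_5yr, workers))
    p_prehyp <- numeric(nrow(workers))
    np <- st != "prehypertensive"
    if (any(np)) {
      p_prehyp[np] <- deale_5yr_to_annual(
        eval_risk_equation(params$risk_equations$prehypertension_5yr,
                           workers[np, , drop = FALSE]))
    }
  } else {
    isP <- st == "prehypertensive"
    p_hyper <- ifelse(isP, tr$crude[["prehyp_to_hyper"]],
                      tr$crude[["normo_to_hyper"]])
    p_prehyp <- ifelse(isP, 0, tr$crude[["normo_to_prehyp"]])
  }
  data.frame(p_prehyp = p_prehyp, p_hyper = p_hyper)
}

#' Advance behaviors one cycle
#'
#' Smoking moves along the age-banded transition table (never -> current,
#' current <-> former); physical activity toggles with the activity
#' transition probabilities; BMI is incremented by the activity-specific
#' drift plus Gaussian noise and floored to avoid log-domain errors.
#'
#' @param workers Data frame of alive workers.
#' @param params A `segsim_params` object.
#' @param u_smoke,u_activity,z_bmi Optional uniform/standard-normal draws
#'   (one per worker); supplied by [advance_cycle()] so that every worker
#'   keeps the same random stream across counterfactual scenarios (common
#'   random numbers).
#' @return The updated workers.
#' @export
step_behaviors <- function(workers, params,
                           u_smoke = stats::runif(nrow(workers)),
                           u_activity = stats::runif(nrow(workers)),
                           z_bmi = stats::rnorm(nrow(workers))) {
  if (any(workers$state == "dead")) {
    stop("step_behaviors called on dead workers", call. = FALSE)
  }
  b <- params$behavior
  band <- findInterval(workers$age, b$smoking$age_breaks)
  sm <- workers$smoking
  p_move <- ifelse(sm == "never", b$smoking$never_to_current[band],
                   ifelse(sm == "current", b$smoking$current_to_former[band],
                          b$smoking$former_to_current[band]))
  moved <- u_smoke < p_move
  workers$smoking[moved & sm == "never"] <- "current"
  workers$smoking[moved & sm == "current"] <- "former"
  workers$smoking[moved & sm == "former"] <- "current"

  act <- workers$active
  p_tog <- ifelse(act, b$activity[["active_to_inactive"]],
                  b$activity[["inactive_to_active"]])
  workers$active <- xor(act, u_activity < p_tog)

  drift <- ifelse(workers$active, b$bmi_drift$active, b$bmi_drift$inactive)
  workers$bmi <- pmax(workers$bmi + drift + b$bmi_drift$sd * z_bmi,
                      b$bmi_drift$floor)
  workers
}

#' Advance employment status one cycle
#'
#' Draws the next status from the three-outcome multinomial employment
#' model conditioned on age, gender, race, unemployment history and
#' occupational class; `ever_unemployed` is set permanently on first
#' unemployment.  When `params$employment$frozen` is `TRUE` the status is
#' left unchanged (toy mode).
#'
#' @param workers Data frame of alive workers.
#' @param params A `segsim_params` object.
#' @param u Optional uniform draws, one per worker (see [step_behaviors()]).
#' @return The updated workers.
#' @export
step_employment <- function(workers, params,
                            u = stats::runif(nrow(workers))) {
  if (any(workers$state == "dead")) {
    stop("step_employment called on dead workers", call. = FALSE)
  }
  if (isTRUE(params$employment$frozen)) return(workers)
  P <- employment_probabilities(workers$race, workers$gender,
                                workers$occupation, workers$age,
                                workers$ever_unemployed, params)
  emp <- SEG_EMPLOYMENT[sample_categorical(P, u)]
  workers$employment <- emp
  workers$ever_unemployed <- workers$ever_unemployed | emp == "unemployed"
  workers
}

#' Medication and blood-pressure control for hypertensive workers
#'
#' Unmedicated hypertensive workers face a race-specific prescription draw
#' every cycle; on first prescription the adherence level is drawn once
#' from the initiation distribution and retained.  Medicated workers move
#' to the controlled state with the adherence-level control probability;
#' unmedicated workers have zero probability of becoming controlled.  A
#' controlled worker who relapses to hypertension remains on medication and
#' faces no new prescription draw.
#'
#' @param workers Data frame of alive, hypertensive workers.
#' @param params A `segsim_params` object.
#' @param u_rx,u_adh,u_ctrl Optional uniform draws, one per worker (see
#'   [step_behaviors()]).
#' @return The updated workers.
#' @export
step_medication_and_control <- function(workers, params,
                                        u_rx = stats::runif(nrow(workers)),
                                        u_adh = stats::runif(nrow(workers)),
                                        u_ctrl = stats::runif(nrow(workers))) {
  if (any(workers$state != "hypertensive")) {
    stop("step_medication_and_control applies only to hypertensive workers",
         call. = FALSE)
  }
  n <- nrow(workers)
  tr <- params$transitions

  newly <- !workers$on_medication &
    u_rx < tr$prescription[workers$race]
  if (any(newly)) {
    adh_p <- matrix(tr$adherence_init[SEG_ADHERENCE], nrow = sum(newly),
                    ncol = 3, byrow = TRUE)
    workers$adherence[newly] <- SEG_ADHERENCE[
      sample_categorical(adh_p, u_adh[newly])]
    workers$on_medication[newly] <- TRUE
  }
  p_ctrl <- ifelse(workers$on_medication,
                   tr$control_by_adherence[
                     match(workers$adherence, SEG_ADHERENCE)], 0)
  p_ctrl[is.na(p_ctrl)] <- 0
  workers$state[u_ctrl < p_ctrl] <- "controlled"
  workers
}

#' Mortality draw
#'
#' Combines the CVD rate (multiplied by the gender-specific hazard ratio
#' for hypertensive workers), the non-CVD rate and, for women, the
#' pregnancy-related rate additively on the rate scale, converts to an
#' annual probability, and makes a single death draw.
#'
#' @param workers Data frame of alive workers.
#' @param params A `segsim_params` object.
#' @param u Optional uniform draws, one per worker (see [step_behaviors()]).
#' @return The updated workers (state `"dead"` where the draw fires).
#' @export
step_mortality <- function(workers, params,
                           u = stats::runif(nrow(workers))) {
  if (any(workers$state == "dead")) {
    stop("step_mortality called on dead workers", call. = FALSE)
  }
  m <- params$mortality
  n <- nrow(workers)
  band <- findInterval(workers$age, m$age_breaks)
  kidx <- match(rg_key(workers$race, workers$gender), SEG_RG_KEYS)
  cvd <- do.call(rbind, m$cvd[SEG_RG_KEYS])[cbind(kidx, band)]
  ncv <- do.call(rbind, m$non_cvd[SEG_RG_KEYS])[cbind(kidx, band)]
  hr <- ifelse(workers$state == "hypertensive",
               m$hr_cvd_hypertensive[workers$gender], 1)
  rate <- cvd * hr + ncv
  fem <- workers$gender == "female"
  if (any(fem)) {
    preg <- do.call(rbind, m$pregnancy[SEG_RACES])
    rate[fem] <- rate[fem] +
      preg[cbind(match(workers$race[fem], SEG_RACES), band[fem])]
  }
  workers$state[u < (1 - exp(-rate))] <- "dead"
  workers
}

# blood-pressure transitions, synchronous on the state at step start
step_health_state <- function(workers, params,
                              u_h1 = stats::runif(nrow(workers)),
                              u_h2 = stats::runif(nrow(workers)),
                              u_rx = stats::runif(nrow(workers)),
                              u_adh = stats::runif(nrow(workers)),
                              u_ctrl = stats::runif(nrow(workers))) {
  st <- workers$state
  nh <- which(st %in% c("normotensive", "controlled", "prehypertensive"))
  if (length(nh)) {
    ons <- annual_onset_probabilities(workers[nh, , drop = FALSE], params)
    u1 <- u_h1[nh]
    u2 <- u_h2[nh]
    isP <- st[nh] == "prehypertensive"
    to_h <- u1 < ons$p_hyper
    to_p <- !to_h & !isP & (u2 < ons$p_prehyp)
    to_c <- !to_h & isP &
      (u2 < params$transitions$prehyp_to_controlled)
    workers$state[nh[to_h]] <- "hypertensive"
    # a controlled worker slipping to prehypertension leaves the treated
    # track: medication and adherence are cleared
    idx_p <- nh[to_p]
    workers$on_medication[idx_p] <- FALSE
    workers$adherence[idx_p] <- "none"
    workers$state[idx_p] <- "prehypertensive"
    workers$state[nh[to_c]] <- "controlled"
  }
  hyp <- which(st == "hypertensive")
  if (length(hyp)) {
    workers[hyp, ] <- step_medication_and_control(
      workers[hyp, , drop = FALSE], params,
      u_rx = u_rx[hyp], u_adh = u_adh[hyp], u_ctrl = u_ctrl[hyp])
  }
  workers
}

# one-row state tally
state_counts <- function(cohort, cycle, age) {
  tab <- tabulate(match(cohort$state, SEG_STATES), nbins = length(SEG_STATES))
  out <- data.frame(cycle = cycle, age = age,
                    normotensive = tab[1], prehypertensive = tab[2],
                    hypertensive = tab[3], controlled = tab[4],
                    dead = tab[5])
  out$alive <- nrow(cohort) - out$dead
  out
}

#' Advance a cohort one annual cycle
#'
#' Applies, in order: the mortality draw; then for survivors the behavior
#' step, the employment step and the blood-pressure/treatment step; tallies
#' the post-transition state occupancy; and finally increments the age of
#' surviving workers (workers become one year older at the end of each
#' cycle).
#'
#' @param cohort Data frame of workers (see [init_cohort()]).
#' @param params A `segsim_params` object.
#' @param cycle Cycle index (1-based); the tallied age is `24 + cycle`.
#' @return A list with the updated `cohort` and a one-row `counts` data
#'   frame (per-state counts plus `alive`).
#' @export
advance_cycle <- function(cohort, params, cycle = 1L) {
  # one draw of every random vector for the full cohort, in a fixed order:
  # worker i consumes the same stream positions whatever happens to the
  # rest of the cohort, which keeps counterfactual scenarios paired under
  # common random numbers
  n <- nrow(cohort)
  u_mort <- stats::runif(n)
  u_smoke <- stats::runif(n)
  u_act <- stats::runif(n)
  z_bmi <- stats::rnorm(n)
  u_emp <- stats::runif(n)
  u_h1 <- stats::runif(n)
  u_h2 <- stats::runif(n)
  u_rx <- stats::runif(n)
  u_adh <- stats::runif(n)
  u_ctrl <- stats::runif(n)

  alive <- which(cohort$state != "dead")
  if (length(alive)) {
    sub <- step_mortality(cohort[alive, , drop = FALSE], params,
                          u = u_mort[alive])
    surv <- which(sub$state != "dead")
    if (length(surv)) {
      idx <- alive[surv]
      s2 <- sub[surv, , drop = FALSE]
      s2 <- step_behaviors(s2, params, u_smoke = u_smoke[idx],
                           u_activity = u_act[idx], z_bmi = z_bmi[idx])
      s2 <- step_employment(s2, params, u = u_emp[idx])
      s2 <- step_health_state(s2, params, u_h1 = u_h1[idx],
                              u_h2 = u_h2[idx], u_rx = u_rx[idx],
                              u_adh = u_adh[idx], u_ctrl = u_ctrl[idx])
      sub[surv, ] <- s2
    }
    cohort[alive, ] <- sub
  }
  counts <- state_counts(cohort, cycle = cycle, age = 24L + cycle)
  live <- cohort$state != "dead"
  cohort$age[live] <- cohort$age[live] + 1L
  list(cohort = cohort, counts = counts)
}

#' Run one cohort for a full career
#'
#' Initialises a cohort of 25-year-old workers and advances it through
#' `n_cycles` annual cycles (ages 25 to 64 with the default 40).  The
#' result is deterministic given the seed.
#'
#' @param n Cohort size.
#' @param race `"white"` or `"Black"`.
#' @param params A `segsim_params` object.
#' @param allocation Allocation matrix; defaults to the status-quo table.
#' @param seed Integer seed for the whole cohort (initialisation and all
#'   cycles).
#' @param n_cycles Number of annual cycles (default 40).
#' @param return_cohort If `TRUE`, the final worker table is attached as
#'   attribute `"cohort"`.
#' @return A `segsim_counts` data frame with one row per cycle (cycle 0 is
#'   the baseline tally at age 25; cycles 1..40 are post-transition tallies
#'   at ages 25..64), columns for each health state, and `alive`.
#' @export
run_cohort <- function(n, race, params, allocation = params$allocation,
                       seed = 1L, n_cycles = 40L, return_cohort = FALSE) {
  stopifnot(n >= 1, n_cycles >= 1)
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  cohort <- init_cohort(n, race, params, allocation)
  rows <- vector("list", n_cycles + 1L)
  rows[[1L]] <- state_counts(cohort, cycle = 0L, age = 25L)
  for (cyc in seq_len(n_cycles)) {
    step <- advance_cycle(cohort, params, cycle = cyc)
    cohort <- step$cohort
    rows[[cyc + 1L]] <- step$counts
  }
  counts <- do.call(rbind, rows)
  attr(counts, "race") <- race
  attr(counts, "seed") <- seed
  if (return_cohort) attr(counts, "cohort") <- cohort
  class(counts) <- c("segsim_counts", "data.frame")
  counts
}
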