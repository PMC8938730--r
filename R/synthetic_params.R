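# Synthetic parameter fixtures.  The source parameters were estimated from
# restricted cohort and survey data (CARDIA, NHANES, NHIS, ACS linked with
# O*NET) and published clinical studies; the fixtures below emulate the
# structure of that parameter set — occupational-class gradients in
# unemployment and psychosocial work environment, race-differential
# medication prescription, age-banded smoking dynamics, race x gender
# baseline distributions — so every downstream stage is testable without any
# restricted download.  Printed quantities (the two risk equations, the
# status-quo allocation rows, the 1%/1%/3%/4% class unemployment gradient
# used for calibration) are embedded exactly; everything else carries
# provenance "fixture".

#' Options controlling synthetic parameter fixtures
#'
#' @param seed Integer; fully determines a randomized fixture.
#' @param gradient_strength Non-negative scale on the occupational-class
#'   gradients (psychosocial work environment means and employment
#'   intercepts); `0` removes all class differences.
#' @param race_effect Non-negative scale on every race differential
#'   (prescription, mortality, baseline distributions, female share);
#'   `0` makes all parameters race-invariant.
#' @param zero_mortality,frozen_behaviors,frozen_employment Degeneracy flags
#'   used by oracle tests: zero all death rates, freeze smoking/activity/BMI
#'   dynamics, freeze employment status.
#' @return A list of class `segsim_fixture_options`.
#' @export
fixture_options <- function(seed = 1L, gradient_strength = 1,
                            race_effect = 1, zero_mortality = FALSE,
                            frozen_behaviors = FALSE,
                            frozen_employment = FALSE) {
  stopifnot(gradient_strength >= 0, race_effect >= 0)
  structure(list(seed = as.integer(seed),
                 gradient_strength = gradient_strength,
                 race_effect = race_effect,
                 zero_mortality = isTRUE(zero_mortality),
                 frozen_behaviors = isTRUE(frozen_behaviors),
                 frozen_employment = isTRUE(frozen_employment)),
            class = "segsim_fixture_options")
}

# printed status-quo allocation rows (predicted probabilities of being in
# each occupational class for 25-year-old healthcare workers)
status_quo_rows <- function() {
  m <- rbind(white_male   = c(0.312, 0.235, 0.291, 0.162),
             Black_male   = c(0.109, 0.151, 0.330, 0.409),
             white_female = c(0.055, 0.409, 0.252, 0.283),
             Black_female = c(0.015, 0.205, 0.223, 0.557))
  colnames(m) <- SEG_CLASSES
  m
}

#' Published reference allocation rows for scenarios A and B
#'
#' The race-independent (A) and race-and-gender-independent (B) predicted
#' allocation rows as published, shipped for cross-checking the
#' mixture-weight marginalisation in [build_scenario_allocation()].  The
#' regression-based marginalisation behind the published rows and the
#' mixture-based reconstruction differ slightly (within 0.005 per entry).
#'
#' @return A list with matrices `A` and `B` (rows: race x gender groups,
#'   columns: occupational classes).
#' @export
reference_scenario_allocations <- function() {
  a_m <- c(0.274, 0.221, 0.299, 0.206)
  a_f <- c(0.046, 0.363, 0.246, 0.346)
  b   <- c(0.087, 0.337, 0.255, 0.321)
  A <- rbind(white_male = a_m, Black_male = a_m,
             white_female = a_f, Black_female = a_f)
  B <- rbind(white_male = b, Black_male = b, white_female = b,
             Black_female = b)
  colnames(A) <- colnames(B) <- SEG_CLASSES
  list(A = A, B = B)
}

# ---------------------------------------------------------------------------
# the builder

# gradient_strength scales class deviations around the class mean;
# race_effect scales Black deviations from the white value; jitter > 0 adds
# seed-reproducible lognormal/logit noise while preserving the structural
# constraints (simplex sums, race ordering, age monotonicity).
build_fixture <- function(gradient_strength = 1, race_effect = 1,
                          jitter = 0, seed = NULL) {
  g <- gradient_strength
  re <- race_effect
  if (!is.null(seed)) set.seed(as.integer(abs(seed) %% .Machine$integer.max))

  jpos <- function(x) if (jitter > 0) x * exp(stats::rnorm(length(x), 0, jitter)) else x
  jprob <- function(x) {
    if (jitter <= 0) return(x)
    stats::plogis(stats::qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6)) +
                    stats::rnorm(length(x), 0, 3 * jitter))
  }
  jmean <- function(x) if (jitter > 0) x + stats::rnorm(length(x), 0, jitter) else x
  grad <- function(x) mean(x) + g * (x - mean(x))        # class gradient
  rmix <- function(white, black) white + re * (black - white)
  rsimplex <- function(white, black) {
    v <- pmax(white + re * (black - white), 0)
    v / sum(v)
  }

  cls <- SEG_CLASSES

  # --- risk equations: printed coefficients, embedded exactly (never jittered)
  risk_equations <- list(
    hypertension_5yr = list(
      intercept = -12.07,
      coefficients = c(LogBMI = 2.497, CurrentSmoker = 0.775,
                       CurrentlyPrehypertensive = 1.710,
                       FamilyHistory = 0.656, WorkFullTime = -0.059,
                       WorkPartTime = -0.135, JobDemand = 0.167,
                       JobControl = -0.347, Support = -0.160,
                       Age = 0.024, Women = 0.197)),
    prehypertension_5yr = list(
      intercept = -5.106,
      coefficients = c(LogBMI = 0.013, CurrentSmoker = -0.424,
                       CurrentlyPrehypertensive = 1.155,
                       FamilyHistory = 0.509, WorkFullTime = 0.361,
                       WorkPartTime = 1.470, JobDemand = -0.278,
                       JobControl = -0.657, Support = -0.206,
                       Age = -0.078, Women = 0.004)))

  # --- treatment and crude transition probabilities (annual)
  rx_white <- jprob(0.34)
  rx_dev <- jpos(0.06)                      # Black - white, kept positive
  prescription <- c(white = rx_white,
                    Black = min(rx_white + re * rx_dev, 1))
  ctrl <- sort(jprob(c(high = 0.30, medium = 0.18, low = 0.08)),
               decreasing = TRUE)
  names(ctrl) <- SEG_ADHERENCE
  adh <- jpos(c(high = 0.52, medium = 0.26, low = 0.22))
  transitions <- list(
    use_risk_equations = TRUE,
    crude = jprob(c(normo_to_prehyp = 0.045, normo_to_hyper = 0.008,
                    prehyp_to_hyper = 0.035)),
    prehyp_to_controlled = jprob(0.032),
    control_by_adherence = ctrl,
    prescription = prescription,
    adherence_init = adh / sum(adh))

  # --- mortality (annual rates, age bands 25-34 / 35-44 / 45-54 / 55-64)
  mono <- function(x) cummax(pmax(x, 0))
  cvd_w_m <- mono(jpos(c(0.00008, 0.00030, 0.00110, 0.00300)))
  cvd_w_f <- mono(jpos(c(0.00003, 0.00012, 0.00045, 0.00130)))
  ncv_w_m <- mono(jpos(c(0.0013, 0.0025, 0.0050, 0.0095)))
  ncv_w_f <- mono(jpos(c(0.0007, 0.0014, 0.0030, 0.0060)))
  cvd_ratio <- jpos(1.8); ncv_ratio <- jpos(1.45)
  preg_w <- jpos(c(0.00002, 0.00001, 0, 0))
  preg_ratio <- jpos(2.5)
  mortality <- list(
    age_breaks = c(25, 35, 45, 55),
    cvd = list(white_male = cvd_w_m,
               Black_male = mono(cvd_w_m * (1 + re * (cvd_ratio - 1))),
               white_female = cvd_w_f,
               Black_female = mono(cvd_w_f * (1 + re * (cvd_ratio - 1)))),
    non_cvd = list(white_male = ncv_w_m,
                   Black_male = mono(ncv_w_m * (1 + re * (ncv_ratio - 1))),
                   white_female = ncv_w_f,
                   Black_female = mono(ncv_w_f * (1 + re * (ncv_ratio - 1)))),
    pregnancy = list(white = preg_w,
                     Black = preg_w * (1 + re * (preg_ratio - 1))),
    hr_cvd_hypertensive = c(male = 1 + jpos(0.6), female = 1 + jpos(1.0)))

  # --- behavior dynamics (annual; age bands 18-29 / 30-44 / 45+)
  behavior <- list(
    smoking = list(age_breaks = c(18, 30, 45),
                   never_to_current = jprob(c(0.015, 0.004, 0.001)),
                   current_to_former = jprob(c(0.035, 0.045, 0.060)),
                   former_to_current = jprob(c(0.060, 0.030, 0.012))),
    activity = jprob(c(inactive_to_active = 0.09,
                       active_to_inactive = 0.11)),
    bmi_drift = list(active = jpos(0.10), inactive = jpos(0.25),
                     sd = jpos(0.10), floor = 12))

  # --- employment model: three-outcome multinomial score; the unemployed
  # intercepts are calibrated so the implied stationary class-level
  # unemployment probabilities track the published 1%/1%/3%/4% gradient
  iu <- cummax(grad(jmean(c(-4.45, -4.15, -3.25, -2.95))))
  ip <- grad(jmean(c(-1.90, -1.30, -1.45, -1.10)))
  names(iu) <- names(ip) <- cls
  employment <- list(
    frozen = FALSE,
    intercept_unemployed = iu,
    intercept_part_time = ip,
    slopes_unemployed = c(age = 0, female = jmean(0.10),
                          Black = re * jpos(0.25),
                          ever_unemployed = jpos(0.90)),
    slopes_part_time = c(age = 0, female = jmean(0.60),
                         Black = re * jpos(0.05),
                         ever_unemployed = jpos(0.25)))

  # --- race x gender baseline distributions
  smoke_w_m <- jprob(c(current = 0.26, former = 0.08, never = 0.66))
  smoke_w_f <- jprob(c(current = 0.21, former = 0.08, never = 0.71))
  smoke_b_m <- jprob(c(current = 0.19, former = 0.05, never = 0.76))
  smoke_b_f <- jprob(c(current = 0.12, former = 0.04, never = 0.84))
  bp_w_m <- jprob(c(normotensive = 0.60, prehypertensive = 0.36,
                    hypertensive = 0.04))
  bp_w_f <- jprob(c(normotensive = 0.76, prehypertensive = 0.21,
                    hypertensive = 0.03))
  bp_b_m <- jprob(c(normotensive = 0.55, prehypertensive = 0.39,
                    hypertensive = 0.06))
  bp_b_f <- jprob(c(normotensive = 0.68, prehypertensive = 0.27,
                    hypertensive = 0.05))
  lb_w_m <- c(meanlog = jmean(3.266) , sdlog = jpos(0.17))
  lb_w_f <- c(meanlog = jmean(3.238), sdlog = jpos(0.20))
  lb_dev_m <- jmean(0.030); lb_dev_f <- jmean(0.129)
  act_w <- jprob(c(white_male = 0.56, white_female = 0.50))
  act_dev <- jmean(c(male = -0.06, female = -0.12))
  fh_w <- jprob(0.44); fh_dev <- jpos(0.14)
  fem_w <- jprob(0.813); fem_dev <- jmean(0.033)
  baselines <- list(
    female_share = c(white = fem_w,
                     Black = min(max(fem_w + re * fem_dev, 0), 1)),
    family_history = c(white = fh_w, Black = min(fh_w + re * fh_dev, 1)),
    smoking = list(white_male = smoke_w_m / sum(smoke_w_m),
                   Black_male = rsimplex(smoke_w_m / sum(smoke_w_m),
                                         smoke_b_m / sum(smoke_b_m)),
                   white_female = smoke_w_f / sum(smoke_w_f),
                   Black_female = rsimplex(smoke_w_f / sum(smoke_w_f),
                                           smoke_b_f / sum(smoke_b_f))),
    log_bmi = list(white_male = lb_w_m,
                   Black_male = c(meanlog = lb_w_m[["meanlog"]] + re * lb_dev_m,
                                  sdlog = lb_w_m[["sdlog"]]),
                   white_female = lb_w_f,
                   Black_female = c(meanlog = lb_w_f[["meanlog"]] + re * lb_dev_f,
                                    sdlog = lb_w_f[["sdlog"]])),
    active = c(white_male = act_w[["white_male"]],
               Black_male = min(max(act_w[["white_male"]] +
                                      re * act_dev[["male"]], 0), 1),
               white_female = act_w[["white_female"]],
               Black_female = min(max(act_w[["white_female"]] +
                                        re * act_dev[["female"]], 0), 1)),
    bp_state = list(white_male = bp_w_m / sum(bp_w_m),
                    Black_male = rsimplex(bp_w_m / sum(bp_w_m),
                                          bp_b_m / sum(bp_b_m)),
                    white_female = bp_w_f / sum(bp_w_f),
                    Black_female = rsimplex(bp_w_f / sum(bp_w_f),
                                            bp_b_f / sum(bp_b_f))))

  # --- psychosocial work environment: class-specific normals on a
  # standardized scale; control and support decrease, and the implied
  # iso-strain index increases, from diagnosing professionals to aides
  pwe_mean <- function(x) { x <- grad(jmean(x)); names(x) <- cls; x }
  pwe_sd <- function(s) stats::setNames(rep(jpos(s), 4), cls)
  pwe <- list(
    demand = list(mean = pwe_mean(c(0.55, 0.40, 0.25, 0.50)),
                  sd = pwe_sd(0.8)),
    control = list(mean = pwe_mean(c(1.00, 0.40, -0.20, -0.80)),
                   sd = pwe_sd(0.8)),
    support = list(mean = pwe_mean(c(0.60, 0.30, 0.00, -0.40)),
                   sd = pwe_sd(0.8)))

  # --- composition weights for mixture marginalisation of scenarios A/B,
  # calibrated so the mixtures reproduce the published A/B rows within 0.005
  composition <- list(female_share_overall = 0.820,
                      white_share_men = 0.813,
                      white_share_women = 0.775)

  provenance <- list(
    risk_equation_hypertension = "CARDIA-estimated logistic risk equation (printed coefficients)",
    risk_equation_prehypertension = "CARDIA-estimated logistic risk equation (printed coefficients)",
    crude_transitions = "CARDIA year-15 crude transition probabilities; fixture values",
    prehyp_to_controlled = "Appel 2003 behavioral modification; fixture value",
    control_by_adherence = "Bramley 2006; fixture values",
    prescription = "Samanic 2020; fixture values",
    adherence_init = "Bramley 2006; fixture values",
    mortality_cvd = "National Vital Statistics System 2017; fixture values",
    mortality_non_cvd = "National Vital Statistics System 2017; fixture values",
    mortality_pregnancy = "National Vital Statistics System 2017; fixture values",
    cvd_hazard_ratio = "Franco 2005; fixture values",
    smoking_transitions = "Yi 2017; fixture values",
    activity_transitions = "Dalziel 2006; fixture values",
    bmi_drift = "fixture",
    family_history = "Muntner 2010; fixture values",
    female_share = "ACS 2012-2017; fixture values",
    smoking_baseline = "NHIS 2000-2018; fixture values",
    bmi_baseline = "NHIS 2000-2018; fixture values",
    bp_state_baseline = "NHANES 1999-2018; fixture values",
    activity_baseline = "NHIS 2000-2018; fixture values",
    employment_model = "ACS 2012-2017 gradient calibration (1%/1%/3%/4%); fixture coefficients",
    pwe_distributions = "ACS 2012-2018 linked with O*NET 3.1; fixture standardized scale",
    allocation_status_quo = "ACS 2012-2017 multinomial predictions (printed rows)",
    composition_weights = "fixture-calibrated mixture weights")

  p <- list(meta = list(name = "fixture"),
            risk_equations = risk_equations,
            transitions = transitions,
            mortality = mortality,
            behavior = behavior,
            employment = employment,
            baselines = baselines,
            pwe = pwe,
            allocation = status_quo_rows(),
            composition = composition,
            provenance = provenance)
  class(p) <- "segsim_params"
  p
}

apply_fixture_flags <- function(p, opts) {
  if (opts$zero_mortality) {
    zero <- rep(0, length(p$mortality$age_breaks))
    for (k in SEG_RG_KEYS) {
      p$mortality$cvd[[k]] <- zero
      p$mortality$non_cvd[[k]] <- zero
    }
    for (k in SEG_RACES) p$mortality$pregnancy[[k]] <- zero
  }
  if (opts$frozen_behaviors) {
    nb <- length(p$behavior$smoking$age_breaks)
    p$behavior$smoking$never_to_current <- rep(0, nb)
    p$behavior$smoking$current_to_former <- rep(0, nb)
    p$behavior$smoking$former_to_current <- rep(0, nb)
    p$behavior$activity[] <- 0
    p$behavior$bmi_drift$active <- 0
    p$behavior$bmi_drift$inactive <- 0
    p$behavior$bmi_drift$sd <- 0
  }
  if (opts$frozen_employment) p$employment$frozen <- TRUE
  p
}

#' The default (reference) parameter fixture
#'
#' Returns the shipped reference parameter set: the printed risk-equation
#' coefficients and status-quo allocation rows exactly as published, an
#' employment model calibrated to the 1%/1%/3%/4% class unemployment
#' gradient, psychosocial work environment distributions with monotone class
#' gradients, a higher prescription probability for Black than for white
#' hypertensive workers, and fixture defaults (tagged in `$provenance`) for
#' every parameter whose source data are restricted.
#'
#' @return A validated `segsim_params` object.
#' @export
default_parameter_fixture <- function() {
  build_fixture(gradient_strength = 1, race_effect = 1, jitter = 0)
}

#' A randomized but valid parameter fixture
#'
#' Draws a parameter set around the default fixture with seed-reproducible
#' jitter; structural constraints (class gradients, race differentials,
#' simplex sums, age-monotone mortality) still hold, so every emitted set
#' passes [validate_parameters()].
#'
#' @param opts A [fixture_options()] list; `opts$seed` fully determines the
#'   result.
#' @return A validated `segsim_params` object.
#' @export
randomized_parameter_fixture <- function(opts = fixture_options()) {
  p <- build_fixture(gradient_strength = opts$gradient_strength,
                     race_effect = opts$race_effect,
                     jitter = 0.05, seed = opts$seed)
  p <- apply_fixture_flags(p, opts)
  validate_parameters(p)
  p
}

#' A minimal deterministic-friendly ("toy") parameter fixture
#'
#' Builds a parameter set for oracle tests: risk equations are replaced by
#' fixed crude transition probabilities, behaviors/employment/mortality can
#' be frozen or zeroed, the psychosocial scores are degenerate, and the
#' baseline blood-pressure distribution can be set directly.  With
#' `prescription` equal to 0 or 1 the whole cohort follows a homogeneous
#' five-state Markov chain, which is what the matrix-power oracle checks.
#'
#' @param flags A [fixture_options()] list of degeneracy flags; by default
#'   mortality is zeroed and behaviors and employment are frozen.
#' @param crude Named annual probabilities `normo_to_prehyp`,
#'   `normo_to_hyper`, `prehyp_to_hyper` (all 0 by default).
#' @param prehyp_to_controlled Annual behavioral-modification probability.
#' @param prescription Prescription probability applied to both races
#'   (scalar), or a named `c(white=, Black=)` vector.
#' @param control Control probability applied to all adherence levels
#'   (scalar), or a named high/medium/low vector.
#' @param flat_mortality Constant annual non-CVD death rate for every
#'   stratum (ignored when `flags$zero_mortality` is `TRUE`).
#' @param bp_state Optional length-3 baseline distribution over
#'   normotensive/prehypertensive/hypertensive applied to every race x
#'   gender group.
#' @param pwe_sd Scale of the psychosocial score distributions (0 gives the
#'   class-mean point mass).
#' @return A validated `segsim_params` object.
#' @export
toy_parameter_fixture <- function(flags = fixture_options(zero_mortality = TRUE,
                                                          frozen_behaviors = TRUE,
                                                          frozen_employment = TRUE),
                                  crude = c(normo_to_prehyp = 0,
                                            normo_to_hyper = 0,
                                            prehyp_to_hyper = 0),
                                  prehyp_to_controlled = 0,
                                  prescription = 0,
                                  control = 0,
                                  flat_mortality = 0,
                                  bp_state = NULL,
                                  pwe_sd = 0) {
  p <- build_fixture(1, 1, jitter = 0)
  p$meta$name <- "toy"
  p$transitions$use_risk_equations <- FALSE
  p$transitions$crude[names(crude)] <- crude
  p$transitions$prehyp_to_controlled <- prehyp_to_controlled
  if (length(control) == 1L) {
    p$transitions$control_by_adherence[] <- control
  } else {
    p$transitions$control_by_adherence[names(control)] <- control
  }
  if (length(prescription) == 1L) {
    p$transitions$prescription[] <- prescription
  } else {
    p$transitions$prescription[names(prescription)] <- prescription
  }
  nb <- length(p$mortality$age_breaks)
  for (k in SEG_RG_KEYS) {
    p$mortality$cvd[[k]] <- rep(0, nb)
    p$mortality$non_cvd[[k]] <- rep(flat_mortality, nb)
  }
  for (k in SEG_RACES) p$mortality$pregnancy[[k]] <- rep(0, nb)
  p$mortality$hr_cvd_hypertensive[] <- 1
  if (!is.null(bp_state)) {
    stopifnot(length(bp_state) == 3L, abs(sum(bp_state) - 1) < 1e-9)
    bp <- stats::setNames(as.numeric(bp_state),
                          c("normotensive", "prehypertensive", "hypertensive"))
    for (k in SEG_RG_KEYS) p$baselines$bp_state[[k]] <- bp
  }
  for (dim in c("demand", "control", "support")) p$pwe[[dim]]$sd[] <- pwe_sd
  p <- apply_fixture_flags(p, flags)
  validate_parameters(p)
  p
}

# closed-form iso-strain index for a class: joint probability of high
# demand, low control and low support under independent normal scores
iso_strain_index <- function(params) {
  d <- params$pwe$demand; co <- params$pwe$control; s <- params$pwe$support
  sdx <- function(x) ifelse(x$sd > 0, x$sd, 1e-12)
  stats::pnorm(0, d$mean, sdx(d), lower.tail = FALSE) *
    stats::pnorm(0, co$mean, sdx(co)) *
    stats::pnorm(0, s$mean, sdx(s))
}
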