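# Scenario engine: constructs the status-quo and four counterfactual
# allocation tables, runs multi-cohort experiments for both races under
# each, and drives the +/- 25% one-way sensitivity analysis.  Identical
# per-cohort random streams are reused across scenarios (common random
# numbers), so scenario contrasts are paired; in particular the white
# workforce under scenario C is bit-identical to the status quo.

#' Scenario names
#' @return `c("status_quo", "A", "B", "C", "D")`.
#' @export
scenario_names <- function() c("status_quo", "A", "B", "C", "D")

#' Build a counterfactual allocation table
#'
#' Starting from the status-quo race x gender allocation rows:
#' * `status_quo` — unchanged;
#' * `A` — race is removed: within each gender, rows are replaced by the
#'   composition-weighted average across races (gender inequity remains);
#' * `B` — race and gender are removed: all rows are replaced by the overall
#'   composition-weighted average;
#' * `C` — Black men and Black women receive the status-quo rows of white
#'   men and white women respectively (white rows unchanged);
#' * `D` — every group receives the status-quo white-male row.
#'
#' Scenarios A and B are mixture-weight marginalisations of the status-quo
#' rows and need the workforce composition weights; the published
#' regression-based rows are available from
#' [reference_scenario_allocations()] for comparison.
#'
#' @param name One of [scenario_names()].
#' @param status_quo Status-quo allocation matrix.
#' @param composition List with `female_share_overall`, `white_share_men`,
#'   `white_share_women` (required for A and B).
#' @return An allocation matrix.
#' @export
build_scenario_allocation <- function(name, status_quo, composition = NULL) {
  name <- match.arg(name, scenario_names())
  validate_allocation(status_quo)
  tab <- status_quo[SEG_RG_KEYS, , drop = FALSE]
  if (name %in% c("A", "B") &&
      (is.null(composition) ||
       is.null(composition$white_share_men) ||
       is.null(composition$white_share_women) ||
       (name == "B" && is.null(composition$female_share_overall)))) {
    stop("scenario ", name, " needs workforce composition weights",
         call. = FALSE)
  }
  switch(name,
    status_quo = tab,
    A = {
      wm <- composition$white_share_men
      ww <- composition$white_share_women
      male <- wm * tab["white_male", ] + (1 - wm) * tab["Black_male", ]
      female <- ww * tab["white_female", ] + (1 - ww) * tab["Black_female", ]
      tab["white_male", ] <- tab["Black_male", ] <- male
      tab["white_female", ] <- tab["Black_female", ] <- female
      tab
    },
    B = {
      f <- composition$female_share_overall
      wm <- composition$white_share_men
      ww <- composition$white_share_women
      w <- c(white_male = (1 - f) * wm, Black_male = (1 - f) * (1 - wm),
             white_female = f * ww, Black_female = f * (1 - ww))
      overall <- drop(w[SEG_RG_KEYS] %*% tab[SEG_RG_KEYS, ])
      tab[] <- matrix(overall, nrow = 4, ncol = 4, byrow = TRUE)
      tab
    },
    C = {
      tab["Black_male", ] <- tab["white_male", ]
      tab["Black_female", ] <- tab["white_female", ]
      tab
    },
    D = {
      tab[] <- matrix(tab["white_male", ], nrow = 4, ncol = 4, byrow = TRUE)
      tab
    })
}

#' Describe a counterfactual scenario
#'
#' @param name Scenario name.
#' @param allocation Its allocation matrix.
#' @param description Free-text description.
#' @return A list of class `segsim_scenario`.
#' @export
scenario_spec <- function(name, allocation, description = "") {
  validate_allocation(allocation)
  structure(list(name = name, allocation = allocation,
                 description = description), class = "segsim_scenario")
}

#' Configure a multi-cohort experiment
#'
#' The defaults mirror the full-scale design (500 cohorts of 100,000
#' workers per race); scale `n_cohorts` and `cohort_size` down for desk
#' runs.
#'
#' @param n_cohorts Number of independent cohorts per scenario x race.
#' @param cohort_size Workers per cohort per race.
#' @param seed Master seed; per-cohort sub-seeds depend only on the master
#'   seed, the race and the cohort index — never on the scenario — so runs
#'   are common-random-number paired across scenarios.
#' @param scenarios Character vector of scenario names to run.
#' @param races Races to simulate.
#' @param n_cycles Annual cycles per cohort (default 40, ages 25-64).
#' @return A list of class `segsim_config`.
#' @export
experiment_config <- function(n_cohorts = 500L, cohort_size = 100000L,
                              seed = 1L, scenarios = scenario_names(),
                              races = worker_races(), n_cycles = 40L) {
  stopifnot(n_cohorts >= 1, cohort_size >= 1, n_cycles >= 1)
  scenarios <- match.arg(scenarios, scenario_names(), several.ok = TRUE)
  races <- match.arg(races, SEG_RACES, several.ok = TRUE)
  structure(list(n_cohorts = as.integer(n_cohorts),
                 cohort_size = as.integer(cohort_size),
                 seed = as.integer(seed),
                 scenarios = scenarios,
                 races = races,
                 n_cycles = as.integer(n_cycles)),
            class = "segsim_config")
}

#' Run the multi-cohort scenario experiment
#'
#' For each scenario x race, runs `n_cohorts` independent cohorts (each on
#' its own sub-seed of the master seed, reused across scenarios for common
#' random numbers) and averages the per-cycle hypertension prevalence with
#' unweighted means across cohorts.  Per-cohort series are retained for
#' dispersion summaries.
#'
#' @param cfg An [experiment_config()].
#' @param params A `segsim_params` object.
#' @return A list of class `segsim_experiment` with elements `config`,
#'   `prevalence` (per-cohort long data frame), `mean_prevalence`
#'   (scenario x race x cycle means) and `params_digest`.
#' @export
run_experiment <- function(cfg, params) {
  stopifnot(inherits(cfg, "segsim_config"))
  validate_parameters(params)
  allocs <- stats::setNames(
    lapply(cfg$scenarios, build_scenario_allocation,
           status_quo = params$allocation, composition = params$composition),
    cfg$scenarios)
  pieces <- list()
  for (sc in cfg$scenarios) {
    for (race in cfg$races) {
      for (i in seq_len(cfg$n_cohorts)) {
        counts <- run_cohort(cfg$cohort_size, race, params,
                             allocation = allocs[[sc]],
                             seed = cohort_seed(cfg$seed, race, i),
                             n_cycles = cfg$n_cycles)
        ps <- prevalence_by_cycle(counts)
        pieces[[length(pieces) + 1L]] <- data.frame(
          scenario = sc, race = race, cohort = i, ps,
          stringsAsFactors = FALSE)
      }
    }
  }
  prevalence <- do.call(rbind, pieces)
  agg <- stats::aggregate(prevalence ~ scenario + race + cycle + age,
                          data = prevalence, FUN = mean)
  names(agg)[names(agg) == "prevalence"] <- "mean_prevalence"
  agg <- agg[order(agg$scenario, agg$race, agg$cycle), ]
  rownames(agg) <- NULL
  structure(list(config = cfg,
                 prevalence = prevalence,
                 mean_prevalence = agg,
                 params_digest = params_digest(params)),
            class = "segsim_experiment")
}

#' @export
print.segsim_experiment <- function(x, ...) {
  cat("segsim experiment:", length(unique(x$prevalence$scenario)),
      "scenario(s) x", length(unique(x$prevalence$race)), "race(s),",
      x$config$n_cohorts, "cohort(s) of", x$config$cohort_size,
      "workers\n")
  print(career_averages(x))
  invisible(x)
}

#' Career-average hypertension prevalence
#'
#' The unweighted mean of the 40 per-cycle prevalences (ages 25-64),
#' averaged with equal weight across cohorts, per scenario x race; the
#' standard deviation of the per-cohort career averages is retained as a
#' dispersion summary.
#'
#' @param experiment A `segsim_experiment`.
#' @return Data frame with columns `scenario`, `race`, `career_prevalence`
#'   (a proportion) and `sd_cohorts`.
#' @export
career_averages <- function(experiment) {
  p <- experiment$prevalence
  per <- stats::aggregate(prevalence ~ scenario + race + cohort, data = p,
                          FUN = mean)
  out <- stats::aggregate(prevalence ~ scenario + race, data = per,
                          FUN = mean)
  names(out)[names(out) == "prevalence"] <- "career_prevalence"
  out$sd_cohorts <- stats::aggregate(prevalence ~ scenario + race,
                                     data = per, FUN = stats::sd)$prevalence
  out[order(match(out$scenario, scenario_names()), out$race), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' One-way sensitivity analysis
#'
#' Reruns the full experiment with each of the two treatment parameter
#' blocks — the race-specific prescription probabilities and the
#' adherence-level control probabilities — separately scaled to
#' `1 - factor` and `1 + factor` of their base values (separate runs).  The
#' uncertainty interval for each scenario x race is the minimum and maximum
#' of the career-average prevalence across the base and the two perturbed
#' runs, so it always contains the base value; the two perturbed arms are
#' also reported.
#'
#' @param cfg An [experiment_config()].
#' @param params A `segsim_params` object.
#' @param factor Relative perturbation (default 0.25 for +/- 25%).
#' @return Data frame of class `segsim_sensitivity` with columns
#'   `scenario`, `race`, `block`, `base`, `minus`, `plus`, `low`, `high`
#'   (all proportions).
#' @export
run_sensitivity <- function(cfg, params, factor = 0.25) {
  base <- career_averages(run_experiment(cfg, params))
  out <- list()
  for (block in c("prescription", "control_by_adherence")) {
    lo <- career_averages(run_experiment(cfg,
      perturb_parameters(params, block, -factor)))
    hi <- career_averages(run_experiment(cfg,
      perturb_parameters(params, block, +factor)))
    m <- base[, c("scenario", "race")]
    m$block <- block
    m$base <- base$career_prevalence
    m$minus <- lo$career_prevalence[match(paste(m$scenario, m$race),
                                          paste(lo$scenario, lo$race))]
    m$plus <- hi$career_prevalence[match(paste(m$scenario, m$race),
                                         paste(hi$scenario, hi$race))]
    m$low <- pmin(m$base, m$minus, m$plus)
    m$high <- pmax(m$base, m$minus, m$plus)
    out[[block]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("segsim_sensitivity", "data.frame")
  res
}
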