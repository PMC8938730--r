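# Outcome aggregation: prevalence trajectories, age-group and career
# averages, Black-white gaps, sensitivity tables, the cost-savings
# estimate, and report files.

AGE_BANDS <- c("25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
               "55-59", "60-64")

#' Hypertension prevalence by cycle
#'
#' Prevalence is the number of hypertensive workers divided by the number
#' of alive workers at each cycle.  Workers in the controlled state are
#' normotensive in the current cycle and are excluded from the numerator by
#' default; set `include_controlled = TRUE` to count them as treated
#' hypertension instead.
#'
#' @param counts A `segsim_counts` data frame from [run_cohort()] (the
#'   baseline cycle-0 row, if present, is dropped).
#' @param include_controlled Count controlled workers in the numerator?
#' @return Data frame with columns `cycle`, `age`, `alive`, `hypertensive`
#'   and `prevalence`.
#' @export
prevalence_by_cycle <- function(counts, include_controlled = FALSE) {
  x <- as.data.frame(counts)
  x <- x[x$cycle >= 1L, , drop = FALSE]
  if (nrow(x) == 0L) stop("no post-baseline cycles in counts", call. = FALSE)
  if (any(x$alive == 0)) {
    stop("prevalence is undefined: no workers alive at cycle ",
         paste(x$cycle[x$alive == 0], collapse = ", "), call. = FALSE)
  }
  hyp <- x$hypertensive + if (include_controlled) x$controlled else 0
  out <- data.frame(cycle = x$cycle, age = x$age, alive = x$alive,
                    hypertensive = hyp, prevalence = hyp / x$alive)
  rownames(out) <- NULL
  out
}

#' Age-group mean prevalence
#'
#' Unweighted means of the per-cycle prevalence over the eight five-year
#' age bands (25-29, ..., 60-64) and over the whole career (25-64),
#' reported per 100 workers.  The career mean equals the unweighted mean of
#' the 40 per-cycle values.
#'
#' @param series A per-cycle prevalence data frame covering all 40 cycles
#'   (ages 25-64), e.g. from [prevalence_by_cycle()] or one scenario x race
#'   slice of an experiment's `mean_prevalence` (column `prevalence` or
#'   `mean_prevalence`).
#' @return Data frame with columns `age_group` and `prevalence_per_100`;
#'   `scenario`/`race` columns are carried through when present.
#' @export
age_group_means <- function(series) {
  s <- as.data.frame(series)
  pcol <- intersect(c("prevalence", "mean_prevalence"), names(s))[1]
  if (is.na(pcol)) stop("series must have a prevalence column", call. = FALSE)
  if (!all(25:64 %in% s$age)) {
    stop("incomplete series: all 40 ages 25-64 are required", call. = FALSE)
  }
  s <- s[s$age %in% 25:64, , drop = FALSE]
  band <- cut(s$age, breaks = seq(25, 65, by = 5), right = FALSE,
              labels = AGE_BANDS)
  m <- tapply(s[[pcol]], band, mean)
  out <- data.frame(age_group = c(AGE_BANDS, "25-64"),
                    prevalence_per_100 = 100 * c(as.numeric(m),
                                                 mean(s[[pcol]])))
  for (meta in c("scenario", "race")) {
    if (meta %in% names(s)) out[[meta]] <- s[[meta]][1]
  }
  out
}

#' Black-white prevalence gap by age band
#'
#' @param black,white Age-group summaries from [age_group_means()] for the
#'   same scenario.
#' @return Data frame with `age_group` and `gap_per_100` (Black minus
#'   white).
#' @export
racial_gap <- function(black, white) {
  if (!identical(black$age_group, white$age_group)) {
    stop("age-group summaries do not align", call. = FALSE)
  }
  if (!is.null(black$scenario) && !is.null(white$scenario) &&
      !identical(black$scenario[1], white$scenario[1])) {
    stop("scenario mismatch between the two summaries", call. = FALSE)
  }
  out <- data.frame(age_group = black$age_group,
                    gap_per_100 = black$prevalence_per_100 -
                      white$prevalence_per_100)
  if (!is.null(black$scenario)) out$scenario <- black$scenario[1]
  out
}

#' Age-group summary for a whole experiment
#'
#' Applies [age_group_means()] to every scenario x race mean-prevalence
#' series of an experiment.
#'
#' @param experiment A `segsim_experiment`.
#' @return Long data frame: `scenario`, `race`, `age_group`,
#'   `prevalence_per_100`.
#' @export
experiment_age_group_summary <- function(experiment) {
  mp <- experiment$mean_prevalence
  pieces <- list()
  for (sc in unique(mp$scenario)) {
    for (rc in unique(mp$race)) {
      s <- mp[mp$scenario == sc & mp$race == rc, , drop = FALSE]
      pieces[[paste(sc, rc)]] <- age_group_means(s)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("scenario", "race", "age_group", "prevalence_per_100")]
}

#' Annual societal savings from a prevalence reduction
#'
#' The product of the workforce size, the excess annual healthcare cost per
#' hypertensive worker, and the prevalence reduction (in proportion points,
#' as a fraction): e.g. 1.7 million workers x $1,920 x 0.01 is about $32.6
#' million per year.
#'
#' @param workforce_size Number of workers.
#' @param excess_cost Excess cost in USD per hypertensive person per year.
#' @param prevalence_drop Prevalence reduction as a fraction (one
#'   percentage point = 0.01).
#' @return Annual savings in USD.
#' @export
savings_estimate <- function(workforce_size, excess_cost, prevalence_drop) {
  vals <- c(workforce_size, excess_cost, prevalence_drop)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop("all savings inputs must be non-negative numbers", call. = FALSE)
  }
  workforce_size * excess_cost * prevalence_drop
}

#' Write report files for an experiment
#'
#' Emits, under `dir`:
#' * `prevalence_by_age_group.csv` — scenario x race x age band means per
#'   100;
#' * `prevalence_by_cycle.csv` — per-cycle mean prevalence trajectories;
#' * `sensitivity.csv` (when a sensitivity result is supplied) — base, the
#'   two +/- arms and the low/high interval per block, per 100;
#' * `manifest.json` — seed, design, parameter digest and versions.
#'
#' @param experiment A `segsim_experiment`.
#' @param sensitivity Optional `segsim_sensitivity` result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(experiment, sensitivity = NULL, dir = ".") {
  stopifnot(inherits(experiment, "segsim_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  t3 <- experiment_age_group_summary(experiment)
  p <- file.path(dir, "prevalence_by_age_group.csv")
  utils::write.csv(t3, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(dir, "prevalence_by_cycle.csv")
  utils::write.csv(experiment$mean_prevalence, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(sensitivity)) {
    s <- as.data.frame(sensitivity)
    stopifnot(all(s$low <= s$base + 1e-12), all(s$base <= s$high + 1e-12))
    for (cl in c("base", "minus", "plus", "low", "high")) {
      s[[cl]] <- 100 * s[[cl]]
    }
    p <- file.path(dir, "sensitivity.csv")
    utils::write.csv(s, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  cfg <- experiment$config
  manifest <- list(seed = cfg$seed,
                   n_cohorts = cfg$n_cohorts,
                   cohort_size = cfg$cohort_size,
                   n_cycles = cfg$n_cycles,
                   scenarios = cfg$scenarios,
                   races = cfg$races,
                   params_digest = experiment$params_digest,
                   package_version =
                     as.character(utils::packageVersion("segsim")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
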