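# Cohort initialisation: seed-reproducible baseline cohorts of 25-year-old
# workers, occupational-class allocation, and psychosocial work environment
# assignment.  Occupational class is immutable after initialisation (no
# interclass mobility), and the psychosocial profile is assigned once at
# age 25.

#' Validate an allocation table
#'
#' An allocation table maps each race x gender group to a probability vector
#' over the four occupational classes.  Printed rows carry rounding, so rows
#' must sum to 1 within `tol` (0.005 by default); tables constructed by the
#' scenario engine from normalised rows are exact to numerical precision.
#'
#' @param table A matrix with rows named by race x gender key
#'   (`white_male`, `Black_male`, `white_female`, `Black_female`) and four
#'   class columns.
#' @param tol Tolerance on each row sum.
#' @return `table`, invisibly.
#' @export
validate_allocation <- function(table, tol = 0.005) {
  chk(is.matrix(table) && ncol(table) == 4,
      "allocation table must be a matrix with one column per occupational class")
  chk(all(SEG_RG_KEYS %in% rownames(table)),
      "allocation table must have rows: ", paste(SEG_RG_KEYS, collapse = ", "))
  chk(all(is.finite(table)) && all(table >= 0) && all(table <= 1),
      "allocation probabilities must lie in [0, 1]")
  bad <- abs(rowSums(table[SEG_RG_KEYS, , drop = FALSE]) - 1) > tol
  chk(!any(bad), "allocation row(s) do not sum to 1: ",
      paste(SEG_RG_KEYS[bad], collapse = ", "))
  invisible(table)
}

#' Read or write allocation tables as CSV
#'
#' Long format with columns `scenario`, `race`, `gender`, `class`,
#' `probability`.
#'
#' @param tables Named list of allocation matrices (names are scenario
#'   labels).
#' @param path CSV file path.
#' @return `read_allocation_csv()`: a named list of allocation matrices;
#'   `write_allocation_csv()`: `path`, invisibly.
#' @name allocation_csv
NULL

#' @rdname allocation_csv
#' @export
write_allocation_csv <- function(tables, path) {
  rows <- list()
  for (sc in names(tables)) {
    tab <- validate_allocation(tables[[sc]])
    for (k in SEG_RG_KEYS) {
      rg <- strsplit(k, "_", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, race = rg[1], gender = rg[2],
        class = SEG_CLASSES, probability = unname(tab[k, ]))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname allocation_csv
#' @export
read_allocation_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "race", "gender", "class", "probability")
  chk(all(need %in% names(x)), "allocation CSV must have columns: ",
      paste(need, collapse = ", "))
  out <- list()
  for (sc in unique(x$scenario)) {
    xs <- x[x$scenario == sc, ]
    tab <- matrix(NA_real_, nrow = length(SEG_RG_KEYS),
                  ncol = length(SEG_CLASSES),
                  dimnames = list(SEG_RG_KEYS, SEG_CLASSES))
    tab[cbind(rg_key(xs$race, xs$gender), xs$class)] <- xs$probability
    out[[sc]] <- validate_allocation(tab)
  }
  out
}

#' Draw occupational classes from an allocation row
#'
#' One categorical draw per worker from the (race, gender) row of the
#' allocation table.  Residual rounding mass in printed rows falls in the
#' last class.
#'
#' @param race,gender Scalars, or vectors of length `n`.
#' @param table Allocation matrix (see [validate_allocation()]).
#' @param n Number of draws.
#' @return Character vector of occupational classes.
#' @export
allocate_occupation <- function(race, gender, table, n = max(length(race),
                                                            length(gender))) {
  keys <- rg_key(rep_len(race, n), rep_len(gender, n))
  missing_keys <- setdiff(unique(keys), rownames(table))
  if (length(missing_keys)) {
    stop("allocation row missing for group(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  validate_allocation(table)
  p <- table[keys, , drop = FALSE]
  SEG_CLASSES[sample_categorical(p, stats::runif(n))]
}

#' Assign psychosocial work environment profiles
#'
#' Draws job demand, job control and workplace support from the
#' class-specific normal distributions.  Profiles are assigned once at age
#' 25 and never redrawn; during unemployed cycles the effective covariates
#' entering the risk equations are zero but the stored profile is unchanged.
#'
#' @param occupation Character vector of occupational classes.
#' @param params A `segsim_params` object.
#' @return A data frame with columns `pwe_demand`, `pwe_control`,
#'   `pwe_support`.
#' @export
assign_pwe <- function(occupation, params) {
  idx <- match(occupation, SEG_CLASSES)
  chk(!anyNA(idx), "unknown occupational class in assign_pwe()")
  n <- length(occupation)
  draw <- function(d) stats::rnorm(n, d$mean[idx], d$sd[idx])
  data.frame(pwe_demand = draw(params$pwe$demand),
             pwe_control = draw(params$pwe$control),
             pwe_support = draw(params$pwe$support))
}

#' Employment-status probabilities
#'
#' Evaluates the three-outcome (full-time / part-time / unemployed)
#' multinomial employment score with covariates age, gender, race,
#' unemployment history and occupational class.  The unemployed intercepts
#' are calibrated so the implied class-level unemployment probabilities are
#' non-decreasing from health diagnosing professionals to aides (the
#' 1%/1%/3%/4% gradient).  Also used for the baseline employment
#' distribution at age 25 (with no unemployment history).
#'
#' @param race,gender,occupation,age,ever_unemployed Worker covariates
#'   (vectors are recycled to a common length).
#' @param params A `segsim_params` object.
#' @return An `n x 3` matrix with columns `full_time`, `part_time`,
#'   `unemployed`.
#' @export
employment_probabilities <- function(race, gender, occupation, age,
                                     ever_unemployed, params) {
  e <- params$employment
  lin <- function(int, sl) {
    int[occupation] +
      sl[["age"]] * (age - 25) +
      sl[["female"]] * (gender == "female") +
      sl[["Black"]] * (race == "Black") +
      sl[["ever_unemployed"]] * as.numeric(ever_unemployed)
  }
  lp_p <- lin(e$intercept_part_time, e$slopes_part_time)
  lp_u <- lin(e$intercept_unemployed, e$slopes_unemployed)
  den <- 1 + exp(lp_p) + exp(lp_u)
  cbind(full_time = 1 / den, part_time = exp(lp_p) / den,
        unemployed = exp(lp_u) / den)
}

#' Initialise a baseline cohort of 25-year-old workers
#'
#' Draws gender, family history, BMI, smoking status, physical activity,
#' baseline blood-pressure state and employment from the race x gender
#' baseline distributions; allocates each worker to an occupational class
#' from the allocation row for their race and gender; and assigns the
#' class-specific psychosocial profile.  Fully reproducible from the seed.
#' Workers may start hypertensive (baseline blood-pressure distribution);
#' baseline hypertensives face the prescription draw in the first cycle.
#'
#' @param n Cohort size.
#' @param race `"white"` or `"Black"`.
#' @param params A `segsim_params` object.
#' @param allocation Allocation matrix; defaults to the status-quo table in
#'   `params`.
#' @param seed Optional integer seed (set before any draw).
#' @return A data frame with one row per worker.
#' @export
init_cohort <- function(n, race, params, allocation = params$allocation,
                        seed = NULL) {
  stopifnot(is.numeric(n), n >= 1)
  race <- match.arg(race, SEG_RACES)
  if (!is.null(seed)) set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  n <- as.integer(n)
  b <- params$baselines

  gender <- ifelse(stats::runif(n) < b$female_share[[race]], "female", "male")
  keys <- rg_key(race, gender)
  kidx <- match(keys, SEG_RG_KEYS)

  family_history <- stats::runif(n) < b$family_history[[race]]

  lb <- do.call(rbind, b$log_bmi[SEG_RG_KEYS])
  bmi <- exp(stats::rnorm(n, lb[kidx, "meanlog"], lb[kidx, "sdlog"]))

  sm <- do.call(rbind, b$smoking[SEG_RG_KEYS])[, c("current", "former", "never")]
  smoking <- c("current", "former", "never")[
    sample_categorical(sm[kidx, , drop = FALSE], stats::runif(n))]

  active <- stats::runif(n) < unlist(b$active)[SEG_RG_KEYS][kidx]

  bp <- do.call(rbind, b$bp_state[SEG_RG_KEYS])[
    , c("normotensive", "prehypertensive", "hypertensive")]
  state <- c("normotensive", "prehypertensive", "hypertensive")[
    sample_categorical(bp[kidx, , drop = FALSE], stats::runif(n))]

  occupation <- allocate_occupation(race, gender, allocation, n = n)
  pwe <- assign_pwe(occupation, params)

  ep <- employment_probabilities(race, gender, occupation, age = 25,
                                 ever_unemployed = FALSE, params = params)
  employment <- SEG_EMPLOYMENT[sample_categorical(ep, stats::runif(n))]

  data.frame(id = seq_len(n),
             race = race,
             gender = gender,
             age = 25L,
             family_history = family_history,
             bmi = bmi,
             smoking = smoking,
             active = active,
             occupation = occupation,
             employment = employment,
             ever_unemployed = employment == "unemployed",
             pwe,
             state = state,
             on_medication = FALSE,
             adherence = "none",
             stringsAsFactors = FALSE)
}
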