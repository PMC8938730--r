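# Parameter registry: definition, validation, conversion, perturbation and
# file round-tripping of every parameter the simulation consumes.  A
# parameter set is a classed list ("segsim_params") of plain vectors and
# lists so that it serialises losslessly to JSON or YAML.

# ---------------------------------------------------------------------------
# probability / rate conversions

#' Convert a five-year probability to an annual probability (DEALE)
#'
#' Constant-hazard (Declining Exponential Approximation to Life Expectancy)
#' conversion of a probability over a five-year horizon to a one-year
#' probability: the five-year probability is mapped to a constant rate
#' \eqn{r = -\log(1 - p_5)/5} and back, \eqn{p_1 = 1 - e^{-r}}, which is
#' algebraically identical to \eqn{p_1 = 1 - (1 - p_5)^{1/5}}.
#' Compounding the result over five annual cycles reproduces the input.
#'
#' @param p5 Numeric vector of five-year probabilities in `[0, 1)`.
#' @return Annual probabilities of the same length.
#' @examples
#' deale_5yr_to_annual(1 - (1 - 0.1)^5)  # 0.1
#' @export
deale_5yr_to_annual <- function(p5) {
  if (!is.numeric(p5) || any(!is.finite(p5)) || any(p5 < 0) || any(p5 >= 1)) {
    stop("p5 must lie in [0, 1): the constant-hazard rate is infinite at 1",
         call. = FALSE)
  }
  1 - (1 - p5)^(1 / 5)
}

#' Apply a hazard ratio to an annual rate and return an annual probability
#'
#' Multiplies an annual event rate by a hazard ratio on the rate scale and
#' converts to an annual probability, \eqn{1 - e^{-hr \cdot rate}}.
#'
#' @param rate Non-negative annual rate(s).
#' @param hr Non-negative hazard ratio(s).
#' @return Annual probabilities.
#' @export
apply_hazard_ratio <- function(rate, hr) {
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0)) {
    stop("rate must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(hr) || any(!is.finite(hr)) || any(hr < 0)) {
    stop("hr must be a non-negative number", call. = FALSE)
  }
  1 - exp(-hr * rate)
}

# ---------------------------------------------------------------------------
# validation

chk <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

chk_prob <- function(x, what) {
  chk(is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1),
      "probability out of [0, 1] in parameter '", what, "'")
}

chk_simplex <- function(x, what, tol = 1e-9) {
  chk_prob(x, what)
  chk(abs(sum(x) - 1) <= tol,
      "distribution '", what, "' does not sum to 1 (sum = ", sum(x), ")")
}

# Provenance entries required for completeness: one per parameter family in
# the model inventory.
PROVENANCE_KEYS <- c(
  "risk_equation_hypertension", "risk_equation_prehypertension",
  "crude_transitions", "prehyp_to_controlled", "control_by_adherence",
  "prescription", "adherence_init",
  "mortality_cvd", "mortality_non_cvd", "mortality_pregnancy",
  "cvd_hazard_ratio",
  "smoking_transitions", "activity_transitions", "bmi_drift",
  "family_history", "female_share", "smoking_baseline", "bmi_baseline",
  "bp_state_baseline", "activity_baseline", "employment_model",
  "pwe_distributions", "allocation_status_quo", "composition_weights")

#' Validate a parameter set
#'
#' Checks structural completeness and every load-time invariant: probability
#' bounds, simplex sums, the exact eleven-covariate set of both risk
#' equations, the race ordering of prescription probabilities, age-monotone
#' CVD and non-CVD mortality rates, hazard ratios of at least one,
#' allocation rows summing to one within printed rounding, and provenance
#' completeness.
#'
#' @param params A `segsim_params` object.
#' @return `params`, invisibly; otherwise an error naming the offending
#'   parameter.
#' @export
validate_parameters <- function(params) {
  chk(inherits(params, "segsim_params"),
      "not a segsim parameter set; see as_parameter_set()")
  required <- c("risk_equations", "transitions", "mortality", "behavior",
                "employment", "baselines", "pwe", "allocation",
                "composition", "provenance")
  miss <- setdiff(required, names(params))
  chk(length(miss) == 0,
      "parameter set is missing required block(s): ",
      paste(miss, collapse = ", "))

  # risk equations: exactly the eleven named covariates, both equations
  for (nm in c("hypertension_5yr", "prehypertension_5yr")) {
    eq <- params$risk_equations[[nm]]
    chk(!is.null(eq), "missing risk equation '", nm, "'")
    chk(is.numeric(eq$intercept) && length(eq$intercept) == 1,
        "risk equation '", nm, "' needs a scalar intercept")
    chk(setequal(names(eq$coefficients), SEG_COVARIATES) &&
          length(eq$coefficients) == length(SEG_COVARIATES),
        "risk equation '", nm, "' must have exactly the covariates: ",
        paste(SEG_COVARIATES, collapse = ", "))
  }

  tr <- params$transitions
  chk_prob(tr$crude, "transitions$crude")
  chk(setequal(names(tr$crude),
               c("normo_to_prehyp", "normo_to_hyper", "prehyp_to_hyper")),
      "transitions$crude must name normo_to_prehyp, normo_to_hyper, prehyp_to_hyper")
  chk_prob(tr$prehyp_to_controlled, "transitions$prehyp_to_controlled")
  chk_prob(tr$control_by_adherence, "transitions$control_by_adherence")
  chk(setequal(names(tr$control_by_adherence), SEG_ADHERENCE),
      "control_by_adherence must be named high/medium/low")
  chk_prob(tr$prescription, "transitions$prescription")
  chk(setequal(names(tr$prescription), SEG_RACES),
      "prescription must be named by race")
  chk(tr$prescription[["Black"]] >= tr$prescription[["white"]],
      "prescription probability for Black workers must be >= white (structural constraint)")
  chk_simplex(tr$adherence_init, "transitions$adherence_init")
  chk(setequal(names(tr$adherence_init), SEG_ADHERENCE),
      "adherence_init must be named high/medium/low")

  m <- params$mortality
  chk(is.numeric(m$age_breaks) && !is.unsorted(m$age_breaks),
      "mortality$age_breaks must be increasing")
  nb <- length(m$age_breaks)
  for (block in c("cvd", "non_cvd")) {
    chk(setequal(names(m[[block]]), SEG_RG_KEYS),
        "mortality$", block, " must have one rate vector per race x gender")
    for (k in SEG_RG_KEYS) {
      r <- m[[block]][[k]]
      chk(is.numeric(r) && length(r) == nb && all(is.finite(r)) && all(r >= 0),
          "mortality$", block, "$", k, " must be ", nb, " non-negative rates")
      chk(!is.unsorted(r),
          "mortality$", block, "$", k,
          " must be non-decreasing in age (structural constraint)")
    }
  }
  chk(setequal(names(m$pregnancy), SEG_RACES),
      "mortality$pregnancy must be named by race")
  for (k in SEG_RACES) {
    r <- m$pregnancy[[k]]
    chk(is.numeric(r) && length(r) == nb && all(r >= 0),
        "mortality$pregnancy$", k, " must be ", nb, " non-negative rates")
  }
  chk(all(m$hr_cvd_hypertensive >= 1),
      "cvd hazard ratio for hypertensive workers must be >= 1")
  chk(setequal(names(m$hr_cvd_hypertensive), SEG_GENDERS),
      "hr_cvd_hypertensive must be named by gender")

  b <- params$behavior
  for (nm in c("never_to_current", "current_to_former", "former_to_current")) {
    chk_prob(b$smoking[[nm]], paste0("behavior$smoking$", nm))
    chk(length(b$smoking[[nm]]) == length(b$smoking$age_breaks),
        "behavior$smoking$", nm, " must have one probability per age band")
  }
  chk_prob(b$activity, "behavior$activity")
  chk(b$bmi_drift$sd >= 0, "bmi drift noise scale must be >= 0")
  chk(b$bmi_drift$floor > 0, "bmi floor must be positive")

  e <- params$employment
  for (nm in c("intercept_unemployed", "intercept_part_time")) {
    chk(setequal(names(e[[nm]]), SEG_CLASSES),
        "employment$", nm, " must be named by occupational class")
  }
  # stationary class gradient: implied unemployment non-decreasing from
  # health diagnosing professionals to aides
  iu <- e$intercept_unemployed[SEG_CLASSES]
  chk(!is.unsorted(iu + 1e-9),
      "class-level unemployment must be non-decreasing from health_diagnosing to aide")

  bl <- params$baselines
  chk_prob(bl$female_share, "baselines$female_share")
  chk_prob(bl$family_history, "baselines$family_history")
  chk_prob(bl$active, "baselines$active")
  for (k in SEG_RG_KEYS) {
    chk_simplex(bl$smoking[[k]], paste0("baselines$smoking$", k))
    chk(setequal(names(bl$smoking[[k]]), c("current", "former", "never")),
        "baselines$smoking$", k, " must be named current/former/never")
    chk_simplex(bl$bp_state[[k]], paste0("baselines$bp_state$", k))
    chk(setequal(names(bl$bp_state[[k]]),
                 c("normotensive", "prehypertensive", "hypertensive")),
        "baselines$bp_state$", k,
        " must be named normotensive/prehypertensive/hypertensive")
    chk(bl$log_bmi[[k]][["sdlog"]] >= 0, "log-BMI scale must be >= 0")
  }

  for (dim in c("demand", "control", "support")) {
    p <- params$pwe[[dim]]
    chk(setequal(names(p$mean), SEG_CLASSES) && all(p$sd >= 0),
        "pwe$", dim, " must have class-named means and non-negative scales")
  }

  validate_allocation(params$allocation, tol = 0.005)

  co <- params$composition
  chk_prob(unlist(co[c("female_share_overall", "white_share_men",
                       "white_share_women")]), "composition")

  miss_prov <- setdiff(PROVENANCE_KEYS, names(params$provenance))
  chk(length(miss_prov) == 0,
      "provenance entries missing for: ", paste(miss_prov, collapse = ", "))

  invisible(params)
}

# ---------------------------------------------------------------------------
# coercion from plain lists (JSON / YAML) to a typed parameter set

num_vec <- function(x) {
  if (is.list(x)) x <- unlist(x)
  storage.mode(x) <- "double"
  x
}

#' Coerce a plain list to a validated parameter set
#'
#' Rebuilds the typed structure (named numeric vectors, the allocation
#' matrix) from a plain nested list, e.g. one read back from a JSON or YAML
#' parameter file, and validates it.
#'
#' @param x A nested list with the parameter-set blocks.
#' @return A validated `segsim_params` object.
#' @export
as_parameter_set <- function(x) {
  p <- list()
  p$meta <- list(name = if (!is.null(x$meta$name)) x$meta$name else "unnamed")
  p$risk_equations <- lapply(x$risk_equations[c("hypertension_5yr",
                                                "prehypertension_5yr")],
                             function(eq) {
                               list(intercept = as.numeric(eq$intercept),
                                    coefficients = num_vec(eq$coefficients))
                             })
  tr <- x$transitions
  p$transitions <- list(
    use_risk_equations = isTRUE(tr$use_risk_equations),
    crude = num_vec(tr$crude),
    prehyp_to_controlled = as.numeric(tr$prehyp_to_controlled),
    control_by_adherence = num_vec(tr$control_by_adherence),
    prescription = num_vec(tr$prescription),
    adherence_init = num_vec(tr$adherence_init))
  m <- x$mortality
  p$mortality <- list(
    age_breaks = num_vec(m$age_breaks),
    cvd = lapply(m$cvd, num_vec),
    non_cvd = lapply(m$non_cvd, num_vec),
    pregnancy = lapply(m$pregnancy, num_vec),
    hr_cvd_hypertensive = num_vec(m$hr_cvd_hypertensive))
  b <- x$behavior
  p$behavior <- list(
    smoking = list(age_breaks = num_vec(b$smoking$age_breaks),
                   never_to_current = num_vec(b$smoking$never_to_current),
                   current_to_former = num_vec(b$smoking$current_to_former),
                   former_to_current = num_vec(b$smoking$former_to_current)),
    activity = num_vec(b$activity),
    bmi_drift = list(active = as.numeric(b$bmi_drift$active),
                     inactive = as.numeric(b$bmi_drift$inactive),
                     sd = as.numeric(b$bmi_drift$sd),
                     floor = as.numeric(b$bmi_drift$floor)))
  e <- x$employment
  p$employment <- list(
    frozen = isTRUE(e$frozen),
    intercept_unemployed = num_vec(e$intercept_unemployed),
    intercept_part_time = num_vec(e$intercept_part_time),
    slopes_unemployed = num_vec(e$slopes_unemployed),
    slopes_part_time = num_vec(e$slopes_part_time))
  bl <- x$baselines
  p$baselines <- list(
    female_share = num_vec(bl$female_share),
    family_history = num_vec(bl$family_history),
    smoking = lapply(bl$smoking, num_vec),
    log_bmi = lapply(bl$log_bmi, num_vec),
    active = num_vec(bl$active),
    bp_state = lapply(bl$bp_state, num_vec))
  p$pwe <- lapply(x$pwe[c("demand", "control", "support")],
                  function(d) list(mean = num_vec(d$mean), sd = num_vec(d$sd)))
  al <- x$allocation
  if (is.matrix(al)) {
    p$allocation <- al
  } else {
    p$allocation <- do.call(rbind, lapply(al[SEG_RG_KEYS], num_vec))
    colnames(p$allocation) <- SEG_CLASSES
  }
  p$composition <- lapply(x$composition, as.numeric)
  p$provenance <- lapply(x$provenance, as.character)
  class(p) <- "segsim_params"
  validate_parameters(p)
  p
}

# ---------------------------------------------------------------------------
# file i/o

# recursively fill blocks missing from `x` with the default fixture values,
# returning the filled list and the dotted paths that were substituted
fill_defaults <- function(x, def, path = character()) {
  filled <- character()
  for (nm in names(def)) {
    here <- paste(c(path, nm), collapse = "$")
    if (is.null(x[[nm]])) {
      x[[nm]] <- def[[nm]]
      filled <- c(filled, here)
    } else if (is.list(def[[nm]]) && is.list(x[[nm]]) &&
               !is.null(names(def[[nm]]))) {
      res <- fill_defaults(x[[nm]], def[[nm]], c(path, nm))
      x[[nm]] <- res$x
      filled <- c(filled, res$filled)
    }
  }
  list(x = x, filled = filled)
}

#' Load a parameter set from a JSON or YAML file
#'
#' Reads a structured parameter file, fills any missing optional block from
#' the default fixture (with a warning naming the substituted blocks), and
#' validates the result.  The blocks `risk_equations`, `transitions`,
#' `baselines` and `allocation` are required.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` parameter file.
#' @return A validated `segsim_params` object.
#' @seealso [write_parameters()] for the round-trippable writer.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported parameter file extension '.", ext,
                     "' (use .json, .yaml or .yml)", call. = FALSE))
  required <- c("risk_equations", "transitions", "baselines", "allocation")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("parameter file is missing required block(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  res <- fill_defaults(raw, unclass(default_parameter_fixture()))
  if (length(res$filled)) {
    warning("parameter file omitted block(s) filled from the default fixture: ",
            paste(res$filled, collapse = ", "), call. = FALSE)
  }
  as_parameter_set(res$x)
}

#' Write a parameter set to a JSON or YAML file
#'
#' The writer is round-trippable: `load_parameters(write_parameters(p, f))`
#' reproduces `p`.
#'
#' @param params A `segsim_params` object.
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  ser <- unclass(params)
  al <- ser$allocation
  ser$allocation <- stats::setNames(
    lapply(seq_len(nrow(al)), function(i) as.list(al[i, ])), rownames(al))
  # named atomic vectors must become objects, not bare arrays
  to_obj <- function(x) {
    if (is.list(x)) lapply(x, to_obj)
    else if (!is.null(names(x)) && length(x) >= 1) as.list(x)
    else x
  }
  ser <- to_obj(ser)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(ser, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yaml = ,
         yml = yaml::write_yaml(ser, path, precision = 15L),
         stop("unsupported parameter file extension '.", ext, "'",
              call. = FALSE))
  invisible(path)
}

# ---------------------------------------------------------------------------
# sensitivity perturbation

#' Perturb one sensitivity parameter block
#'
#' Returns a deep copy of the parameter set with every probability in the
#' chosen block multiplied by `1 + factor` and clamped to `[0, 1]`; all
#' other parameters are untouched.  The two blocks are the ones varied in
#' the one-way sensitivity analysis: the race-specific probability of being
#' prescribed hypertension medication, and the adherence-level probabilities
#' of moving from the hypertensive to the controlled state.
#'
#' @param params A `segsim_params` object.
#' @param block `"prescription"` or `"control_by_adherence"`.
#' @param factor Relative change, e.g. `0.25` or `-0.25`; must be `>= -1`.
#' @return A new `segsim_params` object; the input is not modified.
#' @export
perturb_parameters <- function(params, block, factor) {
  block <- match.arg(block, c("prescription", "control_by_adherence"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor < -1) {
    stop("factor must be a single number >= -1", call. = FALSE)
  }
  out <- params
  p <- out$transitions[[block]]
  out$transitions[[block]] <- pmin(pmax(p * (1 + factor), 0), 1)
  out
}

# compact digest of the numeric content of a parameter set, echoed in run
# manifests so outputs can be traced back to their inputs
params_digest <- function(params) {
  core <- unclass(params)
  core$provenance <- NULL
  core$meta <- NULL
  v <- unlist(core, use.names = FALSE)
  num <- suppressWarnings(as.numeric(v))
  num <- num[is.finite(num)]
  sprintf("p%04d-%.8e", length(num), sum(num * seq_along(num)))
}
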