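---
title: "Modelling occupational desegregation and hypertension inequity with segsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling occupational desegregation and hypertension inequity with segsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(segsim)
```

## The model

`segsim` implements an individual-level state-transition microsimulation of
hypertension among healthcare workers.  Each simulated worker enters the
model at age 25 — roughly when US workers have attained their terminal
degree and chosen an occupation — and is followed in annual cycles to the
pre-retirement age of 64 through five mutually exclusive health states:

* **normotensive** (SBP < 120 mmHg and DBP < 80 mmHg),
* **prehypertensive** (SBP 120–139 or DBP 80–89 mmHg),
* **hypertensive** (SBP > 140, DBP > 90, or on antihypertensive
  medication),
* **controlled** (hypertensive in an earlier cycle but normotensive now,
  through treatment or behavioral modification), and
* **dead** (absorbing).

The blood-pressure thresholds appear only in documentation: the model
tracks states, not continuous pressures.  Prehypertensive workers cannot
return to the normotensive state, hypertensive workers can leave the state
only to *controlled* (with medication) or *dead*, and controlled workers
face the same onset risks as normotensive workers.

### Onset risk equations

Onset of prehypertension and hypertension is driven by two logistic
regressions on a worker's current covariates, estimated in the source
literature from the CARDIA cohort and shipped here with their published
coefficients (see `default_parameter_fixture()`):

$$\operatorname{logit}(p_5^{\mathrm{hyp}}) = -12.07 + 2.497\,\log\mathrm{BMI}
+ 0.775\,\mathrm{Smoker} + 1.710\,\mathrm{Prehyp} + 0.656\,\mathrm{FamHist}
- 0.059\,\mathrm{FT} - 0.135\,\mathrm{PT} + 0.167\,D - 0.347\,C - 0.160\,S
+ 0.024\,\mathrm{Age} + 0.197\,\mathrm{Women}$$

and analogously for five-year prehypertension risk.  $D$, $C$ and $S$ are
the job demand, job control and workplace support scores of the
psychosocial work environment (PWE) under the Job Demand–Control–Support
model: demand raises risk, control and support lower it.  During
unemployed cycles the *effective* work covariates (the PWE scores and the
full-time/part-time indicators) are zero while the stored profile is
unchanged.  Former smokers count as non-smokers in the equations.  The
`CurrentlyPrehypertensive` covariate of the prehypertension equation is
always evaluated at 0, because that equation is only applied to
normotensive and controlled workers.

Five-year risks are converted to annual probabilities with the
constant-hazard (DEALE) conversion
$p_1 = 1 - (1 - p_5)^{1/5} = 1 - e^{-r}$ with $r = -\log(1 - p_5)/5$
(`deale_5yr_to_annual()`); the two forms are algebraically identical and
the round trip is exact to numerical precision.  We apply the same
exponential rate-to-probability convention uniformly, including to the
mortality rates, which is standard decision-model practice.

A *crude mode* (`transitions$use_risk_equations = FALSE`) replaces the
risk equations with fixed annual transition probabilities.  It exists as a
validation reference and fallback: with behaviors, employment and
mortality frozen, the whole cohort follows a homogeneous five-state Markov
chain, so simulated state occupancy can be checked against a matrix-power
oracle — which the test suite does on several toy parameterisations.

### Treatment dynamics

Hypertensive workers who are not on medication face a race-specific
prescription draw every cycle (the same probability each cycle until
prescribed; Black workers are prescribed at a higher probability than
white workers, as observed in US practice data).  At initiation an
adherence level (high: MPR > 0.80; medium: 0.50–0.79; low: < 0.50) is
drawn once and retained — the source describes an initiation distribution
but no redrawing, and retention is the simpler reading.  Each cycle on
medication, the worker becomes controlled with the adherence-specific
control probability; unmedicated hypertensives have zero probability of
becoming controlled.  Workers stay on medication as long as they remain
hypertensive or controlled; consequently a controlled worker who relapses
to hypertension keeps their medication and faces no new prescription draw.
A controlled worker who slips to the *prehypertensive* state leaves the
treated track (medication and adherence are cleared); if they later become
hypertensive again, a fresh prescription spell starts.  Prehypertensive
workers can also reach the controlled state directly through behavioral
modification (weight loss, DASH-style diet, activity), at a single annual
probability.

### Mortality

Every worker faces CVD and non-CVD mortality rates by race, gender and
10-year age band; hypertensive workers' CVD rate is multiplied by a
gender-specific hazard ratio ($\ge 1$) on the rate scale.  Women
additionally face a pregnancy-related rate (by race and age band).  The
three rates are combined additively on the rate scale, converted once with
$1 - e^{-\mathrm{rate}}$, and resolved with a single death draw per cycle.
Note that the structural requirement that mortality rates be
non-decreasing in age is enforced for the CVD and non-CVD components only:
pregnancy-related rates track fertility and decline with age, so the
fixture leaves them unconstrained.

### Behavior and employment dynamics

Between cycles, smoking moves along an age-banded transition table
(never → current, current ↔ former), physical activity toggles with fixed
probabilities, and BMI drifts upward (+0.10 kg/m²/yr when active, +0.25
when inactive, Gaussian noise SD 0.10, floored at 12 kg/m² to protect the
log transform).  Employment status (full-time / part-time / unemployed)
follows a three-outcome multinomial score on age, gender, race,
unemployment history and occupational class; a first spell of
unemployment permanently flips an `ever_unemployed` scar indicator that
raises future unemployment risk.  The class intercepts are calibrated so
the implied class-level unemployment probabilities reproduce the
published 1%/1%/3%/4% gradient from diagnosing professionals to aides.

### Within-cycle event order

The order is fixed and documented because it changes results slightly:
mortality draw first, then (for survivors) behaviors, employment, and the
blood-pressure/treatment step, with all health-state transitions evaluated
synchronously on the state at the start of the health step; workers become
one year older at the end of the cycle.  Prevalence is tallied after the
cycle's transitions, so cycle $c$ (1-based) reports the cohort at attained
age $24 + c$; age bands are inclusive five-year blocks 25–29 … 60–64.

## Cohorts, occupational allocation, and scenarios

A cohort of 25-year-olds is initialised by random sampling from race ×
gender baseline distributions (gender mix, family history, log-normal
BMI, smoking, activity, baseline blood-pressure state, employment) and
allocated to one of four occupational classes — health diagnosing
professionals, health treating professionals, healthcare technicians,
healthcare aides — from a race × gender allocation probability table.
The status-quo table is the published set of predicted probabilities for
25-year-old healthcare workers; the class is immutable afterwards (no
interclass mobility), and the PWE profile is drawn once at age 25 from
class-specific normal distributions.

The counterfactual scenarios modify only the allocation table:

* **A** removes race: within each gender, rows are replaced by the
  composition-weighted average across races;
* **B** removes race and gender: all rows are the overall weighted
  average;
* **C** gives Black men and women the status-quo white-male and
  white-female rows (white rows untouched);
* **D** gives every group the status-quo white-male row.

The published scenario A/B rows came from multinomial regressions refit
without race (and gender); those coefficients are not published, so
`build_scenario_allocation()` reconstructs A and B by mixture-weight
marginalisation of the printed status-quo rows.  The composition weights
(white share among men 0.813, among women 0.775, female share overall
0.820) were solved analytically from the printed rows and are labelled
fixture-calibrated; the mixture reproduces the published A/B rows within
0.005 per entry, and those published rows are shipped in
`reference_scenario_allocations()` as a cross-check.

`run_experiment()` runs `n_cohorts` independent cohorts per scenario ×
race and averages per-cycle prevalence with unweighted means across
cohorts.  Prevalence is the number of hypertensive workers divided by the
number of alive workers; the controlled state is excluded from the
numerator by default because controlled workers are normotensive in the
current cycle (`include_controlled = TRUE` switches to counting them as
treated hypertension).  With equal cohort sizes, averaging per-cohort
prevalences and pooling workers coincide; we average per-cohort values.

### Common random numbers

Per-cohort sub-seeds depend only on the master seed, the race and the
cohort index — never on the scenario — and within each cycle every random
vector is drawn for the full cohort in a fixed order, so each worker
consumes the same stream positions in every scenario.  Scenario contrasts
are therefore paired: the white workforce under scenario C (whose
allocation rows are unchanged) is *bit-identical* to the status quo, which
the tests assert exactly, and status-quo-vs-D contrasts have markedly
lower Monte-Carlo variance than independent-seed runs.

### Sensitivity analysis

Because the simulated individuals are synthetic, standard errors and
significance tests are not meaningful; `run_sensitivity()` instead reruns
the full experiment with each of the two treatment blocks — the
race-specific prescription probabilities and the adherence-level control
probabilities — separately scaled by ±25% (`perturb_parameters()`, with
clamping at 1 so the +25% arm cannot produce an invalid probability).
The reported interval is the minimum and maximum of the career-average
prevalence across the base and the two arms, so it always contains the
base value, and both arms are reported separately.

## The synthetic parameter fixtures

The source parameter set was estimated from restricted data (CARDIA,
NHANES 1999–2018, NHIS 2000–2018, ACS 2012–2017 linked with O*NET) and
published clinical studies; none of those microdata ship with this
package, and re-estimating any parameter from them is out of scope.  The
fixture module instead emulates the *structure* of that parameter set:

* printed quantities — the two risk equations, the status-quo allocation
  rows, the 1%/1%/3%/4% unemployment gradient used for calibration — are
  embedded exactly;
* everything else is a fixture default chosen once on domain grounds and
  tagged `"fixture"` in the mandatory provenance map, so fixture values
  can never be mistaken for published ones.

Notable fixture choices: PWE scores are modelled as class-specific
normals on a standardized scale (SD 0.8) with means chosen so control and
support decline, and the implied iso-strain index (joint probability of
high demand, low control, low support) rises, from diagnosing
professionals to aides, and so the risk-equation linear predictor spans a
plausible range (about 0.8 logits between the top and bottom class); the
empirical score distributions in the source's supplements are
unavailable, and the standardized scale is an explicit stand-in.
Baseline blood-pressure distributions put 3–6% of 25-year-olds in the
hypertensive state with a substantial prehypertensive pool (21–39%,
higher for men and for Black workers); annual treatment parameters
(prescription 0.34 white / 0.40 Black; control 0.30/0.18/0.08 by
adherence; initiation mix 0.52/0.26/0.22) are fixture stand-ins on the
annual-transition scale.  BMI drift defaults stand in for unavailable
supplementary material.  The healthcare workforce is majority-female
(female share 0.813 white, 0.846 Black, consistent with the calibrated
composition weights).

`randomized_parameter_fixture()` jitters the fixture reproducibly while
preserving the structural constraints, and exposes two null dials used by
the tests: `race_effect = 0` makes every parameter race-invariant and
`gradient_strength = 0` removes all class gradients, which together make
the population exchangeable — under scenario B the Black–white gap must
then vanish within Monte-Carlo error.  `toy_parameter_fixture()` produces
degenerate sets (zero mortality, frozen behaviors/employment, crude
transitions, point-mass PWE) for the oracle tests.

Because the fixture is synthetic, simulated prevalence *levels* are not
estimates of US healthcare-worker hypertension; what the model
reproduces, and what the tests check, are the structural contrasts: a
positive Black–white gap under the status quo, gap narrowing under every
desegregation scenario, an unchanged white workforce under C, improvement
for both workforces under D, redistribution costs for the white workforce
under A/B, prevalence non-decreasing with age, and sensitivity intervals
bracketing the base case.  Real data also contain features the generator
does not emulate — measured blood-pressure dynamics, education/income/
seniority effects, workplace discrimination and tokenism stressors,
secular trends — so passing tests demonstrate internal validity of the
mechanism, not calibration to any surveyed population.

## Numerical choices and degenerate inputs

* Printed allocation rows carry rounding (sums 0.999–1.000); they are
  used as printed, residual categorical mass falls in the last class, and
  row sums are validated within 0.005 (tables built from exact rows are
  validated to 1e-9).
* Probabilities are validated to [0, 1], categorical distributions to
  simplex sums within 1e-9; perturbed probabilities are clamped at 1.
* `deale_5yr_to_annual(1)` is a domain error (infinite rate), as are
  negative rates, BMIs ≤ 0, and risk evaluation on dead workers.
* Cycles with zero alive workers raise an explicit error rather than a
  silent `NaN` prevalence.
* Seeds are reduced modulo 2^31 − 1; all sub-seed hashing stays within
  32-bit integer range.

## Problem sizes

The full-scale design (500 cohorts of 100,000 workers per race) is the
`experiment_config()` default.  The shipped tests and the acceptance
script use desk-scale designs chosen to keep Monte-Carlo error well below
the contrasts they check: 10 cohorts × 10,000 workers per race for the
scenario experiment, 5 × 5,000 for the sensitivity reruns, 4,000-worker
cohorts for the Markov oracle, and 6 × 4,000 for the exchangeability
null.

```{r, eval = FALSE}
params <- default_parameter_fixture()
cfg <- experiment_config(n_cohorts = 10, cohort_size = 10000, seed = 1)
experiment <- run_experiment(cfg, params)
career_averages(experiment)
sens <- run_sensitivity(cfg, params)
write_report(experiment, sensitivity = sens, dir = "results")
```

## Known limitations

The model simplifies a far more complex social process.  It omits
continuous blood-pressure tracking, interclass mobility, education,
income and seniority effects, and the stressors prevalent among
high-status workers of color (hiring and workplace discrimination,
tokenism, John Henryism, work–home interference).  Scenario A/B rows are
mixture marginalisations rather than refit regressions and differ from
the published rows by up to 0.005.  Whether prehypertensive workers
should also face the prehypertension equation, and whether baseline
hypertensives' prescription probability differs from incident cases, are
unresolved in the source; the package applies the explicit rules
described above (prehypertensive workers face only the hypertension
equation; one prescription probability for all hypertensives).
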