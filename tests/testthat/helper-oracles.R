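# Shared helpers: hand-built workers, homogeneous-cohort Markov oracle.

# a single worker row with sensible defaults, overridable field by field
make_worker <- function(...) {
  w <- data.frame(id = 1L, race = "white", gender = "male", age = 25L,
                  family_history = FALSE, bmi = 27, smoking = "never",
                  active = TRUE, occupation = "health_treating",
                  employment = "full_time", ever_unemployed = FALSE,
                  pwe_demand = 0, pwe_control = 0, pwe_support = 0,
                  state = "normotensive", on_medication = FALSE,
                  adherence = "none", stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) w[[nm]] <- dots[[nm]]
  w
}

# 5x5 one-cycle transition matrix (states N, P, H, C, D) for a homogeneous
# cohort under crude-probability toy parameters.  The death draw happens
# first; survivors then move by the crude probabilities with the engine's
# composition rule (hypertension draw first, then the secondary draw).
# Valid for prescription probability rx in {0, 1} and a single control
# probability q (memoryless treatment).
markov_oracle_matrix <- function(p_np, p_nh, p_ph, p_pc, rx, q, d_rate = 0) {
  stopifnot(rx %in% c(0, 1))
  q_eff <- rx * q
  T <- rbind(
    N = c((1 - p_nh) * (1 - p_np), (1 - p_nh) * p_np, p_nh, 0, 0),
    P = c(0, (1 - p_ph) * (1 - p_pc), p_ph, (1 - p_ph) * p_pc, 0),
    H = c(0, 0, 1 - q_eff, q_eff, 0),
    C = c(0, (1 - p_nh) * p_np, p_nh, (1 - p_nh) * (1 - p_np), 0),
    D = c(0, 0, 0, 0, 1))
  pd <- 1 - exp(-d_rate)
  M <- (1 - pd) * T
  M[, 5] <- M[, 5] + pd
  M["D", ] <- c(0, 0, 0, 0, 1)
  colnames(M) <- rownames(M)
  M
}

# matrix-power state distribution after n cycles from a baseline
# (N, P, H) distribution
markov_oracle_dist <- function(M, bp, n_cycles) {
  v <- c(bp[1], bp[2], bp[3], 0, 0)
  for (i in seq_len(n_cycles)) v <- drop(v %*% M)
  v
}

# small experiment config used by several tests
tiny_config <- function(...) {
  experiment_config(n_cohorts = 2, cohort_size = 1000, seed = 11,
                    scenarios = c("status_quo", "C"), ...)
}
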