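# shared fixtures, all generated in code (no stored data files)

sim_session <- function(params = agent_params(), config = task_config(),
                        seed = 1, missing_rate = 0) {
  run_session(make_agent(params, p_common = config$p_common), config,
              missing_rate = missing_rate, seed = seed)
}

# hand-enumerated 12-trial table; expected cell tallies counted manually:
#   com+ 1/2, rar+ 2/2, com- 1/3, rar- 1/2   (pair 4-5 and 5-6 dropped: t5 missing)
hand_trials_12 <- function() {
  df <- data.frame(
    trial = 0:11,
    choice1    = c(0L, 0L, 1L, 1L, 0L, NA, 1L, 1L, 0L, 0L, 1L, 1L),
    state2     = c(0L, 0L, 0L, 1L, 1L, NA, 0L, 1L, 1L, 1L, 1L, 1L),
    choice2    = c(0L, 1L, 0L, 0L, 1L, NA, 0L, 1L, 0L, 1L, 0L, 0L),
    transition = c("common", "common", "rare", "common", "rare", NA,
                   "rare", "common", "rare", "rare", "common", "common"),
    reward     = c(1L, 0L, 1L, 0L, 0L, NA, 0L, 1L, 1L, 0L, 0L, 1L),
    missing    = c(rep(FALSE, 5), TRUE, rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )
  df
}

# a stay_table object with chosen cell probabilities (counts immaterial)
fake_stay_table <- function(p_com_plus, p_rar_plus, p_com_minus, p_rar_minus) {
  structure(list(p_com_plus = p_com_plus, p_rar_plus = p_rar_plus,
                 p_com_minus = p_com_minus, p_rar_minus = p_rar_minus,
                 n_cell = c(com_plus = 10L, rar_plus = 10L,
                            com_minus = 10L, rar_minus = 10L),
                 flagged = character(),
                 mf_effect = (p_com_plus + p_rar_plus -
                                p_com_minus - p_rar_minus) / 2,
                 mb_effect = (p_com_plus - p_rar_plus -
                                p_com_minus + p_rar_minus) / 2),
            class = "stay_table")
}

random_params <- function() {
  agent_params(beta1 = rlnorm(1, log(3), 0.5), beta2 = rlnorm(1, log(3), 0.5),
               alpha1 = runif(1, 0.05, 0.95), alpha2 = runif(1, 0.05, 0.95),
               lam = runif(1, 0.05, 0.95), omega = runif(1, 0.05, 0.95),
               pi = rnorm(1, 0.2, 0.3))
}

# tiny cohort for pipeline tests
small_cohort <- function(n_subjects = 3, n_trials = 60, seed = 11, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects, ...),
                  task_config(n_trials = n_trials), seed = seed)
}
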