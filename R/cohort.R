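#' Describe a synthetic cross-over cohort
#'
#' Specifies a cohort emulating the study design: `n_subjects` participants,
#' each completing one session per tryptophan intervention (depletion ATD,
#' balanced BAL, loading ATL) in randomized order, with subject-level
#' heterogeneity in the seven agent parameters, random trial missingness, and
#' four-timepoint blood tryptophan/LNAA-ratio curves per session.
#'
#' The omega prior is centred on the study's reported group mean (0.41,
#' SD 0.29), truncated to \[0, 1\]. The study prints no distributional
#' summaries for the other parameters; their priors are field conventions
#' (uniform learning rates and eligibility, log-normal inverse temperatures
#' around 3, mildly positive perseveration) documented in the package
#' vignette.
#'
#' @param n_subjects Number of subjects (default 98, the study's sample).
#' @param interventions Ordered intervention labels.
#' @param order_randomized Permute session order per subject (cross-over)?
#' @param param_prior Named list of zero-argument-style sampler functions,
#'   one per agent parameter, each taking `n` and returning `n` draws on the
#'   natural scale. Override entries to pin parameters in tests.
#' @param effect_spec Named list mapping an intervention label to a named
#'   numeric vector of additive shifts applied to that session's parameters
#'   on the unconstrained scale (logit for the \[0,1\] parameters, log for
#'   the betas, identity for pi), so shifted draws never leave the domain.
#'   The default (empty) is the null world: no intervention effect.
#' @param missing_rate_alpha,missing_rate_beta Shape parameters of the Beta
#'   distribution of each subject's per-trial missingness probability
#'   (defaults give mean ~3%, far below the 30% exclusion threshold).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 98L,
                        interventions = c("ATD", "BAL", "ATL"),
                        order_randomized = TRUE,
                        param_prior = default_param_prior(),
                        effect_spec = list(),
                        missing_rate_alpha = 1.5,
                        missing_rate_beta = 48.5) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 1L, length(interventions) >= 2L,
            !anyDuplicated(interventions))
  if (length(effect_spec) > 0) {
    stopifnot(!is.null(names(effect_spec)),
              all(names(effect_spec) %in% interventions))
    for (ef in effect_spec)
      stopifnot(all(names(ef) %in% param_names))
  }
  structure(list(n_subjects = n_subjects, interventions = interventions,
                 order_randomized = order_randomized,
                 param_prior = param_prior, effect_spec = effect_spec,
                 missing_rate_alpha = missing_rate_alpha,
                 missing_rate_beta = missing_rate_beta),
            class = "cohort_spec")
}

#' Default subject-level parameter priors
#'
#' @return Named list of sampler functions `function(n)`.
#' @export
default_param_prior <- function() {
  list(
    beta1 = function(n) stats::rlnorm(n, log(3), 0.5),
    beta2 = function(n) stats::rlnorm(n, log(3), 0.5),
    alpha1 = function(n) stats::runif(n),
    alpha2 = function(n) stats::runif(n),
    lam = function(n) stats::runif(n),
    omega = function(n) rtruncnorm01(n, 0.41, 0.29),
    pi = function(n) stats::rnorm(n, 0.2, 0.2)
  )
}

# Truncated-normal draws on [0, 1] by inverse-CDF (exact, no rejection).
rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd); hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Draw one subject's agent parameters from the cohort prior
#'
#' @param spec A [cohort_spec()].
#' @return An [agent_params()].
#' @export
draw_subject_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  draws <- lapply(spec$param_prior[param_names], function(f) f(1))
  # guard conventions: priors are responsible for their own domains, but a
  # user-supplied prior straying outside is truncated with a message
  clamp <- function(x, lo, hi, nm) {
    if (x < lo || x > hi) {
      message("prior draw for ", nm, " truncated into [", lo, ", ", hi, "]")
      x <- min(max(x, lo), hi)
    }
    x
  }
  agent_params(beta1 = max(draws$beta1, 0), beta2 = max(draws$beta2, 0),
               alpha1 = clamp(draws$alpha1, 0, 1, "alpha1"),
               alpha2 = clamp(draws$alpha2, 0, 1, "alpha2"),
               lam = clamp(draws$lam, 0, 1, "lam"),
               omega = clamp(draws$omega, 0, 1, "omega"),
               pi = draws$pi)
}

# apply an unconstrained-scale shift to a subject's parameters
shift_params <- function(params, shift) {
  if (length(shift) == 0) return(params)
  u <- untransform_safe(params)
  u[names(shift)] <- u[names(shift)] + shift
  transform_params(unname(u[param_names]))
}

# untransform with interior nudge so boundary prior draws (e.g. uniform
# alphas near 0/1 after clamping) stay mappable
untransform_safe <- function(params) {
  eps <- 1e-9
  p <- unlist(params[param_names])
  p[c("alpha1", "alpha2", "lam", "omega")] <-
    pmin(pmax(p[c("alpha1", "alpha2", "lam", "omega")], eps), 1 - eps)
  p[c("beta1", "beta2")] <- pmax(p[c("beta1", "beta2")], eps)
  stats::setNames(c(log(p[["beta1"]]), log(p[["beta2"]]),
                    stats::qlogis(p[["alpha1"]]), stats::qlogis(p[["alpha2"]]),
                    stats::qlogis(p[["lam"]]), stats::qlogis(p[["omega"]]),
                    p[["pi"]]), param_names)
}

# Blood tryptophan/LNAA-ratio template curves, relative to T0, at
# timepoints 0, 1, 3 and 6.5 h. Loading peaks at 3 h, depletion bottoms out
# at 3 h, balanced stays near baseline. Synthetic stand-ins for the study's
# (supplement-only) pharmacokinetic curves, not measured values.
blood_templates <- list(
  ATD = c(1.0, 0.60, 0.30, 0.50),
  BAL = c(1.0, 1.00, 1.00, 1.00),
  ATL = c(1.0, 2.20, 3.50, 2.80)
)

#' Blood sampling timepoints (hours)
#'
#' T0 immediately before the amino-acid drink, then 1, 3 and 6.5 hours after.
#' @export
blood_timepoints <- c(0, 1, 3, 6.5)

# one subject-session blood series: subject baseline ratio times template,
# with multiplicative log-normal noise (CV ~ cv)
sample_blood_series <- function(intervention, baseline_ratio, cv = 0.10) {
  template <- blood_templates[[intervention]]
  if (is.null(template)) template <- c(1, 1, 1, 1)
  sdlog <- sqrt(log(1 + cv^2))
  baseline_ratio * template * stats::rlnorm(4, -sdlog^2 / 2, sdlog)
}

#' Generate a full synthetic cohort
#'
#' For each subject: one base parameter draw from the prior; per intervention
#' the `effect_spec` shift applied on the unconstrained scale; one session of
#' `task$n_trials` trials simulated per intervention with the subject's
#' missingness rate; and a four-timepoint blood tryptophan/LNAA-ratio series
#' per session. Session order is permuted per subject when
#' `spec$order_randomized` is set.
#'
#' @param spec A [cohort_spec()].
#' @param task A [task_config()].
#' @param seed Integer seed controlling the whole cohort.
#' @return List of class `cohort_data` with `trials` (one row per trial:
#'   subject_id, intervention, session_order, trial, choice1, state2,
#'   choice2, transition, reward, missing), `true_params` (one row per
#'   subject-session with the realized parameters and missing rate), `blood`
#'   (subject_id, intervention, t0..t3) and `manifest` (spec + seed echo).
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 2), task_config(), seed = 1)
#' table(co$trials$intervention)
#' @export
generate_cohort <- function(spec = cohort_spec(), task = task_config(),
                            seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(task, "task_config"))
  set.seed(seed)
  trial_list <- list(); param_list <- list(); blood_list <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%03d", s)
    base <- draw_subject_params(spec)
    miss_rate <- stats::rbeta(1, spec$missing_rate_alpha, spec$missing_rate_beta)
    baseline_ratio <- stats::rlnorm(1, log(0.10), 0.15)
    order_idx <- if (spec$order_randomized)
      sample(seq_along(spec$interventions)) else seq_along(spec$interventions)
    for (k in seq_along(spec$interventions)) {
      iv <- spec$interventions[k]
      pars <- shift_params(base, spec$effect_spec[[iv]])
      agent <- make_agent(pars, p_common = task$p_common)
      tab <- run_session(agent, task, missing_rate = miss_rate, seed = NULL)
      tab$reward_prob_used <- NULL
      trial_list[[length(trial_list) + 1L]] <-
        cbind(data.frame(subject_id = sid, intervention = iv,
                         session_order = order_idx[k],
                         stringsAsFactors = FALSE), tab)
      param_list[[length(param_list) + 1L]] <-
        data.frame(subject_id = sid, intervention = iv,
                   as.list(unlist(pars[param_names])),
                   missing_rate = miss_rate, stringsAsFactors = FALSE)
      blood_list[[length(blood_list) + 1L]] <- cbind(
        data.frame(subject_id = sid, intervention = iv,
                   stringsAsFactors = FALSE),
        stats::setNames(as.data.frame(t(sample_blood_series(iv, baseline_ratio))),
                        c("t0", "t1", "t2", "t3")))
    }
  }
  trials <- do.call(rbind, trial_list)
  # column order per the TSV contract
  trials <- trials[, c("subject_id", "intervention", "session_order", "trial",
                       "choice1", "state2", "choice2", "transition", "reward",
                       "missing")]
  structure(list(trials = trials,
                 true_params = do.call(rbind, param_list),
                 blood = do.call(rbind, blood_list),
                 manifest = list(seed = seed,
                                 n_subjects = spec$n_subjects,
                                 interventions = spec$interventions,
                                 order_randomized = spec$order_randomized,
                                 effect_spec = spec$effect_spec,
                                 missing_rate_alpha = spec$missing_rate_alpha,
                                 missing_rate_beta = spec$missing_rate_beta,
                                 task = unclass(task))),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d interventions, %d trials total\n",
              length(unique(x$trials$subject_id)),
              length(unique(x$trials$intervention)), nrow(x$trials)))
  invisible(x)
}
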