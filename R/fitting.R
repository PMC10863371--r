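#' Session negative log-likelihood of the hybrid model
#'
#' Sums `-log P(choice1) - log P(choice2)` over the non-missing trials of one
#' session, with the learner state evolved by the SARSA update after each
#' non-missing trial. Missing trials contribute nothing and freeze the state.
#'
#' @param params An [agent_params()].
#' @param trials A single-session trial table as returned by [run_session()].
#' @param q_init Initial action value.
#' @param p_common Common-transition probability the model assumes.
#' @return Non-negative scalar.
#' @examples
#' tab <- run_session(make_agent(agent_params()), task_config(), seed = 1)
#' session_negll(agent_params(), tab)
#' @export
session_negll <- function(params, trials, q_init = 0.5, p_common = 0.7) {
  stopifnot(inherits(params, "agent_params"))
  trials <- validate_trials(trials)
  .negll_cpp(unlist(params[param_names]),
             as.integer(trials$choice1), as.integer(trials$state2),
             as.integer(trials$choice2), as.integer(trials$reward),
             as.logical(trials$missing), q_init, p_common)
}

#' Reference (oracle) negative log-likelihood
#'
#' A deliberately literal trial-by-trial R re-implementation built from the
#' exported single-step primitives ([stage1_choice_probs()],
#' [stage2_choice_probs()], [update_mf()]). Used by the test suite to verify
#' the compiled likelihood to 1e-10; not meant for production fitting.
#'
#' @inheritParams session_negll
#' @return Non-negative scalar.
#' @export
session_negll_ref <- function(params, trials, q_init = 0.5, p_common = 0.7) {
  trials <- validate_trials(trials)
  qs <- q_state(q_init)
  nll <- 0
  for (t in seq_len(nrow(trials))) {
    if (isTRUE(trials$missing[t])) next
    c1 <- trials$choice1[t]; s2 <- trials$state2[t]
    c2 <- trials$choice2[t]; r <- trials$reward[t]
    p1 <- stage1_choice_probs(qs, params, p_common)
    p2 <- stage2_choice_probs(qs, s2, params)
    nll <- nll - log(p1[c1 + 1L]) - log(p2[c2 + 1L])
    qs <- update_mf(qs, c1, s2, c2, r, params)
  }
  nll
}

validate_trials <- function(trials) {
  need <- c("choice1", "state2", "choice2", "reward", "missing")
  if (!all(need %in% names(trials)))
    stop("trial table lacks required columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  if (nrow(trials) == 0L || all(trials$missing))
    stop("no likelihood-bearing trials")
  # C++ cannot take NA; missing rows are skipped, placeholders are inert
  for (col in c("choice1", "state2", "choice2", "reward"))
    trials[[col]][trials$missing] <- 0L
  trials
}

#' Map an unconstrained 7-vector to legal agent parameters (and back)
#'
#' The optimizer searches an unconstrained space: a logistic map produces the
#' \[0, 1\] parameters (alpha1, alpha2, lam, omega), an exponential the
#' non-negative inverse temperatures, and the perseveration pi passes through
#' unchanged. Components with `|u| > 50` are clamped (with a warning) to keep
#' the maps finite. The inverse is exact on the open domain; boundary values
#' (alpha of exactly 0 or 1, beta of 0) have no finite preimage and raise.
#'
#' @param u Unconstrained numeric 7-vector, ordered
#'   (beta1, beta2, alpha1, alpha2, lam, omega, pi).
#' @return [transform_params()]: an [agent_params()];
#'   [untransform_params()]: an unconstrained 7-vector.
#' @export
transform_params <- function(u) {
  stopifnot(length(u) == 7L, all(is.finite(u)))
  if (any(abs(u) > 50)) {
    warning("unconstrained parameters clamped to [-50, 50]")
    u <- pmin(pmax(u, -50), 50)
  }
  agent_params(beta1 = exp(u[1]), beta2 = exp(u[2]),
               alpha1 = stats::plogis(u[3]), alpha2 = stats::plogis(u[4]),
               lam = stats::plogis(u[5]), omega = stats::plogis(u[6]),
               pi = u[7])
}

#' @rdname transform_params
#' @param params An [agent_params()].
#' @export
untransform_params <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  bounded <- unlist(params[c("alpha1", "alpha2", "lam", "omega")])
  if (any(bounded <= 0) || any(bounded >= 1) || params$beta1 <= 0 ||
      params$beta2 <= 0)
    stop("boundary parameter values have no finite unconstrained preimage")
  c(log(params$beta1), log(params$beta2),
    stats::qlogis(bounded), params$pi)
}

# quiet variant used inside the optimizer objective
transform_quiet <- function(u) {
  u <- pmin(pmax(u, -50), 50)
  list(beta1 = exp(u[1]), beta2 = exp(u[2]),
       alpha1 = stats::plogis(u[3]), alpha2 = stats::plogis(u[4]),
       lam = stats::plogis(u[5]), omega = stats::plogis(u[6]), pi = u[7])
}

#' Maximum-likelihood fit of one subject-session
#'
#' Multi-start quasi-Newton (L-BFGS-B) minimization of [session_negll()] over
#' the unconstrained parameter space; starts are standard-normal draws (the
#' first start is the origin, i.e. alphas/lambda/omega at 0.5, betas at 1,
#' pi at 0) and the best of `n_restarts` is returned. Deterministic given
#' `seed`.
#'
#' The search is boxed to `|u| <= box` on the unconstrained scale. Maximum
#' likelihood for this model has flat directions (e.g. the inverse
#' temperature is unidentified when a learning rate collapses to zero) along
#' which unboxed estimates diverge; the default box of 6.9 caps the betas at
#' about 1000 and the logit-scaled parameters at about 0.001/0.999 —
#' generous for behavioural data — while keeping estimates finite.
#'
#' @param trials Single-session trial table.
#' @param n_restarts Number of optimizer starts.
#' @param seed Integer seed for the start draws.
#' @param q_init,p_common Model constants, see [session_negll()].
#' @param maxit Maximum optimizer iterations per start.
#' @param box Half-width of the unconstrained-scale search box.
#' @return A `fit_result`: list with `params_hat` ([agent_params()]),
#'   `neg_log_lik`, `n_restarts`, `converged`, `best_start_index`,
#'   `n_trials_used`, `degenerate` (fewer than 30 usable trials).
#' @export
fit_subject_session <- function(trials, n_restarts = 10, seed = NULL,
                                q_init = 0.5, p_common = 0.7,
                                maxit = 500, box = 6.9) {
  trials <- validate_trials(trials)
  n_used <- sum(!trials$missing)
  degenerate <- n_used < 30L
  if (degenerate)
    warning("fewer than 30 non-missing trials; fit flagged degenerate")
  if (!is.null(seed)) set.seed(seed)

  c1 <- as.integer(trials$choice1); s2 <- as.integer(trials$state2)
  c2 <- as.integer(trials$choice2); rw <- as.integer(trials$reward)
  ms <- as.logical(trials$missing)
  obj <- function(u) {
    th <- transform_quiet(u)
    .negll_cpp(unlist(th), c1, s2, c2, rw, ms, q_init, p_common)
  }

  starts <- vector("list", n_restarts)
  starts[[1]] <- rep(0, 7)
  if (n_restarts > 1)
    for (i in 2:n_restarts)
      starts[[i]] <- pmin(pmax(stats::rnorm(7), -box), box)

  best <- NULL; best_i <- NA_integer_; any_conv <- FALSE
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[[i]], obj, method = "L-BFGS-B",
                   lower = rep(-box, 7), upper = rep(box, 7),
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$convergence == 0L
    any_conv <- any_conv || conv
    if (is.null(best) || fit$value < best$value) { best <- fit; best_i <- i }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (!any_conv)
    warning("no optimizer start reported convergence; returning best value")

  structure(list(
    params_hat = transform_params(best$par),
    neg_log_lik = best$value,
    n_restarts = n_restarts,
    converged = any_conv,
    best_start_index = best_i,
    n_trials_used = n_used,
    degenerate = degenerate
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Hybrid-model ML fit: negLL = %.3f over %d trials (%s)\n",
              x$neg_log_lik, x$n_trials_used,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params_hat)
  invisible(x)
}

#' Fit every subject-session of a cohort trial table
#'
#' @param trials Cohort trial table with `subject_id` and `intervention`
#'   columns (the `trials.tsv` dialect).
#' @param n_restarts,q_init,p_common,maxit,box Passed to
#'   [fit_subject_session()].
#' @param seed Base seed; each session gets a distinct derived seed.
#' @return A `data.frame`: subject_id, intervention, the seven parameters,
#'   negll, converged, n_restarts, n_trials_used.
#' @export
fit_cohort <- function(trials, n_restarts = 10, seed = 1, q_init = 0.5,
                       p_common = 0.7, maxit = 500, box = 6.9) {
  keys <- unique(trials[, c("subject_id", "intervention")])
  keys <- keys[order(keys$subject_id, keys$intervention), , drop = FALSE]
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- trials[trials$subject_id == keys$subject_id[i] &
                    trials$intervention == keys$intervention[i], , drop = FALSE]
    f <- fit_subject_session(sub, n_restarts = n_restarts,
                             seed = (seed + i * 1009L) %% .Machine$integer.max,
                             q_init = q_init, p_common = p_common,
                             maxit = maxit, box = box)
    rows[[i]] <- data.frame(subject_id = keys$subject_id[i],
                            intervention = keys$intervention[i],
                            as.list(unlist(f$params_hat[param_names])),
                            negll = f$neg_log_lik, converged = f$converged,
                            n_restarts = f$n_restarts,
                            n_trials_used = f$n_trials_used,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate-and-refit identifiability audit
#'
#' Draws subjects from the cohort prior, simulates their sessions, fits every
#' session by maximum likelihood, and tabulates truth against estimate per
#' parameter: Pearson correlation, bias (mean estimate minus truth) and RMSE.
#' Subject-level estimates average the subject's per-session fits.
#'
#' @param spec A [cohort_spec()] (its `n_subjects` sets the audit size).
#' @param task A [task_config()].
#' @param n_restarts Optimizer restarts per session.
#' @param seed Integer seed for the whole audit.
#' @return A `recovery_report`: list with `summary` (one row per parameter:
#'   r, bias, rmse, n) and `estimates` (subject-level truth and estimate).
#' @export
recovery_study <- function(spec = cohort_spec(n_subjects = 50), task = task_config(),
                           n_restarts = 10, seed = 1) {
  cohort <- generate_cohort(spec, task, seed = seed)
  fits <- fit_cohort(cohort$trials, n_restarts = n_restarts, seed = seed + 1L)
  est <- stats::aggregate(fits[param_names], by = list(subject_id = fits$subject_id),
                          FUN = mean)
  truth <- cohort$true_params[match(est$subject_id, cohort$true_params$subject_id),
                              param_names]
  summ <- do.call(rbind, lapply(param_names, function(nm) {
    tr <- truth[[nm]]; ha <- est[[nm]]
    data.frame(parameter = nm,
               r = if (stats::sd(tr) > 0 && stats::sd(ha) > 0)
                 stats::cor(tr, ha) else NA_real_,
               bias = mean(ha - tr),
               rmse = sqrt(mean((ha - tr)^2)),
               n = length(tr), stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ,
                 estimates = data.frame(subject_id = est$subject_id,
                                        truth, stats::setNames(est[param_names],
                                                               paste0(param_names, "_hat"))),
                 fits = fits),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery (simulate -> ML refit)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
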