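#' The seven parameters of the hybrid model-free/model-based agent
#'
#' The hybrid reinforcement-learning account of two-stage task behaviour mixes
#' a model-free SARSA temporal-difference learner with a model-based planner
#' that uses the task's transition structure. Seven parameters govern it: the
#' source study names the mixing weight omega, the stage-skipping eligibility
#' lambda, the perseveration bias pi, and one learning rate alpha per stage;
#' the remaining two (to reach the stated seven) are the stage-specific
#' softmax inverse temperatures of the canonical model this family derives
#' from.
#'
#' @param beta1 Non-negative first-stage inverse temperature.
#' @param beta2 Non-negative second-stage inverse temperature.
#' @param alpha1 First-stage learning rate in \[0, 1\].
#' @param alpha2 Second-stage learning rate in \[0, 1\].
#' @param lam Stage-skipping eligibility weight in \[0, 1\]: how strongly the
#'   second-stage reward prediction error also updates the first-stage value.
#' @param omega Model-based weight in \[0, 1\]: 0 is pure model-free control,
#'   1 pure model-based control.
#' @param pi Perseveration strength (any real): bias toward repeating the
#'   previous first-stage choice irrespective of value. The repetition
#'   indicator is 0/1 (a +/-0.5 coding would only re-scale pi).
#' @return An object of class `agent_params` (a named numeric list).
#' @examples
#' agent_params(omega = 0.41)
#' @export
agent_params <- function(beta1 = 3, beta2 = 3, alpha1 = 0.5, alpha2 = 0.5,
                         lam = 0.5, omega = 0.5, pi = 0.2) {
  p <- stats::setNames(as.numeric(c(beta1, beta2, alpha1, alpha2,
                                    lam, omega, pi)),
                       c("beta1", "beta2", "alpha1", "alpha2",
                         "lam", "omega", "pi"))
  if (any(!is.finite(p))) stop("all parameters must be finite")
  if (beta1 < 0 || beta2 < 0) stop("inverse temperatures must be >= 0")
  for (nm in c("alpha1", "alpha2", "lam", "omega"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  structure(as.list(p), class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Hybrid agent parameters\n")
  cat(sprintf("  beta1 = %.3f  beta2 = %.3f\n", x$beta1, x$beta2))
  cat(sprintf("  alpha1 = %.3f  alpha2 = %.3f  lambda = %.3f\n",
              x$alpha1, x$alpha2, x$lam))
  cat(sprintf("  omega = %.3f  pi = %.3f\n", x$omega, x$pi))
  invisible(x)
}

param_names <- c("beta1", "beta2", "alpha1", "alpha2", "lam", "omega", "pi")

#' Fresh learner state
#'
#' Model-free first-stage values and the 2x2 second-stage action values all
#' start at `q_init`; no previous choice is recorded. The default `q_init` of
#' 0.5 is the midpoint of the 0.25-0.75 reward-probability range.
#'
#' @param q_init Initial action value.
#' @return A list with `q_mf1` (length-2), `q2` (2x2 matrix, state x action),
#'   and `prev_choice1` (`NA` before the first trial).
#' @export
q_state <- function(q_init = 0.5) {
  list(q_mf1 = rep(q_init, 2),
       q2 = matrix(q_init, 2, 2),
       prev_choice1 = NA_integer_)
}

#' Model-based first-stage action values
#'
#' The planner evaluates each first-stage action by the Bellman expectation
#' over the known transition structure:
#' `Q_MB(a) = p_common * max(q2[common(a), ]) + (1 - p_common) * max(q2[other, ])`.
#' The agent uses the true transition probabilities; transition learning is
#' not modelled.
#'
#' @param qstate A [q_state()].
#' @param p_common Common-transition probability.
#' @return Numeric vector of two model-based values.
#' @export
mb_values <- function(qstate, p_common = 0.7) {
  m <- apply(qstate$q2, 1, max)   # best option per second-stage state
  c(p_common * m[1] + (1 - p_common) * m[2],
    p_common * m[2] + (1 - p_common) * m[1])
}

softmax2 <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' First-stage choice probabilities
#'
#' Net value is the convex mixture `omega * Q_MB + (1 - omega) * Q_MF`;
#' choice follows a softmax over `beta1 * value + pi * rep(a)` where
#' `rep(a)` indicates repetition of the previous first-stage choice
#' (identically zero on the first trial).
#'
#' @param qstate A [q_state()].
#' @param params An [agent_params()].
#' @param p_common Common-transition probability.
#' @return Two probabilities summing to one.
#' @export
stage1_choice_probs <- function(qstate, params, p_common = 0.7) {
  v <- params$omega * mb_values(qstate, p_common) +
    (1 - params$omega) * qstate$q_mf1
  rep_ind <- if (is.na(qstate$prev_choice1)) c(0, 0) else
    as.numeric(c(0L, 1L) == qstate$prev_choice1)
  x <- params$beta1 * v + params$pi * rep_ind
  if (any(!is.finite(x))) stop("non-finite first-stage utilities")
  softmax2(x)
}

#' Second-stage choice probabilities
#'
#' Softmax with inverse temperature `beta2` over the second-stage action
#' values of the visited state.
#'
#' @param qstate A [q_state()].
#' @param state2 Visited second-stage state, 0 or 1.
#' @param params An [agent_params()].
#' @return Two probabilities summing to one.
#' @export
stage2_choice_probs <- function(qstate, state2, params) {
  stopifnot(state2 %in% c(0L, 1L))
  x <- params$beta2 * qstate$q2[state2 + 1L, ]
  if (any(!is.finite(x))) stop("non-finite second-stage utilities")
  softmax2(x)
}

#' SARSA temporal-difference update after one completed trial
#'
#' On-policy updates in trial order: the first-stage prediction error
#' `delta1 = q2[state2, choice2] - q_mf1[choice1]` moves the first-stage
#' value by `alpha1 * delta1`; the second-stage reward prediction error
#' `delta2 = reward - q2[state2, choice2]` moves the second-stage value by
#' `alpha2 * delta2` and, scaled by the eligibility `lam`, also skips a stage
#' back into the first-stage value (`alpha1 * lam * delta2`). Unchosen values
#' are untouched; the previous first-stage choice is recorded for the
#' perseveration term.
#'
#' @param qstate A [q_state()].
#' @param choice1,state2,choice2 Trial events (0/1 each).
#' @param reward Reward, 0 or 1.
#' @param params An [agent_params()].
#' @return The updated state.
#' @export
update_mf <- function(qstate, choice1, state2, choice2, reward, params) {
  if (any(is.na(c(choice1, state2, choice2, reward))))
    stop("update_mf requires a non-missing trial; caller must skip missing trials")
  i1 <- choice1 + 1L; is <- state2 + 1L; i2 <- choice2 + 1L
  delta1 <- qstate$q2[is, i2] - qstate$q_mf1[i1]
  qstate$q_mf1[i1] <- qstate$q_mf1[i1] + params$alpha1 * delta1
  delta2 <- reward - qstate$q2[is, i2]
  qstate$q2[is, i2] <- qstate$q2[is, i2] + params$alpha2 * delta2
  qstate$q_mf1[i1] <- qstate$q_mf1[i1] + params$alpha1 * params$lam * delta2
  qstate$prev_choice1 <- as.integer(choice1)
  qstate
}

#' Bind parameters and learner state into a stateful policy
#'
#' Returns the policy interface consumed by [run_session()]: closures sharing
#' one mutable learner state, with a `reset()` giving a fresh state per
#' session.
#'
#' @param params An [agent_params()].
#' @param q_init Initial action value, see [q_state()].
#' @param p_common Common-transition probability the planner assumes.
#' @return An object of class `agent_policy` with elements `stage1_probs()`,
#'   `stage2_probs(state2)`, `update(choice1, state2, choice2, reward)`,
#'   `reset()`, `qstate()` and `params`.
#' @export
make_agent <- function(params, q_init = 0.5, p_common = 0.7) {
  stopifnot(inherits(params, "agent_params"))
  env <- new.env(parent = emptyenv())
  env$qs <- q_state(q_init)
  structure(list(
    stage1_probs = function() stage1_choice_probs(env$qs, params, p_common),
    stage2_probs = function(state2) stage2_choice_probs(env$qs, state2, params),
    update = function(choice1, state2, choice2, reward) {
      env$qs <- update_mf(env$qs, choice1, state2, choice2, reward, params)
      invisible(NULL)
    },
    reset = function() { env$qs <- q_state(q_init); invisible(NULL) },
    qstate = function() env$qs,
    params = params
  ), class = "agent_policy")
}
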