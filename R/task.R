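#' Configure the two-stage task environment
#'
#' Builds an immutable description of the two-stage sequential choice task:
#' two first-stage actions lead probabilistically to one of two second-stage
#' states (the "common" transition with probability `p_common`, the "rare"
#' one otherwise), each second-stage state offers two options rewarded
#' stochastically, and the four reward probabilities drift trial-by-trial as
#' Gaussian random walks reflected at `walk_bounds`.
#'
#' Defaults reproduce the study task: 201 trials per session, 70/30
#' transitions, reward-probability walks reflected at 0.25 and 0.75, and a
#' 20-cent reward. The walk step SD is not printed in the source study; the
#' default 0.025 follows the original task convention.
#'
#' @param n_trials Positive integer, trials per session.
#' @param p_common Probability in (0.5, 1) that a first-stage action leads to
#'   its commonly-associated second-stage state.
#' @param walk_sd Standard deviation (probability units per trial) of the
#'   Gaussian random-walk step.
#' @param walk_bounds Ordered pair `c(lower, upper)` of reflecting boundaries,
#'   with `0 < lower < upper < 1`.
#' @param reward_magnitude Monetary units (cents) per rewarded trial.
#' @param init_probs Optional explicit numeric vector of four initial reward
#'   probabilities inside `walk_bounds`; if `NULL` they are drawn uniformly.
#' @param rng_seed Optional integer seed recorded in the config and used by
#'   [run_session()] when no explicit seed is given.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
#' @export
task_config <- function(n_trials = 201L, p_common = 0.7, walk_sd = 0.025,
                        walk_bounds = c(0.25, 0.75), reward_magnitude = 20,
                        init_probs = NULL, rng_seed = NULL) {
  n_trials <- as.integer(n_trials)
  stopifnot(length(n_trials) == 1L, n_trials >= 1L)
  if (!(length(p_common) == 1L && p_common > 0.5 && p_common < 1))
    stop("p_common must lie in (0.5, 1) so that 'common' is well defined")
  if (!(length(walk_bounds) == 2L && walk_bounds[1] > 0 &&
        walk_bounds[1] < walk_bounds[2] && walk_bounds[2] < 1))
    stop("walk_bounds must satisfy 0 < lower < upper < 1")
  if (!(length(walk_sd) == 1L && walk_sd > 0))
    stop("walk_sd must be a positive scalar")
  if (!is.null(init_probs)) {
    if (length(init_probs) != 4L ||
        any(init_probs < walk_bounds[1]) || any(init_probs > walk_bounds[2]))
      stop("init_probs must be four values inside walk_bounds")
  }
  structure(
    list(n_trials = n_trials, p_common = p_common, walk_sd = walk_sd,
         walk_bounds = walk_bounds, reward_magnitude = reward_magnitude,
         init_probs = init_probs, rng_seed = rng_seed),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-stage task configuration\n")
  cat(sprintf("  trials/session : %d\n", x$n_trials))
  cat(sprintf("  p(common)      : %.2f\n", x$p_common))
  cat(sprintf("  walk sd        : %.4f, bounds [%.2f, %.2f]\n",
              x$walk_sd, x$walk_bounds[1], x$walk_bounds[2]))
  cat(sprintf("  reward         : %g cents\n", x$reward_magnitude))
  invisible(x)
}

#' Reflect values into an interval by repeated folding
#'
#' Excursions past a boundary are folded back inside (`2*bound - x`), applied
#' repeatedly so arbitrarily large steps end up inside `[lower, upper]`.
#' Folding (rather than clipping) preserves the spread of the walk's
#' stationary distribution.
#'
#' @param x Numeric vector.
#' @param lower,upper Interval bounds.
#' @return Numeric vector inside `[lower, upper]`.
#' @keywords internal
reflect_bounds <- function(x, lower, upper) {
  width <- upper - lower
  # fold onto [0, 2*width) then mirror the upper half
  y <- (x - lower) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  y + lower
}

#' Initialize the reward-probability random walks
#'
#' Draws the four second-stage reward probabilities independently and
#' uniformly from inside `walk_bounds`, unless the config carries an explicit
#' `init_probs` vector.
#'
#' @param config A [task_config()].
#' @return Numeric vector of four reward probabilities
#'   (order: state 0 option 0, state 0 option 1, state 1 option 0,
#'   state 1 option 1).
#' @export
init_walks <- function(config) {
  if (!is.null(config$init_probs)) return(as.numeric(config$init_probs))
  stats::runif(4, config$walk_bounds[1], config$walk_bounds[2])
}

#' Advance the reward-probability walks one trial
#'
#' Adds an independent Gaussian step (`sd = walk_sd`) to each of the four
#' reward probabilities and reflects any excursion back inside `walk_bounds`.
#'
#' @param probs Numeric vector of four current reward probabilities.
#' @param config A [task_config()].
#' @return Updated numeric vector of four probabilities.
#' @export
step_walk <- function(probs, config) {
  stopifnot(length(probs) == 4L)
  reflect_bounds(probs + stats::rnorm(4, 0, config$walk_sd),
                 config$walk_bounds[1], config$walk_bounds[2])
}

# Fixed action -> common-state mapping: action a (0/1) commonly leads to
# state a. Counterbalancing of the on-screen mapping is presentation-level
# and irrelevant to the statistics.
common_state <- function(choice1) choice1

#' Sample the first-to-second-stage transition
#'
#' With probability `p_common` the chosen action leads to its
#' commonly-associated second-stage state ("common" transition), otherwise
#' to the other state ("rare").
#'
#' @param choice1 First-stage choice, 0 or 1.
#' @param config A [task_config()].
#' @return List with `state2` (0/1) and `transition` ("common"/"rare").
#' @export
sample_transition <- function(choice1, config) {
  stopifnot(choice1 %in% c(0L, 1L))
  common <- stats::runif(1) < config$p_common
  state2 <- if (common) common_state(choice1) else 1L - common_state(choice1)
  list(state2 = as.integer(state2),
       transition = if (common) "common" else "rare")
}

#' Sample a stochastic reward
#'
#' @param prob Reward probability of the chosen second-stage option.
#' @return Integer 0/1.
#' @export
sample_reward <- function(prob) {
  stopifnot(prob >= 0, prob <= 1)
  as.integer(stats::runif(1) < prob)
}

#' Simulate one session of the two-stage task
#'
#' Runs an agent through `config$n_trials` trials: on each trial the agent's
#' first-stage choice is sampled from its choice probabilities, the
#' transition and second-stage choice follow, the reward is drawn from the
#' current random-walk probability of the chosen option, the agent's learning
#' update is applied, and the walks then drift one step. Missing trials
#' (injected with probability `missing_rate`) record no choices, contribute
#' no reward, and freeze the agent's values; the walks still step.
#'
#' @param agent An agent policy from [make_agent()].
#' @param config A [task_config()].
#' @param missing_rate Per-trial probability that the trial is missing.
#' @param seed Optional integer seed (falls back to `config$rng_seed`).
#' @return A `data.frame` with one row per trial: `trial` (0-based),
#'   `choice1`, `state2`, `choice2`, `transition`, `reward`,
#'   `reward_prob_used`, `missing`. Missing trials carry `NA` in the choice,
#'   state, transition, reward and probability columns.
#' @examples
#' agent <- make_agent(agent_params(omega = 0))
#' tab <- run_session(agent, task_config(), seed = 1)
#' nrow(tab)
#' @export
run_session <- function(agent, config = task_config(), missing_rate = 0,
                        seed = NULL) {
  stopifnot(inherits(agent, "agent_policy"))
  seed <- if (is.null(seed)) config$rng_seed else seed
  if (!is.null(seed)) set.seed(seed)
  agent$reset()
  n <- config$n_trials
  probs <- init_walks(config)

  choice1 <- state2 <- choice2 <- reward <- rep(NA_integer_, n)
  transition <- rep(NA_character_, n)
  prob_used <- rep(NA_real_, n)
  miss <- rep(FALSE, n)

  for (t in seq_len(n)) {
    if (missing_rate > 0 && stats::runif(1) < missing_rate) {
      miss[t] <- TRUE
    } else {
      p1 <- agent$stage1_probs()
      check_prob_vector(p1)
      c1 <- as.integer(stats::runif(1) < p1[2])
      tr <- sample_transition(c1, config)
      p2 <- agent$stage2_probs(tr$state2)
      check_prob_vector(p2)
      c2 <- as.integer(stats::runif(1) < p2[2])
      pr <- probs[2L * tr$state2 + c2 + 1L]
      r <- sample_reward(pr)
      agent$update(c1, tr$state2, c2, r)
      choice1[t] <- c1; state2[t] <- tr$state2; choice2[t] <- c2
      transition[t] <- tr$transition; reward[t] <- r; prob_used[t] <- pr
    }
    probs <- step_walk(probs, config)
  }
  data.frame(trial = seq_len(n) - 1L, choice1 = choice1, state2 = state2,
             choice2 = choice2, transition = transition, reward = reward,
             reward_prob_used = prob_used, missing = miss,
             stringsAsFactors = FALSE)
}

check_prob_vector <- function(p, tol = 1e-8) {
  if (length(p) != 2L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > tol)
    stop("agent returned an invalid choice-probability vector")
  invisible(TRUE)
}
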