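test_that("agent_params enforces domain constraints", {
  p <- agent_params()
  expect_s3_class(p, "agent_params")
  expect_error(agent_params(alpha1 = 1.2), "alpha1")
  expect_error(agent_params(omega = -0.1), "omega")
  expect_error(agent_params(beta1 = -1), "inverse temperatures")
  expect_error(agent_params(pi = Inf), "finite")
  expect_silent(agent_params(pi = -3))   # perseveration is unbounded
})

test_that("mb_values is the Bellman expectation over the true transitions", {
  qs <- q_state()
  qs$q2 <- matrix(c(0.6, 0.2, 0.3, 0.1), 2, 2, byrow = TRUE)
  v <- mb_values(qs, p_common = 0.7)
  expect_equal(v[1], 0.7 * 0.6 + 0.3 * 0.3)   # 0.51
  expect_equal(v[2], 0.7 * 0.3 + 0.3 * 0.6)   # 0.39

  # all second-stage values equal c -> both MB values equal c
  qs$q2 <- matrix(0.37, 2, 2)
  expect_equal(mb_values(qs, 0.7), c(0.37, 0.37))

  # p_common = 0.5 makes the two actions indistinguishable
  qs$q2 <- matrix(c(0.9, 0.1, 0.4, 0.2), 2, 2, byrow = TRUE)
  v5 <- mb_values(qs, 0.5)
  expect_equal(v5[1], v5[2])
})

test_that("stage-1 softmax matches the closed form and its limits", {
  qs <- q_state()
  flat <- agent_params(beta1 = 0, pi = 0)
  expect_equal(stage1_choice_probs(qs, flat), c(0.5, 0.5))

  # v = (1, 0), beta1 = 1, pi = 0, omega = 0 -> (e/(e+1), 1/(e+1))
  qs1 <- q_state(); qs1$q_mf1 <- c(1, 0)
  p <- stage1_choice_probs(qs1, agent_params(beta1 = 1, pi = 0, omega = 0))
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)

  # strong perseveration dominates a flat value landscape
  qs2 <- q_state(); qs2$prev_choice1 <- 0L
  p2 <- stage1_choice_probs(qs2, agent_params(beta1 = 0, pi = 30))
  expect_gt(p2[1], 1 - 1e-12)
})

test_that("stage-2 softmax matches the closed form", {
  qs <- q_state()
  expect_equal(stage2_choice_probs(qs, 0L, agent_params(beta2 = 0)),
               c(0.5, 0.5))
  expect_equal(stage2_choice_probs(qs, 1L, agent_params(beta2 = 50)),
               c(0.5, 0.5))   # equal values stay flat for any beta

  qs$q2[1, ] <- c(0.75, 0.25)
  p <- stage2_choice_probs(qs, 0L, agent_params(beta2 = 2))
  expect_equal(p[1], exp(1.5) / (exp(1.5) + exp(0.5)), tolerance = 1e-12)
})

test_that("update_mf follows the hand-traced SARSA arithmetic", {
  # single-step second-stage update
  qs <- q_state(0.5)
  qs$q2[1, 1] <- 0.4
  out <- update_mf(qs, 0L, 0L, 0L, 1L,
                   agent_params(alpha1 = 0, alpha2 = 0.5, lam = 0))
  expect_equal(out$q2[1, 1], 0.7)   # delta2 = 0.6, 0.4 + 0.5*0.6

  # full two-step trace: q_mf1 = 0.2, q2 = 0.4, alpha1 = 0.5, lam = 1,
  # alpha2 = 0.5, reward = 1:
  # delta1 step -> q_mf1 = 0.3; delta2 = 0.6 -> q_mf1 = 0.6, q2 = 0.7
  qs <- q_state(0.5)
  qs$q_mf1[1] <- 0.2; qs$q2[1, 1] <- 0.4
  out <- update_mf(qs, 0L, 0L, 0L, 1L,
                   agent_params(alpha1 = 0.5, alpha2 = 0.5, lam = 1))
  expect_equal(out$q_mf1[1], 0.6)
  expect_equal(out$q2[1, 1], 0.7)
  expect_equal(out$prev_choice1, 0L)
  # unchosen entries untouched
  expect_equal(out$q_mf1[2], 0.5)
  expect_equal(out$q2[2, ], c(0.5, 0.5))

  # lam = 0 gates the stage-skipping update off entirely
  qs <- q_state(0.5); qs$q_mf1[1] <- 0.2; qs$q2[1, 1] <- 0.4
  out0 <- update_mf(qs, 0L, 0L, 0L, 1L,
                    agent_params(alpha1 = 0.5, alpha2 = 0.5, lam = 0))
  expect_equal(out0$q_mf1[1], 0.3)   # only the delta1 backup

  expect_error(update_mf(q_state(), NA, 0L, 0L, 1L, agent_params()),
               "non-missing")
})

test_that("choice probabilities are proper and the omega mixture is linear", {
  set.seed(8)
  for (i in 1:25) {
    pars <- random_params()
    qs <- q_state()
    qs$q_mf1 <- runif(2); qs$q2 <- matrix(runif(4), 2, 2)
    qs$prev_choice1 <- sample(c(NA, 0L, 1L), 1)
    p1 <- stage1_choice_probs(qs, pars)
    p2 <- stage2_choice_probs(qs, sample(0:1, 1), pars)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(sum(p2), 1, tolerance = 1e-12)
    expect_true(all(p1 > 0) && all(p2 > 0))

    # net value is exactly the convex MB/MF combination: recover it from
    # the log-odds and compare elementwise
    pars0 <- agent_params(beta1 = 1, pi = 0, omega = pars$omega)
    v <- pars$omega * mb_values(qs, 0.7) + (1 - pars$omega) * qs$q_mf1
    lo <- log(stage1_choice_probs(qs, pars0)[1]) -
      log(stage1_choice_probs(qs, pars0)[2])
    expect_equal(lo, v[1] - v[2], tolerance = 1e-10)
  }
})

test_that("Q values stay in [0, 1] over long simulations", {
  set.seed(12)
  pars <- agent_params(alpha1 = 0.9, alpha2 = 0.9, lam = 1)
  agent <- make_agent(pars)
  cfg <- task_config(n_trials = 500)
  run_session(agent, cfg, seed = 31)
  qs <- agent$qstate()
  expect_true(all(qs$q_mf1 >= 0 & qs$q_mf1 <= 1))
  expect_true(all(qs$q2 >= 0 & qs$q2 <= 1))
})

test_that("identical parameters and seeds give identical behaviour", {
  pars <- agent_params(omega = 0.3)
  t1 <- run_session(make_agent(pars), task_config(), seed = 77)
  t2 <- run_session(make_agent(pars), task_config(), seed = 77)
  expect_identical(t1, t2)
})

test_that("pure MF and pure MB agents show the expected stay signatures", {
  sig <- function(om, n = 60, seed0) {
    mf <- mb <- numeric(n)
    for (i in seq_len(n)) {
      a <- make_agent(agent_params(beta1 = 3, beta2 = 3, alpha1 = 0.5,
                                   alpha2 = 0.5, lam = 0.5, omega = om,
                                   pi = 0.2))
      st <- stay_table(run_session(a, task_config(), seed = seed0 + i))
      mf[i] <- mf_effect(st); mb[i] <- mb_effect(st)
    }
    list(mf = mf, mb = mb)
  }
  s0 <- sig(0, seed0 = 5000)
  expect_lt(t.test(s0$mf)$p.value, 1e-4)          # reward main effect
  expect_gt(mean(s0$mf), 0)
  expect_gt(t.test(s0$mb)$p.value, 0.01)          # no interaction

  s1 <- sig(1, seed0 = 6000)
  expect_lt(t.test(s1$mb)$p.value, 1e-4)          # crossover interaction
  expect_gt(mean(s1$mb), 0)
  expect_gt(t.test(s1$mf)$p.value, 0.01)          # no reward main effect
})
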