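test_that("stay table matches the hand-enumerated 12-trial fixture", {
  st <- stay_table(hand_trials_12())
  expect_equal(st$p_com_plus, 1 / 2)
  expect_equal(st$p_rar_plus, 2 / 2)
  expect_equal(st$p_com_minus, 1 / 3)
  expect_equal(st$p_rar_minus, 1 / 2)
  expect_equal(unname(st$n_cell), c(2L, 2L, 3L, 2L))
  expect_equal(st$mf_effect, (0.5 + 1 - 1 / 3 - 0.5) / 2)
  expect_equal(st$mb_effect, (0.5 - 1 - 1 / 3 + 0.5) / 2)
  expect_equal(mf_effect(st), st$mf_effect)
  expect_equal(mb_effect(st), st$mb_effect)
})

test_that("degenerate stay patterns behave as defined", {
  # an agent that always repeats: all four cells 1, both effects 0
  tab <- sim_session(agent_params(beta1 = 0, beta2 = 0, pi = 50), seed = 71)
  st <- stay_table(tab)
  expect_equal(c(st$p_com_plus, st$p_rar_plus, st$p_com_minus, st$p_rar_minus),
               rep(1, 4))
  expect_equal(st$mf_effect, 0)
  expect_equal(st$mb_effect, 0)

  # empty cells are flagged and the effect getters refuse
  two <- hand_trials_12()[1:2, ]
  st2 <- stay_table(two)
  expect_true(length(st2$flagged) > 0)
  expect_error(mf_effect(st2), "empty")
  expect_error(mb_effect(st2), "empty")

  allmiss <- hand_trials_12()
  allmiss$missing <- TRUE
  expect_error(stay_table(allmiss), "missing")
})

test_that("MF/MB effect formulas and their algebraic identities hold", {
  expect_equal(mf_effect(fake_stay_table(0.8, 0.8, 0.6, 0.6)), 0.2)
  expect_equal(mb_effect(fake_stay_table(0.8, 0.8, 0.6, 0.6)), 0)
  expect_equal(mf_effect(fake_stay_table(0.9, 0.5, 0.5, 0.9)), 0)
  expect_equal(mb_effect(fake_stay_table(0.9, 0.5, 0.5, 0.9)), 0.4)
  expect_equal(mf_effect(fake_stay_table(0.5, 0.5, 0.5, 0.5)), 0)
  expect_equal(mb_effect(fake_stay_table(0.5, 0.5, 0.5, 0.5)), 0)

  set.seed(17)
  for (i in 1:200) {
    p <- runif(4)
    st <- fake_stay_table(p[1], p[2], p[3], p[4])
    mf <- mf_effect(st); mb <- mb_effect(st)
    expect_equal(mf + mb, st$p_com_plus - st$p_com_minus, tolerance = 1e-14)
    expect_equal(mf - mb, st$p_rar_plus - st$p_rar_minus, tolerance = 1e-14)
    expect_true(abs(mf) <= 1 && abs(mb) <= 1)
  }
})

test_that("exclusion filter applies the strict 30% rule per session", {
  mk <- function(sid, iv, n_missing, n = 201) {
    data.frame(subject_id = sid, intervention = iv, session_order = 1L,
               trial = seq_len(n) - 1L, choice1 = 0L, state2 = 0L,
               choice2 = 0L, transition = "common", reward = 0L,
               missing = c(rep(TRUE, n_missing), rep(FALSE, n - n_missing)),
               stringsAsFactors = FALSE)
  }
  trials <- rbind(
    mk("A", "ATD", 61), mk("A", "BAL", 0), mk("A", "ATL", 0),   # 61/201 > .30
    mk("B", "ATD", 60), mk("B", "BAL", 60), mk("B", "ATL", 60), # 60/201 < .30
    mk("C", "ATD", 0), mk("C", "BAL", 0), mk("C", "ATL", 0))
  out <- exclusion_filter(trials)
  expect_equal(out$excluded, "A")
  expect_setequal(unique(out$trials$subject_id), c("B", "C"))
  expect_equal(nrow(out$log), 9)
  expect_equal(sum(out$log$excluded), 3)   # A's three sessions flagged
  # exactly at threshold is retained: 60.3 would be needed to cross
  expect_true(all(out$log$frac_missing[out$log$subject_id == "B"] < 0.30))
})

test_that("RM-ANOVA matches hand-computed decompositions and edge cases", {
  # constant data
  expect_warning(res <- rm_anova_oneway(matrix(3, 5, 3)), "constant")
  expect_equal(res$F, 0); expect_equal(res$p, 1)

  # {(1,2),(2,3),(3,4)}: SS_cond = 1.5, SS_error = 0 -> infinite-F sentinel
  m <- rbind(c(1, 2), c(2, 3), c(3, 4))
  expect_warning(res2 <- rm_anova_oneway(m), "zero error variance")
  expect_true(is.infinite(res2$F))
  expect_equal(res2$eta_p_sq, 1)

  expect_error(rm_anova_oneway(matrix(1:3, 1, 3)), "at least 2")
  mm <- matrix(rnorm(12), 4, 3); mm[2, 2] <- NA
  expect_error(rm_anova_oneway(mm), "complete")
})

test_that("RM-ANOVA agrees with the aov() oracle on random fixtures", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:20, 1); k <- sample(2:4, 1)
    y <- matrix(rnorm(n * k, sd = runif(1, 0.5, 2)), n, k) +
      rnorm(n)   # subject random effect
    res <- rm_anova_oneway(y)
    long <- data.frame(y = as.vector(y),
                       subj = factor(rep(seq_len(n), k)),
                       cond = factor(rep(seq_len(k), each = n)))
    av <- summary(stats::aov(y ~ cond + Error(subj), data = long))
    tabl <- av[["Error: Within"]][[1]]
    expect_equal(res$F, tabl["cond", "F value"], tolerance = 1e-8)
    expect_equal(res$p, tabl["cond", "Pr(>F)"], tolerance = 1e-8)
    eta_oracle <- tabl["cond", "Sum Sq"] /
      (tabl["cond", "Sum Sq"] + tabl["Residuals", "Sum Sq"])
    expect_equal(res$eta_p_sq, eta_oracle, tolerance = 1e-8)
    expect_equal(res$df_num, k - 1L)
    expect_equal(res$df_den, (k - 1L) * (n - 1L))
  }
})

test_that("Greenhouse-Geisser correction only deflates significance", {
  set.seed(29)
  y <- matrix(rnorm(60), 20, 3) + outer(rep(0, 20), c(0, 0.5, 1), "+")
  plain <- rm_anova_oneway(y)
  gg <- rm_anova_oneway(y, gg_correction = TRUE)
  expect_equal(plain$F, gg$F)
  expect_gte(gg$p, plain$p)
})

test_that("experimental BIC Bayes factor tracks the evidence direction", {
  set.seed(31)
  null_y <- matrix(rnorm(90), 30, 3)
  eff_y <- null_y + matrix(rep(c(0, 0, 1.5), each = 30), 30, 3)
  bf_null <- rm_anova_oneway(null_y, bf_bic = TRUE)$bf10_bic
  bf_eff <- rm_anova_oneway(eff_y, bf_bic = TRUE)$bf10_bic
  expect_gt(bf_eff, 1)        # strong injected effect -> evidence for H1
  expect_lt(bf_null, bf_eff)
  expect_null(rm_anova_oneway(null_y)$bf10_bic)   # off by default
  suppressWarnings(
    expect_true(is.na(rm_anova_oneway(matrix(3, 5, 3), bf_bic = TRUE)$bf10_bic)))
})

test_that("intervention_analysis emits one row per outcome and drops incomplete subjects", {
  co <- small_cohort(n_subjects = 4, n_trials = 80, seed = 81)
  fits <- fit_cohort(co$trials, n_restarts = 2, seed = 82)
  st <- cohort_stay_tables(co$trials)
  out <- intervention_analysis(fits, st)
  expect_equal(nrow(out$report), 9)
  expect_setequal(out$report$outcome,
                  c("mf_effect", "mb_effect", twostepRL:::param_names))
  expect_true(all(out$report$p >= 0 & out$report$p <= 1))
  expect_true(all(out$report$eta_p_sq >= 0 & out$report$eta_p_sq <= 1))
  expect_length(out$dropped, 0)

  # a subject missing one session is dropped with a log entry
  fits2 <- fits[!(fits$subject_id == "S001" & fits$intervention == "ATL"), ]
  out2 <- intervention_analysis(fits2, st)
  expect_equal(out2$dropped, "S001")
  expect_equal(out2$report$n[out2$report$outcome == "omega"], 3)
  # behavioural outcomes keep their own complete set
  expect_equal(out2$report$n[out2$report$outcome == "mf_effect"], 4)

  expect_error(intervention_analysis(fits[fits$subject_id == "S001", ], st),
               "fewer than 2")
})
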