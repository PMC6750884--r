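test_that("stage-1 values implement planning, caching and their hybrid", {
  spec <- model_spec("MB")
  par <- resolve_params(spec)
  st <- init_agent_state(spec, par)
  st$Tmat["L", ] <- c(S1 = 0, S2 = 1)
  st$Q2["S2", ] <- c(L = 0.2, R = 0.6)
  v <- stage1_values(spec, par, st)
  expect_equal(unname(v["L"]), 0.6)

  hspec <- model_spec("MB-MF")
  hpar <- resolve_params(hspec, c(w = 0.5))
  hst <- init_agent_state(hspec, hpar)
  hst$Tmat["L", ] <- c(S1 = 0, S2 = 1)
  hst$Q2["S2", ] <- c(L = 0.2, R = 0.6)
  hst$Q1mf["L"] <- 0.2
  expect_equal(unname(stage1_values(hspec, hpar, hst)["L"]), 0.4)

  # exact stage-2 ties leave planning at the tied value
  tst <- init_agent_state(spec, par)
  tst$Q2["S2", ] <- c(L = 0.3, R = 0.3)
  tst$Tmat["L", ] <- c(S1 = 0, S2 = 1)
  expect_equal(unname(stage1_values(spec, par, tst)["L"]), 0.3)
})

test_that("softmax policies match the hand-evaluated logistic and lapse-mix to uniform", {
  spec <- model_spec("MB")
  par <- resolve_params(spec, c(beta1 = 2, beta2 = 2))
  st <- init_agent_state(spec, par)
  st$Tmat["L", ] <- c(S1 = 0, S2 = 1)
  st$Tmat["R", ] <- c(S1 = 1, S2 = 0)
  st$Q2["S2", ] <- c(L = 0.2, R = 0.6)  # V(L) = 0.6
  st$Q2["S1", ] <- c(L = 0.2, R = 0.2)  # V(R) = 0.2
  p1 <- stage1_policy(spec, par, st)
  expect_equal(unname(p1["L"]), 1 / (1 + exp(-2 * 0.4)), tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)

  p2 <- stage2_policy("S2", spec, par, st)
  expect_equal(unname(p2["R"]), 1 / (1 + exp(-2 * 0.4)), tolerance = 1e-12)

  flat0 <- resolve_params(spec, c(beta1 = 0, beta2 = 0))
  expect_equal(unname(stage1_policy(spec, flat0, st)), c(0.5, 0.5))

  # equal values are indifferent; a large discrimination bias dominates
  eq <- init_agent_state(spec, par)
  expect_equal(unname(stage2_policy("S1", spec, par, eq)), c(0.5, 0.5))
  bpar <- resolve_params(model_spec("MB", disc_bias = TRUE), c(b_disc = 50))
  expect_gt(stage2_policy("S1", model_spec("MB", disc_bias = TRUE), bpar, eq)["L"],
            0.9999)

  # lapse floor mixes towards uniform
  lspec <- model_spec("MB", lapse = TRUE)
  lpar <- resolve_params(lspec, c(beta1 = 50, eps = 0.2))
  pl <- stage1_policy(lspec, lpar, st)
  expect_equal(unname(pl["R"]), 0.1, tolerance = 1e-7)
})

test_that("trial likelihood reduces correctly and flags impossible observations", {
  trial <- list(a1 = "L", s2 = "S1", a2 = "R", outcome = 0L)
  spec <- model_spec("MB")
  par <- resolve_params(spec)
  st <- init_agent_state(spec, par)
  tl <- trial_loglik(trial, spec, par, st)
  expect_equal(tl$loglik, log(tl$p1[["L"]]) + log(tl$p2[["R"]]))
  expect_identical(tl$resp_seq, 0)

  hspec <- model_spec("H")
  hpar <- resolve_params(hspec, c(p_int = 0))
  hst <- init_agent_state(hspec, hpar)
  # sequence starting with L must end in R; observing a2 = L is impossible
  bad <- list(a1 = "L", s2 = "S1", a2 = "L", outcome = 0L)
  expect_error(trial_loglik(bad, hspec, hpar, hst),
               class = "twostagerl_impossible_observation")
  ok <- list(a1 = "L", s2 = "S1", a2 = "R", outcome = 0L)
  expect_equal(trial_loglik(ok, hspec, hpar, hst)$resp_seq, 1)

  expect_error(trial_loglik(list(a1 = "L", s2 = "S1", a2 = NA, outcome = 0,
                                 aborted = 1L), hspec, hpar, hst), "aborted")
})

test_that("updates follow the delta rules and the responsibility weighting contract", {
  spec <- model_spec("H-MB")
  par <- resolve_params(spec, c(alpha = 1))
  st <- init_agent_state(spec, par)
  trial <- list(a1 = "L", s2 = "S2", a2 = "R", outcome = 1L)
  up <- update_state(st, trial, resp_seq = 1, spec, par)
  expect_identical(unname(up$Q2["S2", "R"]), 1)     # full update to the reward
  expect_identical(unname(up$Qseq["LR"]), 1)

  zero <- resolve_params(spec, c(alpha = 0))
  expect_identical(update_state(st, trial, 1, spec, zero)[c("Q2", "Qseq", "Q1mf")],
                   st[c("Q2", "Qseq", "Q1mf")])

  half <- resolve_params(spec, c(alpha = 0.5))
  w1 <- update_state(st, trial, 1, spec, half)
  w0 <- update_state(st, trial, 0, spec, half)
  expect_equal(unname(w1$Qseq["LR"]), 0.75)  # unweighted delta rule
  expect_identical(w0$Qseq, st$Qseq)         # responsibility 0: untouched
  # transition rows stay normalised
  expect_equal(unname(rowSums(w1$Tmat)), c(1, 1))

  # stage-1 cached update uses the pre-update stage-2 value
  mf <- model_spec("MF", eligibility = TRUE)
  mpar <- resolve_params(mf, c(alpha = 0.5, lam = 0.5))
  mst <- init_agent_state(mf, mpar)
  mup <- update_state(mst, trial, 0, mf, mpar)
  expect_equal(unname(mup$Q1mf["L"]),
               0.5 + 0.5 * (0.5 - 0.5) + 0.5 * 0.5 * (1 - 0.5))
})

test_that("probabilities normalise and values stay within the reward range", {
  set.seed(61)
  for (fam in c("FLAT", "MF", "MB-MF", "H", "H-MB", "H-MB-MF")) {
    spec <- model_spec(fam)
    par <- resolve_params(spec, random_free_params(spec))
    st <- init_agent_state(spec, par)
    for (i in 1:60) {
      trial <- list(a1 = sample(c("L", "R"), 1), s2 = sample(c("S1", "S2"), 1),
                    a2 = sample(c("L", "R"), 1), outcome = sample(0:1, 1))
      tl <- trial_loglik(trial, spec, par, st)
      expect_equal(sum(tl$p1), 1, tolerance = 1e-12)
      expect_equal(sum(tl$p2), 1, tolerance = 1e-12)
      st <- update_state(st, trial, tl$resp_seq, spec, par)
      vals <- c(st$Q2, st$Q1mf, st$Qseq, st$Qflat)
      expect_true(all(vals >= 0 & vals <= 1))
      expect_equal(unname(rowSums(st$Tmat)), c(1, 1), tolerance = 1e-12)
    }
  }
})

test_that("compiled likelihood equals the R reference on random cohorts", {
  set.seed(71)
  for (fam in c("FLAT", "MF", "MB", "MB-MF", "H", "H-MF", "H-MB", "H-MB-MF")) {
    spec <- model_spec(fam)
    free <- random_free_params(spec)
    par <- resolve_params(spec, free)
    co <- simulate_probe_cohort(spec, n_subjects = 2, n_trials = 80,
                                seed = 100 + nchar(fam))
    ref <- session_loglik(spec, par, co$trials)
    cdata <- twostagerl:::make_cpp_data(co$trials)
    cspec <- twostagerl:::make_cpp_spec(spec, prior_spec(spec))
    theta <- twostagerl:::to_transformed(free, spec$params$transform)
    nll <- twostagerl:::cpp_neg_log_post(theta, cdata, cspec, FALSE)
    expect_equal(nll, -ref$loglik, tolerance = 1e-10)
  }
})

test_that("a flat learner repeats the previously rewarded proximal press", {
  spec <- model_spec("FLAT")
  par <- resolve_params(spec, c(alpha1 = 0.5, beta1 = 5))
  set.seed(81)
  res <- run_session(rl_agent(spec, par),
                     task_config(max_outcomes = 500L, max_trials = 1500L))
  tr <- res$trials
  n <- nrow(tr)
  rewarded_prev <- tr$outcome[-n] == 1
  repeats <- tr$a1[-1][rewarded_prev] == tr$a2[-n][rewarded_prev]
  expect_gt(mean(repeats), 0.5)
})

test_that("an uninterrupted sequence forces its second press even after a rare transition", {
  spec <- model_spec("H-MB")
  par <- resolve_params(spec, c(p_int = 0))
  ag <- rl_agent(spec, par)
  set.seed(91)
  found_rare_seq <- 0
  for (i in 1:400) {
    act <- agent_act1(ag, "S2")
    tr <- sample_transition(act$a1, task_config(p_common = 0.5))
    a2 <- agent_act2(ag, tr$s2, act)
    if (act$mode == "seq") {
      expect_identical(a2, c(L = "R", R = "L")[[act$a1]])
      if (tr$transition == "rare") found_rare_seq <- found_rare_seq + 1
    }
    ag <- agent_learn(ag, act, tr$s2, a2,
                      outcome_reward(tr$s2, a2, "S2"))
  }
  expect_gt(found_rare_seq, 0)
})
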