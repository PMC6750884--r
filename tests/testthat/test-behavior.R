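toy3 <- function() {
  make_trials(a1 = c("L", "L", "R"), s2 = c("S2", "S1", "S1"),
              a2 = c("R", "R", "L"), outcome = c(1L, 0L, 0L))
}

test_that("lag annotation reproduces the hand-walked toy session", {
  ann <- annotate_trials(toy3())
  expect_true(all(is.na(ann[1, c("reward_prev", "stay1", "transition_prev")])))
  expect_identical(ann$stay1[2], 1L)
  expect_identical(ann$reward_prev[2], 1L)
  expect_identical(ann$same_s2_as_prev[2], 0L)
  expect_identical(ann$correct_disc_prev[2], 1L)  # R in S2 was correct
  expect_identical(ann$transition_prev[2], "common")
  expect_identical(ann$stay1[3], 0L)
  expect_identical(ann$stay2[3], 0L)
  expect_identical(ann$correct_disc_prev[3], 0L)  # R in S1 was incorrect
})

test_that("aborted trials are skipped by the lag chain, not treated as predecessors", {
  tr <- make_trials(a1 = c("L", "R", "L"), s2 = c("S2", "S1", "S2"),
                    a2 = c("R", NA, "R"), outcome = c(1L, 0L, 0L),
                    aborted = c(0L, 1L, 0L))
  ann <- annotate_trials(tr)
  expect_true(all(is.na(ann[2, c("reward_prev", "stay1")])))
  # trial 3 lags back to trial 1 across the aborted trial
  expect_identical(ann$reward_prev[3], 1L)
  expect_identical(ann$stay1[3], 1L)
  expect_identical(ann$stay2[3], 1L)
})

test_that("session boundaries break all lag relationships", {
  tr <- rbind(make_trials(c("L", "L"), c("S2", "S2"), c("R", "R"), c(1L, 1L)),
              make_trials(c("L", "R"), c("S2", "S1"), c("R", "L"), c(0L, 0L),
                          session = 2L))
  ann <- annotate_trials(tr)
  expect_true(is.na(ann$reward_prev[3]))
  expect_identical(ann$reward_prev[4], 0L)
  expect_error(annotate_trials(tr[c(2, 1, 3, 4), ]), "ordered")
})

test_that("the correct-discrimination filter honours its flag", {
  ann <- annotate_trials(toy3())
  with_flag <- filter_stage1(ann)
  without <- filter_stage1(ann, require_correct_disc = FALSE)
  # trial 3's predecessor (R in S1) was an incorrect discrimination
  expect_identical(with_flag$trial, 1L)
  expect_identical(without$trial, c(1L, 2L))
})

test_that("filters drop first-of-session and aborted trials and are idempotent", {
  set.seed(101)
  res <- run_session(random_agent(), task_config(p_common = 0.8, p_abort = 0.15,
                                                 max_outcomes = 40L))
  ann <- annotate_trials(res$trials)
  f1 <- filter_stage1(ann)
  expect_true(all(f1$aborted == 0))
  expect_false(0L %in% f1$trial)
  expect_identical(filter_stage1(f1), f1)
  f2 <- filter_stage2(ann)
  expect_true(all(f2$same_s2_as_prev == 0))
  expect_identical(filter_stage2(ann), filter_stage1(ann)[
    filter_stage1(ann)$same_s2_as_prev == 0, ])
})

test_that("a deterministic session with constant staying leaves no stage-2 trials", {
  # same stage-1 action under p_common = 1 always reaches the same state
  tr <- make_trials(rep("L", 6), rep("S2", 6), rep("R", 6),
                    c(1L, 0L, 1L, 0L, 0L, 1L))
  expect_identical(nrow(filter_stage2(annotate_trials(tr))), 0L)
})

test_that("a discriminating cohort keeps between half and all stage-1 trials", {
  co <- simulate_probe_cohort(model_spec("H-MB"), 4, 250, seed = 102)
  ann <- annotate_trials(co$trials)
  frac <- nrow(filter_stage1(ann)) / nrow(filter_stage1(ann, FALSE))
  expect_gt(frac, 0.5)
  expect_lt(frac, 1.0)
})

test_that("regression on coin-flip stays finds nothing", {
  set.seed(103)
  n <- 4000
  tr <- data.frame(subject = rep(sprintf("s%d", 1:8), each = n / 8),
                   session = 1L,
                   reward_prev = sample(0:1, n, TRUE),
                   transition_prev = sample(c("common", "rare"), n, TRUE),
                   stay1 = sample(0:1, n, TRUE),
                   correct_disc_prev = 1L, aborted = 0L)
  tab <- stay_regression(tr, "stay1")
  expect_true(all(abs(tab$estimate) < 0.25))
  expect_true(all(tab$p[tab$term != "(Intercept)"] > 0.05))
  expect_true(all(abs(tab$ci_hi - (tab$estimate + 1.96 * tab$se)) < 1e-12))
})

test_that("generative logistic coefficients are recovered by the mixed model", {
  set.seed(104)
  n <- 6000
  subj <- rep(sprintf("s%d", 1:8), each = n / 8)
  u <- rnorm(8, 0, 0.3)[as.integer(factor(subj))]
  reward <- sample(0:1, n, TRUE)
  transition <- sample(c("common", "rare"), n, TRUE)
  eta <- -0.2 + u + 0.6 * (reward - 0.5) +
    0.9 * (reward - 0.5) * ((transition == "common") - 0.5)
  tr <- data.frame(subject = subj, session = 1L, reward_prev = reward,
                   transition_prev = transition,
                   stay1 = rbinom(n, 1, plogis(eta)),
                   correct_disc_prev = 1L, aborted = 0L)
  tab <- stay_regression(tr, "stay1", random = "intercept")
  est <- setNames(tab$estimate, tab$term)
  expect_equal(unname(est["reward"]), 0.6, tolerance = 0.35)
  expect_equal(unname(est["reward:transition"]), 0.9, tolerance = 0.45)
  expect_true(attr(tab, "converged"))
})

test_that("session profiles flag degenerate sessions and recover signs", {
  # all rewards zero: the reward lag is constant, hence inestimable
  tr <- make_trials(sample(c("L", "R"), 30, TRUE), rep("S2", 30),
                    sample(c("L", "R"), 30, TRUE), rep(0L, 30))
  prof <- session_stay_profile(tr, require_correct_disc = FALSE)
  expect_true(prof$flagged[1])
  expect_true(is.na(prof$reward_logodds[1]))
})
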