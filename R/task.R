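#' Task configuration for the two-stage decision task
#'
#' Defines the generative rules of one session of the two-stage task: the
#' stage-1 to stage-2 contingency, the common-transition probability, the
#' reward-reversal probability, and the session caps.
#'
#' During training, each stage-1 action leads deterministically to its
#' "common" stage-2 state (`L` to `S2`, `R` to `S1` by default). In probe
#' sessions the transition is probabilistic: the common state is reached
#' with probability `p_common` (0.8 in the standard probe, 0.5 in the
#' uniform probe). Only one stage-2 state is rewarding at any moment, and it
#' switches with probability `p_reversal` after every earned outcome.
#'
#' @param contingency Named character vector mapping each stage-1 action to
#'   its common stage-2 state. Must be a bijection between `c("L","R")` and
#'   `c("S1","S2")`. Default `c(L = "S2", R = "S1")`; pass the reversed map
#'   for reversed-contingency sessions.
#' @param p_common Probability in `[0,1]` that a stage-1 action leads to its
#'   common state (1 for training sessions, 0.8 or 0.5 for probes).
#' @param p_reversal Probability in `[0,1]` of switching the rewarding
#'   stage-2 state after an earned outcome. Default 0.14.
#' @param max_outcomes Session cap on earned outcomes (default 60).
#' @param max_trials Safety cap on total trials per session (default 2000).
#' @param p_abort Per-trial probability that the trial is aborted between
#'   the stage-1 and stage-2 presses (no stage-2 action, no outcome).
#'   Default 0; used to exercise the analysis-side exclusion rules.
#' @param strict_sequence Logical flag recording that the session used the
#'   strict-sequence (abort-on-magazine-entry) procedure. Semantics only;
#'   aborts are generated through `p_abort`.
#' @return An object of class `task_config`.
#' @examples
#' training <- task_config()                 # deterministic transitions
#' probe    <- task_config(p_common = 0.8)   # standard probe session
#' @export
task_config <- function(contingency = c(L = "S2", R = "S1"),
                        p_common = 1.0,
                        p_reversal = 0.14,
                        max_outcomes = 60L,
                        max_trials = 2000L,
                        p_abort = 0,
                        strict_sequence = FALSE) {
  if (!identical(sort(names(contingency)), c("L", "R")) ||
      !identical(sort(unname(contingency)), c("S1", "S2"))) {
    stop("contingency must be a bijection between {L,R} and {S1,S2}")
  }
  for (p in c(p_common = p_common, p_reversal = p_reversal, p_abort = p_abort)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("p_common, p_reversal and p_abort must be probabilities in [0,1]")
    }
  }
  if (max_outcomes < 1) stop("max_outcomes must be >= 1")
  if (is.null(max_trials) || is.na(max_trials)) {
    stop("max_trials must be set to guarantee termination")
  }
  structure(
    list(contingency = contingency, p_common = p_common,
         p_reversal = p_reversal, max_outcomes = as.integer(max_outcomes),
         max_trials = as.integer(max_trials), p_abort = p_abort,
         strict_sequence = strict_sequence),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Two-stage task configuration\n")
  cat(sprintf("  contingency : L -> %s, R -> %s\n",
              x$contingency[["L"]], x$contingency[["R"]]))
  cat(sprintf("  p_common    : %.2f%s\n", x$p_common,
              if (x$p_common == 1) " (deterministic / training)" else " (probe)"))
  cat(sprintf("  p_reversal  : %.2f  max_outcomes: %d  max_trials: %d\n",
              x$p_reversal, x$max_outcomes, x$max_trials))
  invisible(x)
}

#' Discriminative stage-2 action for a stage-2 state
#'
#' The only stage-2 action ever rewarded in a given stage-2 state:
#' `R` in `S2` and `L` in `S1`.
#'
#' @param s2 Character vector of stage-2 states (`"S1"` or `"S2"`).
#' @return Character vector of actions.
#' @export
discriminative_action <- function(s2) {
  out <- ifelse(s2 == "S2", "R", ifelse(s2 == "S1", "L", NA_character_))
  if (anyNA(out)) stop("unknown stage-2 state symbol")
  out
}

#' Sample a stage-1 transition
#'
#' Draws the stage-2 state reached after a stage-1 action: the action's
#' common state with probability `p_common`, the other state otherwise.
#'
#' @param a1 Stage-1 action, `"L"` or `"R"`.
#' @param config A [task_config()].
#' @return A list with `s2` (the stage-2 state) and `transition`
#'   (`"common"` or `"rare"`).
#' @export
sample_transition <- function(a1, config) {
  if (!a1 %in% c("L", "R")) stop("unknown stage-1 action symbol: ", a1)
  common_state <- config$contingency[[a1]]
  other_state <- setdiff(c("S1", "S2"), common_state)
  if (stats::runif(1) < config$p_common) {
    list(s2 = common_state, transition = "common")
  } else {
    list(s2 = other_state, transition = "rare")
  }
}

#' Outcome rule of the two-stage task
#'
#' Reward (1) is delivered iff the stage-2 state is the currently rewarding
#' state and the action taken there is its discriminative action; otherwise
#' no reward (0). The non-rewarding state never pays regardless of action.
#'
#' @param s2 Stage-2 state reached.
#' @param a2 Stage-2 action taken.
#' @param rewarding The currently rewarding stage-2 state.
#' @return Integer 0 or 1.
#' @export
outcome_reward <- function(s2, a2, rewarding) {
  if (!s2 %in% c("S1", "S2") || !rewarding %in% c("S1", "S2")) {
    stop("unknown stage-2 state symbol")
  }
  if (!a2 %in% c("L", "R")) stop("unknown stage-2 action symbol: ", a2)
  as.integer(s2 == rewarding && a2 == discriminative_action(s2))
}

#' Reversal rule for the rewarding stage-2 state
#'
#' After an earned outcome the rewarding state flips with probability
#' `p_reversal`; after a non-rewarded trial it never changes.
#'
#' @param rewarding Current rewarding stage-2 state.
#' @param reward Outcome of the trial just finished (0/1).
#' @param config A [task_config()].
#' @return The (possibly flipped) rewarding state.
#' @export
maybe_reverse <- function(rewarding, reward, config) {
  stopifnot(reward %in% c(0L, 1L))
  if (reward == 1L && stats::runif(1) < config$p_reversal) {
    setdiff(c("S1", "S2"), rewarding)
  } else {
    rewarding
  }
}

empty_trials <- function() {
  data.frame(subject = character(), session = integer(), phase = character(),
             trial = integer(), a1 = character(), s2 = character(),
             a2 = character(), outcome = integer(), transition = character(),
             aborted = integer(), rt = numeric(), rewarding = character(),
             stringsAsFactors = FALSE)
}

#' Run one session of the two-stage task
#'
#' Iterates the trial event flow -- stage-1 choice (possibly the first
#' element of an action sequence), transition, stage-2 action (forced second
#' element if an uninterrupted sequence was selected), outcome, possible
#' reversal, agent update -- until `max_outcomes` outcomes have been earned
#' or `max_trials` trials completed.
#'
#' The rewarding stage-2 state at session start is drawn uniformly at random
#' and recorded per trial in the `rewarding` column, so analysis-side
#' "correct action" predictors can be computed for synthetic data.
#'
#' The agent's learned state is *not* reset here: values persist across
#' consecutive sessions of the same subject, as they do in animals. A
#' freshly constructed [rl_agent()] starts from its initial values; call
#' [agent_reset()] explicitly to force a re-initialisation.
#'
#' @param agent An agent object: an [rl_agent()], [oracle_agent()] or
#'   [random_agent()].
#' @param config A [task_config()].
#' @param subject,session,phase Identifiers stamped on every trial row.
#' @return A list with `trials` (one row per trial; 0-based `trial` index)
#'   and `agent` (the agent with its learned state after the session).
#' @export
run_session <- function(agent, config, subject = "s1", session = 1L,
                        phase = if (config$p_common < 1) "probe" else "training") {
  rewarding <- sample(c("S1", "S2"), 1L)
  n <- config$max_trials
  rows <- vector("list", n)
  outcomes <- 0L
  t <- 0L
  while (outcomes < config$max_outcomes && t < config$max_trials) {
    act1 <- agent_act1(agent, rewarding)
    tr <- sample_transition(act1$a1, config)
    aborted <- config$p_abort > 0 && stats::runif(1) < config$p_abort
    if (aborted) {
      rows[[t + 1L]] <- list(a1 = act1$a1, s2 = tr$s2, a2 = NA_character_,
                             outcome = 0L, transition = tr$transition,
                             aborted = 1L, rewarding = rewarding)
      t <- t + 1L
      next
    }
    a2 <- agent_act2(agent, tr$s2, act1)
    r <- outcome_reward(tr$s2, a2, rewarding)
    rows[[t + 1L]] <- list(a1 = act1$a1, s2 = tr$s2, a2 = a2, outcome = r,
                           transition = tr$transition, aborted = 0L,
                           rewarding = rewarding)
    agent <- agent_learn(agent, act1, tr$s2, a2, r)
    rewarding <- maybe_reverse(rewarding, r, config)
    outcomes <- outcomes + r
    t <- t + 1L
  }
  if (t == 0L) return(list(trials = empty_trials(), agent = agent))
  rows <- rows[seq_len(t)]
  trials <- data.frame(
    subject = subject, session = as.integer(session), phase = phase,
    trial = seq_len(t) - 1L,
    a1 = vapply(rows, `[[`, "", "a1"),
    s2 = vapply(rows, `[[`, "", "s2"),
    a2 = vapply(rows, function(x) if (is.na(x$a2)) NA_character_ else x$a2, ""),
    outcome = vapply(rows, `[[`, 0L, "outcome"),
    transition = vapply(rows, `[[`, "", "transition"),
    aborted = vapply(rows, `[[`, 0L, "aborted"),
    rt = NA_real_,
    rewarding = vapply(rows, `[[`, "", "rewarding"),
    stringsAsFactors = FALSE)
  list(trials = trials, agent = agent)
}
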