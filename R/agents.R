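#' Initialise the learned state of an agent
#'
#' All value structures start at `q0` (default 0.5, the midpoint of the
#' reward range, so both actions start symmetric) and the transition
#' estimate starts at the trained contingency smoothed towards the
#' configured prior weight: `T[a, common(a)] = t_common0`. Learned values
#' persist across consecutive sessions of the same subject; likelihood
#' evaluation re-initialises at subject boundaries only.
#'
#' @param spec A [model_spec()].
#' @param params Full parameter vector from [resolve_params()].
#' @param contingency Stage-1 to stage-2 contingency used to orient the
#'   initial transition estimate.
#' @return A list with matrices/vectors `Q2`, `Q1mf`, `Tmat`, `Qseq`,
#'   `Qflat`.
#' @export
init_agent_state <- function(spec, params, contingency = c(L = "S2", R = "S1")) {
  q0 <- params[["q0"]]
  states <- c("S1", "S2")
  acts <- c("L", "R")
  Q2 <- matrix(q0, 2, 2, dimnames = list(states, acts))
  Tmat <- matrix(0, 2, 2, dimnames = list(acts, states))
  for (a in acts) {
    Tmat[a, contingency[[a]]] <- params[["t_common0"]]
    Tmat[a, setdiff(states, contingency[[a]])] <- 1 - params[["t_common0"]]
  }
  list(Q2 = Q2,
       Q1mf = c(L = q0, R = q0),
       Tmat = Tmat,
       Qseq = c(LR = q0, RL = q0),
       Qflat = c(L = q0, R = q0))
}

#' Stage-1 values of the agent's options
#'
#' Single actions are valued as `w * V_MB(a) + (1 - w) * Q1mf(a)`, where
#' `V_MB(a) = sum_s T[a, s] * max_a' Q2[s, a']` is the planned value over
#' the transition estimate (pure MB: `w = 1`; pure MF: `w = 0`). Sequences
#' are valued by their cached value `Qseq`. The flat agent values its two
#' presses by `Qflat` on the single merged state.
#'
#' @param spec A [model_spec()].
#' @param params Full parameter vector.
#' @param state Agent state from [init_agent_state()].
#' @return Named numeric vector over [option_set()].
#' @export
stage1_values <- function(spec, params, state) {
  opts <- option_set(spec)
  v <- stats::setNames(numeric(length(opts)), opts)
  if (spec$traits$is_flat) {
    v[c("L", "R")] <- state$Qflat[c("L", "R")]
    return(v)
  }
  if (spec$traits$has_single) {
    vmb <- c(L = 0, R = 0)
    if (spec$traits$uses_mb) {
      best <- apply(state$Q2, 1L, max)  # max over stage-2 actions, per state
      vmb <- as.vector(state$Tmat %*% best[colnames(state$Tmat)])
      names(vmb) <- rownames(state$Tmat)
    }
    w <- params[["w"]]
    v[c("L", "R")] <- w * vmb[c("L", "R")] + (1 - w) * state$Q1mf[c("L", "R")]
  }
  if (spec$traits$has_seq) v[c("LR", "RL")] <- state$Qseq[c("LR", "RL")]
  v
}

lapse_softmax <- function(u, eps) {
  p <- exp(u - max(u))
  p <- p / sum(p)
  (1 - eps) * p + eps / length(p)
}

#' Stage-1 choice probabilities
#'
#' Softmax with inverse temperature `beta1` over [stage1_values()], mixed
#' with a uniform lapse floor `eps`.
#'
#' @inheritParams stage1_values
#' @return Named probability vector over [option_set()], summing to 1.
#' @export
stage1_policy <- function(spec, params, state) {
  v <- stage1_values(spec, params, state)
  lapse_softmax(params[["beta1"]] * v, params[["eps"]])
}

#' Stage-2 choice probabilities
#'
#' Softmax over utilities `beta2 * Q2[s2, a] + b_disc * 1[a ==
#' discriminative(s2)]`, mixed with the lapse floor. `b_disc` is the
#' discrimination-tendency bias: a fixed pull towards the only action ever
#' rewarded in each stage-2 state. The flat agent instead reuses its merged
#' single-state values with `beta1` (it does not represent stage-2 states).
#'
#' @param s2 Stage-2 state, `"S1"` or `"S2"`.
#' @inheritParams stage1_values
#' @return Named probability vector over `c("L", "R")`.
#' @export
stage2_policy <- function(s2, spec, params, state) {
  if (!s2 %in% c("S1", "S2")) stop("unknown stage-2 state symbol: ", s2)
  if (spec$traits$is_flat) {
    return(lapse_softmax(params[["beta1"]] * state$Qflat, params[["eps"]]))
  }
  u <- params[["beta2"]] * state$Q2[s2, c("L", "R")]
  u[discriminative_action(s2)] <- u[discriminative_action(s2)] + params[["b_disc"]]
  lapse_softmax(u, params[["eps"]])
}

#' Joint likelihood of one trial's observed actions
#'
#' Marginalises over the latent execution modes consistent with the
#' observed stage-1 press: either a single action was selected (followed by
#' a stage-2 choice), or the unique sequence starting with that press was
#' selected and then either ran to completion (stage-2 press forced to the
#' sequence's second element) or was interrupted with probability `p_int`
#' (control returned to the stage-2 policy). Families without sequences
#' reduce to `P1(a1) * P2(a2 | s2)`; the pure sequence family `H` has no
#' single-action mode.
#'
#' @param trial A list or one-row data.frame with `a1`, `s2`, `a2`,
#'   `outcome`, and optionally `aborted`.
#' @inheritParams stage1_values
#' @return A list: `loglik` (log joint probability of `(a1, a2)`),
#'   `resp_seq` (posterior probability that a sequence was *selected* at
#'   stage 1, whether it then completed or was interrupted -- the
#'   responsibility that weights the sequence-value update, since reward
#'   is attributed to the option chosen at stage 1), `resp_complete`
#'   (posterior that a sequence ran to completion, the signature of
#'   habitual execution), `p1`, `p2` (the two policies used).
#'   If the observation has probability zero, a condition of class
#'   `twostagerl_impossible_observation` is signalled instead of silently
#'   returning `-Inf`.
#' @export
trial_loglik <- function(trial, spec, params, state) {
  if (!is.null(trial$aborted) && isTRUE(trial$aborted == 1)) {
    stop("aborted trials carry no stage-2 action; exclude them before ",
         "computing likelihoods")
  }
  a1 <- trial$a1; s2 <- trial$s2; a2 <- trial$a2
  if (spec$traits$is_flat) {
    p1 <- stage1_policy(spec, params, state)
    # the first press updates the merged-state value before the second press
    st2 <- state
    st2$Qflat[a1] <- st2$Qflat[a1] + params[["alpha1"]] * (0 - st2$Qflat[a1])
    p2 <- stage2_policy(s2, spec, params, st2)
    p_obs <- p1[[a1]] * p2[[a2]]
    resp <- 0
    resp_complete <- 0
  } else {
    p1 <- stage1_policy(spec, params, state)
    p2 <- stage2_policy(s2, spec, params, state)
    p_obs <- 0
    p_complete <- 0
    p_selected <- 0
    if (spec$traits$has_single) p_obs <- p_obs + p1[[a1]] * p2[[a2]]
    if (spec$traits$has_seq) {
      sq <- seq_of_a1(a1)
      p_int <- params[["p_int"]]
      p_complete <- p1[[sq]] * (1 - p_int) * as.numeric(a2 == seq_second(sq))
      p_selected <- p_complete + p1[[sq]] * p_int * p2[[a2]]
      p_obs <- p_obs + p_selected
    }
    resp <- if (p_obs > 0) p_selected / p_obs else 0
    resp_complete <- if (p_obs > 0) p_complete / p_obs else 0
  }
  if (p_obs <= 0) {
    cond <- structure(
      class = c("twostagerl_impossible_observation", "error", "condition"),
      list(message = sprintf(
        "observed (a1=%s, s2=%s, a2=%s) has probability 0 under spec %s (set eps > 0 or p_int > 0)",
        a1, s2, a2, spec$id), call = sys.call(-1)))
    stop(cond)
  }
  list(loglik = log(p_obs), resp_seq = resp, resp_complete = resp_complete,
       p1 = p1, p2 = p2)
}

#' Update the agent state after a completed trial
#'
#' Applies the family's learning rules with reward `r`:
#' stage-2 delta rule `Q2[s2, a2] += alpha2 * (r - Q2)`; SARSA-style
#' stage-1 cached update with eligibility `lam`,
#' `Q1mf[a1] += alpha1 * (Q2_pre - Q1mf) + alpha1 * lam * (r - Q2_pre)`
#' (using the pre-update stage-2 value); transition estimate
#' `T[a1, s2] += alpha_T * (1 - T[a1, s2])` with the complementary entry
#' keeping the row normalised; responsibility-weighted sequence update
#' `Qseq += resp_seq * alpha_seq * (r - Qseq)`, where `resp_seq` is the
#' (posterior) probability that the sequence was the option selected at
#' stage 1 -- reward is credited to the selected option whether or not its
#' execution was interrupted. The flat agent treats each
#' press as a choice from one merged state with immediate feedback: the
#' stage-1 press is followed by nothing (`target 0`), the stage-2 press by
#' the reward. Only structures the family uses are touched.
#'
#' @param state Agent state.
#' @param trial As in [trial_loglik()].
#' @param resp_seq Sequence-selection responsibility from [trial_loglik()]
#'   (1/0 when the mode is known, as in simulation).
#' @inheritParams stage1_values
#' @return The updated state.
#' @export
update_state <- function(state, trial, resp_seq, spec, params) {
  a1 <- trial$a1; s2 <- trial$s2; a2 <- trial$a2
  r <- as.numeric(trial$outcome)
  tr <- spec$traits
  if (tr$is_flat) {
    a1rate <- params[["alpha1"]]
    state$Qflat[a1] <- state$Qflat[a1] + a1rate * (0 - state$Qflat[a1])
    state$Qflat[a2] <- state$Qflat[a2] + a1rate * (r - state$Qflat[a2])
    return(state)
  }
  q2_pre <- state$Q2[s2, a2]
  state$Q2[s2, a2] <- q2_pre + params[["alpha2"]] * (r - q2_pre)
  if (tr$uses_mf) {
    state$Q1mf[a1] <- state$Q1mf[a1] +
      params[["alpha1"]] * (q2_pre - state$Q1mf[a1]) +
      params[["alpha1"]] * params[["lam"]] * (r - q2_pre)
  }
  if (tr$uses_mb) {
    state$Tmat[a1, s2] <- state$Tmat[a1, s2] +
      params[["alpha_T"]] * (1 - state$Tmat[a1, s2])
    state$Tmat[a1, setdiff(c("S1", "S2"), s2)] <- 1 - state$Tmat[a1, s2]
  }
  if (tr$has_seq) {
    sq <- seq_of_a1(a1)
    state$Qseq[sq] <- state$Qseq[sq] +
      resp_seq * params[["alpha_seq"]] * (r - state$Qseq[sq])
  }
  state
}

#' Log-likelihood of a set of trials (R reference implementation)
#'
#' Walks the trials in order, initialising the agent state once per
#' subject (values persist across a subject's sessions), skipping aborted
#' trials (no likelihood contribution, no update), accumulating
#' [trial_loglik()] and applying [update_state()]
#' with the marginal responsibilities. This is the readable reference path;
#' fitting uses a compiled implementation verified against it.
#'
#' @param spec A [model_spec()].
#' @param params Full parameter vector ([resolve_params()]).
#' @param trials Trial data.frame (see [read_trials()] for the schema),
#'   one or more subjects, ordered by session and trial within subject.
#' @param contingency Contingency orienting the initial transition estimate.
#' @return A list: `loglik` (total over both decisions of every non-aborted
#'   trial), `n_choices` (2 per non-aborted trial), `per_trial` log-lik.
#' @export
session_loglik <- function(spec, params, trials,
                           contingency = c(L = "S2", R = "S1")) {
  ll <- numeric(nrow(trials))
  ll[] <- NA_real_
  key_prev <- NULL
  state <- NULL
  for (i in seq_len(nrow(trials))) {
    key <- as.character(trials$subject[i])
    if (!identical(key, key_prev)) {
      state <- init_agent_state(spec, params, contingency)
      key_prev <- key
    }
    if (trials$aborted[i] == 1) next
    tl <- trial_loglik(trials[i, ], spec, params, state)
    ll[i] <- tl$loglik
    state <- update_state(state, trials[i, ], tl$resp_seq, spec, params)
  }
  list(loglik = sum(ll, na.rm = TRUE),
       n_choices = 2L * sum(trials$aborted == 0),
       per_trial = ll)
}

# ---- agents used by the simulator -------------------------------------

#' Reinforcement-learning agent for simulation
#'
#' Wraps a [model_spec()] and parameter set into an agent that can act in
#' [run_session()]. The agent samples a stage-1 option from its policy; if
#' it selects a sequence it commits to the second press unless the sequence
#' is interrupted (probability `p_int`), in which case the stage-2 policy
#' takes over.
#'
#' By default learning weights the sequence-value update by the *marginal*
#' responsibility that a sequence was selected given the observable
#' actions, exactly as the fitted likelihood does -- the latent mode is
#' treated as unobserved by the credit-assignment process itself, so the
#' simulator and the likelihood describe the same generative model.
#' `updates = "hard"` instead uses the agent's actual mode (0/1 weights),
#' for sensitivity analyses.
#'
#' @param spec A [model_spec()].
#' @param params Full parameter vector; defaults to [default_params()].
#' @param contingency Contingency orienting the initial transition
#'   estimate at construction (and on [agent_reset()]).
#' @param updates `"marginal"` (default) or `"hard"` sequence-value
#'   updates.
#' @return An agent object.
#' @export
rl_agent <- function(spec, params = default_params(spec),
                     contingency = c(L = "S2", R = "S1"),
                     updates = c("marginal", "hard")) {
  structure(list(spec = spec, params = params, contingency = contingency,
                 updates = match.arg(updates),
                 state = init_agent_state(spec, params, contingency)),
            class = c("rl_agent", "twostagerl_agent"))
}

#' Scripted oracle agent
#'
#' Always takes the stage-1 action whose common stage-2 state is the
#' currently rewarding state, and the discriminative stage-2 action. Used
#' to probe task dynamics (e.g. it earns an outcome on every trial of a
#' deterministic training session).
#'
#' @param contingency The session's stage-1 contingency.
#' @return An agent object.
#' @export
oracle_agent <- function(contingency = c(L = "S2", R = "S1")) {
  structure(list(contingency = contingency),
            class = c("oracle_agent", "twostagerl_agent"))
}

#' Uniformly random agent
#'
#' Picks both presses uniformly at random; useful as a behavioural floor.
#'
#' @return An agent object.
#' @export
random_agent <- function() {
  structure(list(), class = c("random_agent", "twostagerl_agent"))
}

#' Agent protocol used by the session loop
#'
#' [run_session()] drives any agent through three generics: `agent_reset`
#' (called at session start; learning agents re-initialise their state),
#' `agent_act1` (returns the stage-1 press, the selected option, and -- for
#' uninterrupted sequences -- the committed second press), `agent_act2`
#' (the stage-2 press given the reached state) and `agent_learn` (state
#' update from the completed trial). Scripted agents receive the current
#' rewarding state in `agent_act1` so task dynamics can be probed with
#' known behaviour.
#'
#' @param agent An agent object.
#' @param rewarding Currently rewarding stage-2 state (scripted agents may
#'   use it; learning agents must not).
#' @param s2 Stage-2 state reached.
#' @param act1 The list returned by `agent_act1`.
#' @param a2 Stage-2 action taken.
#' @param r Outcome (0/1).
#' @name agent-protocol
NULL

#' @rdname agent-protocol
#' @export
agent_act1 <- function(agent, rewarding) UseMethod("agent_act1")
#' @rdname agent-protocol
#' @export
agent_act2 <- function(agent, s2, act1) UseMethod("agent_act2")
#' @rdname agent-protocol
#' @export
agent_learn <- function(agent, act1, s2, a2, r) UseMethod("agent_learn")
#' @rdname agent-protocol
#' @param config The session's [task_config()] (learning agents orient
#'   their initial transition estimate to its contingency).
#' @export
agent_reset <- function(agent, config) UseMethod("agent_reset")

#' @export
agent_reset.twostagerl_agent <- function(agent, config) agent

#' @export
agent_reset.rl_agent <- function(agent, config) {
  agent$contingency <- config$contingency
  agent$state <- init_agent_state(agent$spec, agent$params, agent$contingency)
  agent
}

#' @export
agent_act1.rl_agent <- function(agent, rewarding) {
  p1 <- stage1_policy(agent$spec, agent$params, agent$state)
  opt <- sample(names(p1), 1L, prob = p1)
  if (opt %in% c("LR", "RL")) {
    interrupted <- stats::runif(1) < agent$params[["p_int"]]
    list(a1 = substr(opt, 1, 1), option = opt, mode = "seq",
         committed_a2 = if (interrupted) NA_character_ else seq_second(opt))
  } else {
    list(a1 = opt, option = opt, mode = "single", committed_a2 = NA_character_)
  }
}

#' @export
agent_act2.rl_agent <- function(agent, s2, act1) {
  if (!is.na(act1$committed_a2)) return(act1$committed_a2)
  state <- agent$state
  if (agent$spec$traits$is_flat) {
    # the stage-1 press has already been devalued when the choice is made
    state$Qflat[act1$a1] <- state$Qflat[act1$a1] +
      agent$params[["alpha1"]] * (0 - state$Qflat[act1$a1])
  }
  p2 <- stage2_policy(s2, agent$spec, agent$params, state)
  sample(names(p2), 1L, prob = p2)
}

#' @export
agent_learn.rl_agent <- function(agent, act1, s2, a2, r) {
  trial <- list(a1 = act1$a1, s2 = s2, a2 = a2, outcome = r)
  resp <- if (!agent$spec$traits$has_seq) {
    0
  } else if (identical(agent$updates, "hard")) {
    as.numeric(act1$mode == "seq")
  } else {
    tryCatch(
      trial_loglik(trial, agent$spec, agent$params, agent$state)$resp_seq,
      twostagerl_impossible_observation = function(e) {
        as.numeric(act1$mode == "seq")
      })
  }
  agent$state <- update_state(agent$state, trial, resp,
                              agent$spec, agent$params)
  agent
}

#' @export
agent_act1.oracle_agent <- function(agent, rewarding) {
  inv <- stats::setNames(names(agent$contingency), agent$contingency)
  list(a1 = inv[[rewarding]], option = inv[[rewarding]], mode = "single",
       committed_a2 = NA_character_)
}

#' @export
agent_act2.oracle_agent <- function(agent, s2, act1) discriminative_action(s2)

#' @export
agent_learn.oracle_agent <- function(agent, act1, s2, a2, r) agent

#' @export
agent_act1.random_agent <- function(agent, rewarding) {
  list(a1 = sample(c("L", "R"), 1L), option = NA_character_, mode = "single",
       committed_a2 = NA_character_)
}

#' @export
agent_act2.random_agent <- function(agent, s2, act1) sample(c("L", "R"), 1L)

#' @export
agent_learn.random_agent <- function(agent, act1, s2, a2, r) agent
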