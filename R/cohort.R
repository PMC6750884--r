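#' Draw simulation parameters for a model specification
#'
#' Per-subject generating parameters for synthetic cohorts: learning rates
#' and the eligibility weight from `Beta(3, 3)` (mid-range, non-degenerate
#' learning), inverse temperatures from a log-normal with median 3 (sdlog
#' 0.4; decisive but stochastic choice), interruption probability from
#' `Beta(2, 8)` (sequences usually run to completion), hybrid weight from
#' `Beta(2, 2)`, discrimination bias from `N(1, 0.5)`, lapse from
#' `0.5 * Beta(1, 9)`.
#'
#' @param spec A [model_spec()].
#' @return Named numeric vector over the spec's free parameters (natural
#'   scale), usable with [resolve_params()].
#' @export
draw_params <- function(spec) {
  draw1 <- function(name) {
    base <- sub("[0-9]+$", "", name)
    switch(base,
           alpha = , alpha_seq = , alpha_T = , lam = stats::rbeta(1, 3, 3),
           beta = stats::rlnorm(1, log(3), 0.4),
           p_int = stats::rbeta(1, 2, 8),
           w = stats::rbeta(1, 2, 2),
           b_disc = stats::rnorm(1, 1, 0.5),
           eps = 0.5 * stats::rbeta(1, 1, 9),
           stop("no sampling rule for parameter ", name))
  }
  stats::setNames(vapply(spec$params$name, draw1, 0), spec$params$name)
}

#' Developmental regime: which controller generates each session
#'
#' Emulates the developmental shift seen across training -- early sessions
#' governed by a flat single-stage controller (repeat the press most
#' proximal to reward), later sessions by a hierarchical model-based
#' controller -- as either a hard switch at session `k_switch` or a
#' gradual per-trial mixture whose flat-controller weight decays across
#' sessions. This is an emulation device for testing the analysis
#' pipeline, not a mechanistic claim.
#'
#' @param k_switch Hard switch: sessions `1..k_switch` use `before`, later
#'   sessions use `after`.
#' @param weight_schedule Gradual mixture: a function mapping the session
#'   index to the per-trial probability (in `[0,1]`) that the flat
#'   controller takes the trial. Exactly one of `k_switch` /
#'   `weight_schedule` must be given.
#' @param before,after Family names for the early and late controller.
#' @return An object of class `regime`.
#' @examples
#' developmental_mixture(k_switch = 10)
#' developmental_mixture(weight_schedule = function(i) exp(-i / 8))
#' @export
developmental_mixture <- function(k_switch = NULL, weight_schedule = NULL,
                                  before = "FLAT", after = "H-MB") {
  if (is.null(k_switch) == is.null(weight_schedule)) {
    stop("give exactly one of k_switch or weight_schedule")
  }
  before <- match.arg(before, FAMILIES)
  after <- match.arg(after, FAMILIES)
  w_fun <- if (!is.null(k_switch)) {
    function(i) as.numeric(i <= k_switch)
  } else {
    function(i) {
      w <- weight_schedule(i)
      if (!is.finite(w) || w < 0 || w > 1) {
        stop("weight_schedule must return values in [0,1]")
      }
      w
    }
  }
  structure(list(before = before, after = after, w_flat = w_fun,
                 hard = !is.null(k_switch), k_switch = k_switch),
            class = "regime")
}

#' Per-trial mixture of two controllers
#'
#' On every trial one of the two wrapped agents is drawn to control both
#' presses (probability `w_flat` for the first agent); both agents learn
#' from every trial -- the controller with its known execution mode, the
#' observer with its marginal sequence responsibility.
#'
#' @param flat,main Two [rl_agent()]s.
#' @param w_flat Probability in `[0,1]` that `flat` controls a trial.
#' @return An agent object usable with [run_session()].
#' @export
mixture_agent <- function(flat, main, w_flat) {
  stopifnot(w_flat >= 0, w_flat <= 1)
  structure(list(flat = flat, main = main, w_flat = w_flat),
            class = c("mixture_agent", "twostagerl_agent"))
}

#' @export
agent_reset.mixture_agent <- function(agent, config) {
  agent$flat <- agent_reset(agent$flat, config)
  agent$main <- agent_reset(agent$main, config)
  agent
}

#' @export
agent_act1.mixture_agent <- function(agent, rewarding) {
  ctrl <- if (stats::runif(1) < agent$w_flat) "flat" else "main"
  act <- agent_act1(agent[[ctrl]], rewarding)
  act$controller <- ctrl
  act
}

#' @export
agent_act2.mixture_agent <- function(agent, s2, act1) {
  agent_act2(agent[[act1$controller]], s2, act1)
}

#' @export
agent_learn.mixture_agent <- function(agent, act1, s2, a2, r) {
  ctrl <- act1$controller
  obs <- setdiff(c("flat", "main"), ctrl)
  agent[[ctrl]] <- agent_learn(agent[[ctrl]], act1, s2, a2, r)
  ob <- agent[[obs]]
  trial <- list(a1 = act1$a1, s2 = s2, a2 = a2, outcome = r)
  resp <- tryCatch(
    trial_loglik(trial, ob$spec, ob$params, ob$state)$resp_seq,
    twostagerl_impossible_observation = function(e) 0)
  ob$state <- update_state(ob$state, trial, resp, ob$spec, ob$params)
  agent[[obs]] <- ob
  agent
}

default_schedule <- function(n_training = 40L, probe_after = c(20L, 30L, 40L),
                             p_common_probe = 0.8) {
  phases <- list()
  done <- 0L
  for (p in probe_after) {
    if (p > done) {
      phases[[length(phases) + 1L]] <-
        list(phase = "training", config = task_config(), n_sessions = p - done)
      done <- p
    }
    phases[[length(phases) + 1L]] <-
      list(phase = "probe", config = task_config(p_common = p_common_probe),
           n_sessions = 1L)
  }
  if (n_training > done) {
    phases[[length(phases) + 1L]] <-
      list(phase = "training", config = task_config(),
           n_sessions = n_training - done)
  }
  phases
}

#' Configuration of a synthetic cohort
#'
#' Describes the cohort the generator simulates: number of subjects, the
#' session schedule (by default 40 deterministic training sessions with an
#' 80/20 probe session inserted after sessions 20 and 30 and at the end,
#' mirroring the mid/end probe placement of the experimental design), and
#' the developmental regime mapping session index to generating
#' controller.
#'
#' @param n_subjects Number of simulated subjects (default 8).
#' @param schedule List of phases, each `list(phase =, config =
#'   task_config(), n_sessions =)`; sessions are numbered consecutively
#'   across phases.
#' @param regime A [developmental_mixture()] (default: hard switch from
#'   `FLAT` to `H-MB` after session 10).
#' @param param_sampler Function `function(spec)` drawing per-subject free
#'   parameters; default [draw_params()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8L, schedule = default_schedule(),
                          regime = developmental_mixture(k_switch = 10L),
                          param_sampler = draw_params) {
  if (!length(schedule)) stop("schedule must be non-empty")
  structure(list(n_subjects = as.integer(n_subjects), schedule = schedule,
                 regime = regime, param_sampler = param_sampler),
            class = "cohort_config")
}

session_plan <- function(schedule) {
  do.call(rbind, lapply(seq_along(schedule), function(i) {
    ph <- schedule[[i]]
    data.frame(phase = ph$phase, block = i, n = ph$n_sessions)
  })) -> blocks
  idx <- rep(seq_len(nrow(blocks)), blocks$n)
  data.frame(session = seq_along(idx), phase = blocks$phase[idx],
             block = blocks$block[idx])
}

derive_seed <- function(master, i, j = 0L) {
  as.integer((as.double(master) * 48271 + i * 7907 + j * 104729) %% 2147483629)
}

#' Generate a full synthetic cohort
#'
#' Simulates every subject through the schedule with the regime's
#' controller: subjects get parameters drawn once per family from the
#' configured sampler, every (subject, session) pair gets a seed derived
#' deterministically from the master seed, and each controller's learned
#' state persists across the subject's sessions. The output carries
#' everything needed to regenerate the data bit-exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed (integer).
#' @return A list: `trials` (all subjects/sessions, trial-log schema plus
#'   the `rewarding` column) and `ground_truth` (per-subject drawn
#'   parameters per family, per-session seeds and generating family/weight,
#'   the master seed).
#' @export
generate_cohort <- function(config, seed = 1L) {
  regime <- config$regime
  spec_before <- model_spec(regime$before)
  spec_after <- model_spec(regime$after)
  plan <- session_plan(config$schedule)
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  params <- lapply(subjects, function(s) {
    ps <- list()
    ps[[regime$before]] <- config$param_sampler(spec_before)
    if (regime$after != regime$before) {
      ps[[regime$after]] <- config$param_sampler(spec_after)
    }
    ps
  })
  names(params) <- subjects

  seeds <- matrix(NA_integer_, config$n_subjects, nrow(plan),
                  dimnames = list(subjects, NULL))
  out <- vector("list", config$n_subjects * nrow(plan))
  k <- 0L
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    ag_before <- rl_agent(spec_before,
                          resolve_params(spec_before, params[[sub]][[regime$before]]))
    ag_after <- rl_agent(spec_after,
                         resolve_params(spec_after, params[[sub]][[regime$after]]))
    for (i in seq_len(nrow(plan))) {
      sseed <- derive_seed(seed, si, i)
      seeds[si, i] <- sseed
      set.seed(sseed)
      w <- regime$w_flat(i)
      agent <- if (w >= 1) ag_before else if (w <= 0) ag_after
               else mixture_agent(ag_before, ag_after, w)
      cfg <- config$schedule[[plan$block[i]]]$config
      res <- run_session(agent, cfg, subject = sub, session = i,
                         phase = plan$phase[i])
      if (inherits(res$agent, "mixture_agent")) {
        ag_before <- res$agent$flat
        ag_after <- res$agent$main
      } else if (w >= 1) ag_before <- res$agent else ag_after <- res$agent
      k <- k + 1L
      out[[k]] <- res$trials
    }
  }
  trials <- do.call(rbind, out[seq_len(k)])
  rownames(trials) <- NULL
  list(trials = trials,
       ground_truth = list(seed = seed, params = params,
                           session_seeds = seeds, plan = plan,
                           regime = regime))
}

#' Simulate a probe-only cohort from one agent family
#'
#' Runs each subject through consecutive probe sessions (default 80/20
#' transitions, 60-outcome cap, reversals at 0.14) until the requested
#' number of trials is reached, with per-subject parameters drawn from
#' [draw_params()] unless supplied. The workhorse behind model recovery,
#' parameter recovery and the behavioural fingerprint analyses.
#'
#' @param spec A [model_spec()] (the generating model).
#' @param n_subjects,n_trials Cohort size and trials per subject.
#' @param p_common Common-transition probability of the probe sessions.
#' @param seed Master seed.
#' @param params Optional list (length `n_subjects`) of named free
#'   parameter vectors; drawn if `NULL`.
#' @return A list: `trials`, `params` (the generating free parameters,
#'   one row per subject).
#' @export
simulate_probe_cohort <- function(spec, n_subjects = 8L, n_trials = 300L,
                                  p_common = 0.8, seed = 1L, params = NULL) {
  cfg <- task_config(p_common = p_common)
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  set.seed(seed)
  if (is.null(params)) params <- lapply(subjects, function(s) draw_params(spec))
  rows <- list()
  for (si in seq_along(subjects)) {
    agent <- rl_agent(spec, resolve_params(spec, params[[si]]))
    got <- 0L
    sess <- 0L
    while (got < n_trials) {
      sess <- sess + 1L
      set.seed(derive_seed(seed, si, sess))
      res <- run_session(agent, cfg, subject = subjects[si], session = sess,
                         phase = "probe")
      agent <- res$agent
      tr <- res$trials
      if (nrow(tr) > n_trials - got) tr <- tr[seq_len(n_trials - got), ]
      rows[[length(rows) + 1L]] <- tr
      got <- got + nrow(tr)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  pmat <- do.call(rbind, lapply(params, function(p) p[spec$params$name]))
  colnames(pmat) <- spec$params$name
  list(trials = trials,
       params = data.frame(subject = subjects, pmat, check.names = FALSE))
}
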