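#' Annotate trials with lagged stay/switch fields
#'
#' Adds the derived per-trial fields the stay-probability analyses use:
#' `reward_prev`, `stay1` (same stage-1 action as the previous trial),
#' `stay2`, `transition_prev`, `same_s2_as_prev`, `correct_disc_prev`
#' (previous stage-2 press was the discriminative action for its state)
#' and, when the data carry the `rewarding` column, `correct_prev`
#' (previous stage-1 action was the one whose common state was rewarding
#' -- the control predictor for reward-function response bias).
#'
#' "Previous trial" always means the immediately preceding *non-aborted*
#' trial within the same session: aborted trials are dropped from the lag
#' chain (they carry `NA` derived fields and never serve as a
#' predecessor), and session boundaries break all lag relationships, so
#' the first usable trial of each session has `NA` lags.
#'
#' @param trials Trial data.frame (see [read_trials()]), ordered by trial
#'   within each subject and session.
#' @param contingency Stage-1 contingency used for `correct_prev`.
#' @return The input with derived columns appended.
#' @export
annotate_trials <- function(trials, contingency = c(L = "S2", R = "S1")) {
  grp <- interaction(trials$subject, trials$session, drop = TRUE)
  for (g in split(seq_len(nrow(trials)), grp)) {
    if (is.unsorted(trials$trial[g], strictly = TRUE)) {
      stop("trials must be strictly ordered by trial index within session")
    }
  }
  n <- nrow(trials)
  out <- trials
  out$reward_prev <- NA_integer_
  out$stay1 <- NA_integer_
  out$stay2 <- NA_integer_
  out$transition_prev <- NA_character_
  out$same_s2_as_prev <- NA_integer_
  out$correct_disc_prev <- NA_integer_
  out$correct_prev <- NA_integer_
  has_rewarding <- "rewarding" %in% names(trials)
  for (g in split(seq_len(n), grp)) {
    usable <- g[trials$aborted[g] == 0]
    if (length(usable) < 2L) next
    cur <- usable[-1L]
    prev <- usable[-length(usable)]
    out$reward_prev[cur] <- as.integer(trials$outcome[prev])
    out$stay1[cur] <- as.integer(trials$a1[cur] == trials$a1[prev])
    out$stay2[cur] <- as.integer(trials$a2[cur] == trials$a2[prev])
    out$transition_prev[cur] <- trials$transition[prev]
    out$same_s2_as_prev[cur] <- as.integer(trials$s2[cur] == trials$s2[prev])
    out$correct_disc_prev[cur] <-
      as.integer(trials$a2[prev] == discriminative_action(trials$s2[prev]))
    if (has_rewarding) {
      out$correct_prev[cur] <-
        as.integer(contingency[trials$a1[prev]] == trials$rewarding[prev])
    }
  }
  attr(out, "annotated") <- TRUE
  out
}

check_annotated <- function(data) {
  if (!all(c("reward_prev", "stay1", "correct_disc_prev") %in% names(data))) {
    stop("data must be passed through annotate_trials() first")
  }
}

#' Stage-1 analysis inclusion filter
#'
#' Drops aborted trials and trials without a usable predecessor
#' (first-of-session), and -- by default -- keeps only trials whose
#' previous trial ended in a correct discrimination (`R` in `S2`, `L` in
#' `S1`). The flag exists because the response-bias control analysis with
#' the `correct` predictor keeps all trials.
#'
#' @param data An annotated trial data.frame ([annotate_trials()]).
#' @param require_correct_disc Keep only trials with
#'   `correct_disc_prev == 1` (default `TRUE`).
#' @return The filtered subset.
#' @export
filter_stage1 <- function(data, require_correct_disc = TRUE) {
  check_annotated(data)
  keep <- data$aborted == 0 & !is.na(data$reward_prev)
  if (require_correct_disc) keep <- keep & data$correct_disc_prev == 1
  data[keep, , drop = FALSE]
}

#' Stage-2 analysis inclusion filter
#'
#' Applies the stage-1 rules and additionally keeps only trials whose
#' stage-2 state differs from the previous trial's (staying on the same
#' stage-2 action in a *different* state is the signature of an executed
#' action sequence).
#'
#' @inheritParams filter_stage1
#' @return The filtered subset.
#' @export
filter_stage2 <- function(data, require_correct_disc = TRUE) {
  out <- filter_stage1(data, require_correct_disc)
  out[out$same_s2_as_prev == 0, , drop = FALSE]
}

build_regression_frame <- function(data, outcome) {
  df <- data.frame(
    y = data[[outcome]],
    reward = data$reward_prev - 0.5,
    subject = factor(data$subject),
    session = factor(data$session))
  if ("transition_prev" %in% names(data)) {
    df$transition <- (data$transition_prev == "common") - 0.5
  }
  if ("stay1" %in% names(data)) df$stay <- data$stay1 - 0.5
  if ("correct_prev" %in% names(data)) df$correct <- data$correct_prev - 0.5
  df
}

per_subject_fallback <- function(df, fixed_rhs) {
  fml <- stats::as.formula(paste("y ~", fixed_rhs))
  coefs <- lapply(split(df, df$subject), function(d) {
    fit <- try(suppressWarnings(stats::glm(fml, binomial(), data = d)),
               silent = TRUE)
    if (inherits(fit, "try-error")) NULL else stats::coef(fit)
  })
  coefs <- do.call(rbind, coefs[!vapply(coefs, is.null, TRUE)])
  est <- colMeans(coefs)
  se <- apply(coefs, 2L, stats::sd) / sqrt(nrow(coefs))
  p <- 2 * stats::pt(-abs(est / se), df = nrow(coefs) - 1L)
  list(term = colnames(coefs), estimate = est, se = se, p = p,
       separation = any(!is.finite(coefs)) || any(abs(coefs) > 15))
}

#' Mixed-effects logistic stay/switch regression
#'
#' Regresses staying on the same action on the previous trial's reward,
#' transition type and/or stage-1 stay, with all fixed effects (including
#' the intercept) also varying randomly across subjects; multi-session
#' analyses additionally nest session within subject. Predictors are
#' effect-coded (+/-0.5: rewarded/common/stay high), so main effects are
#' averages over the other factors and the reward-by-transition
#' interaction is orthogonal to the reward main effect. Confidence
#' intervals are Wald: `estimate +/- 1.96 * SE`.
#'
#' If the mixed fit fails or does not converge, a documented fallback fits
#' per-subject ordinary logistic regressions and summarises the
#' coefficients across subjects (t-based); the result is flagged with
#' `engine = "per_subject"`. Complete separation is flagged, never a
#' silent crash.
#'
#' @param data A filtered, annotated trial data.frame ([filter_stage1()] /
#'   [filter_stage2()]).
#' @param outcome `"stay1"` or `"stay2"`.
#' @param terms Fixed-effect terms from
#'   `{reward, transition, stay, correct, reward:transition, reward:stay}`.
#'   Defaults to the stage-appropriate set: `reward * transition` for
#'   `stay1`, `reward * stay` for `stay2`.
#' @param nested Add session-within-subject random intercepts (use for
#'   multi-session analyses).
#' @param random `"slopes"` (default: all fixed effects vary by subject,
#'   uncorrelated) or `"intercept"` (subject intercepts only).
#' @param engine `"glmer"` (with fallback) or `"per_subject"` directly.
#' @return A `regression_table` data.frame with one row per term:
#'   `estimate` (log-odds), `se`, `ci_lo`, `ci_hi`, `p`; metadata in
#'   attributes (`n`, `n_subjects`, `n_sessions`, `engine`, `converged`,
#'   `random_structure`, `separation`).
#' @export
stay_regression <- function(data, outcome = c("stay1", "stay2"), terms = NULL,
                            nested = FALSE, random = c("slopes", "intercept"),
                            engine = c("glmer", "per_subject")) {
  outcome <- match.arg(outcome)
  random <- match.arg(random)
  engine <- match.arg(engine)
  check_annotated(data)
  if (nrow(data) == 0L) stop("no trials left after filtering")
  if (is.null(terms)) {
    terms <- if (outcome == "stay1") c("reward", "transition", "reward:transition")
             else c("reward", "stay", "reward:stay")
  }
  df <- build_regression_frame(data, outcome)
  df <- df[stats::complete.cases(df[unique(c("y", unlist(strsplit(terms, ":"))))]), ]
  fixed_rhs <- paste(terms, collapse = " + ")
  re <- if (random == "slopes") sprintf("(1 + %s || subject)", fixed_rhs)
        else "(1 | subject)"
  if (nested) re <- paste(re, "+ (1 | subject:session)")
  fml <- stats::as.formula(paste("y ~", fixed_rhs, "+", re))

  res <- NULL
  converged <- FALSE
  used_engine <- engine
  if (engine == "glmer") {
    fit <- try(suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = df, family = stats::binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE)))),
      silent = TRUE)
    if (!inherits(fit, "try-error")) {
      sm <- summary(fit)$coefficients
      conv_ok <- length(fit@optinfo$conv$lme4) == 0 ||
        is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code >= 0
      if (conv_ok && all(is.finite(sm[, "Std. Error"]))) {
        res <- list(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], p = sm[, "Pr(>|z|)"],
                    separation = any(abs(sm[, "Estimate"]) > 15))
        converged <- TRUE
      }
    }
    if (is.null(res)) used_engine <- "per_subject"
  }
  if (is.null(res)) {
    res <- per_subject_fallback(df, fixed_rhs)
    converged <- FALSE
  }
  tab <- data.frame(term = res$term, estimate = unname(res$estimate),
                    se = unname(res$se),
                    ci_lo = unname(res$estimate - 1.96 * res$se),
                    ci_hi = unname(res$estimate + 1.96 * res$se),
                    p = unname(res$p), stringsAsFactors = FALSE)
  attr(tab, "n") <- nrow(df)
  attr(tab, "n_subjects") <- length(unique(df$subject))
  attr(tab, "n_sessions") <- length(unique(df$session))
  attr(tab, "engine") <- used_engine
  attr(tab, "converged") <- converged
  attr(tab, "random_structure") <- re
  attr(tab, "separation") <- isTRUE(res$separation)
  class(tab) <- c("regression_table", "data.frame")
  tab
}

#' @export
print.regression_table <- function(x, ...) {
  cat(sprintf(
    "Stay/switch logistic regression (%s; %d trials, %d subjects%s)\n",
    attr(x, "engine"), attr(x, "n"), attr(x, "n_subjects"),
    if (isTRUE(attr(x, "converged"))) "" else "; NOT converged, fallback used"))
  if (isTRUE(attr(x, "separation"))) cat("  warning: possible separation\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a regression table to CSV
#'
#' @param tab A `regression_table`.
#' @param path Output file path.
#' @export
write_regression_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$n <- attr(tab, "n")
  out$converged <- attr(tab, "converged")
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-session reward effect on stage-1 staying
#'
#' For every session, regresses staying on the same stage-1 action on the
#' previous trial's reward (subject-varying intercept and slope) and
#' returns the reward coefficient -- the log odds ratio of staying after a
#' rewarded versus a non-rewarded trial -- together with the intercept and
#' p-values. Early flat-controller behaviour shows up as negative reward
#' coefficients (repeat the last rewarded *press*, hence switch stage-1
#' action), adaptive two-stage behaviour as positive ones.
#'
#' Sessions with fewer than 2 usable trials, a single reward level, or a
#' degenerate outcome are flagged and skipped.
#'
#' @param trials Trial data.frame (annotated or raw; multi-session).
#' @param require_correct_disc Apply the correct-discrimination inclusion
#'   filter (default `TRUE`).
#' @return A data.frame keyed by session: `session`, `phase`, `n`,
#'   `reward_logodds`, `reward_p`, `intercept`, `intercept_p`,
#'   `converged`, `flagged`.
#' @export
session_stay_profile <- function(trials, require_correct_disc = TRUE) {
  if (is.null(attr(trials, "annotated"))) trials <- annotate_trials(trials)
  sessions <- sort(unique(trials$session))
  rows <- lapply(sessions, function(s) {
    sub <- filter_stage1(trials[trials$session == s, , drop = FALSE],
                         require_correct_disc)
    base <- data.frame(session = s, phase = sub$phase[1] %||% NA_character_,
                       n = nrow(sub), reward_logodds = NA_real_,
                       reward_p = NA_real_, intercept = NA_real_,
                       intercept_p = NA_real_, converged = FALSE,
                       flagged = TRUE, stringsAsFactors = FALSE)
    if (nrow(sub) < 2L || length(unique(sub$reward_prev)) < 2L ||
        length(unique(sub$stay1)) < 2L) {
      return(base)
    }
    tab <- try(stay_regression(sub, "stay1", terms = "reward"), silent = TRUE)
    if (inherits(tab, "try-error")) return(base)
    base$reward_logodds <- tab$estimate[tab$term == "reward"]
    base$reward_p <- tab$p[tab$term == "reward"]
    base$intercept <- tab$estimate[tab$term == "(Intercept)"]
    base$intercept_p <- tab$p[tab$term == "(Intercept)"]
    base$converged <- attr(tab, "converged")
    base$flagged <- isTRUE(attr(tab, "separation"))
    base
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
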