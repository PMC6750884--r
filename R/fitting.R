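TRANSFORM_CODES <- c(identity = 0L, logit = 1L, log = 2L, logit_half = 3L)

to_natural <- function(theta, transforms) {
  out <- theta
  out[transforms == "logit"] <- stats::plogis(theta[transforms == "logit"])
  out[transforms == "log"] <- exp(theta[transforms == "log"])
  out[transforms == "logit_half"] <- 0.5 * stats::plogis(theta[transforms == "logit_half"])
  out
}

to_transformed <- function(x, transforms) {
  out <- x
  out[transforms == "logit"] <- stats::qlogis(x[transforms == "logit"])
  out[transforms == "log"] <- log(x[transforms == "log"])
  out[transforms == "logit_half"] <- stats::qlogis(x[transforms == "logit_half"] / 0.5)
  out
}

make_cpp_spec <- function(spec, priors) {
  slots <- spec$params$slots
  slot_idx <- unlist(lapply(slots, function(s) match(s, PARAM_SLOTS) - 1L))
  slot_ptr <- c(0L, cumsum(vapply(slots, length, 0L)))
  list(is_flat = spec$traits$is_flat, has_single = spec$traits$has_single,
       has_seq = spec$traits$has_seq, uses_mf = spec$traits$uses_mf,
       uses_mb = spec$traits$uses_mb,
       slot_ptr = as.integer(slot_ptr), slots = as.integer(slot_idx),
       transform = unname(TRANSFORM_CODES[priors$transform]),
       prior_mean = priors$prior_mean, prior_sd = priors$prior_sd,
       fixed_full = unname(fixed_param_defaults(spec$traits)))
}

make_cpp_data <- function(trials, contingency = c(L = "S2", R = "S1")) {
  stopifnot(nrow(trials) == 0 || all(trials$a1 %in% c("L", "R")))
  key <- as.character(trials$subject)
  newsess <- if (nrow(trials)) c(TRUE, key[-1L] != key[-length(key)]) else logical()
  list(a1 = match(trials$a1, c("L", "R")) - 1L,
       s2 = match(trials$s2, c("S1", "S2")) - 1L,
       a2 = match(trials$a2, c("L", "R")) - 1L,
       reward = as.integer(trials$outcome),
       newsess = newsess,
       common_state = c(match(contingency[["L"]], c("S1", "S2")) - 1L,
                        match(contingency[["R"]], c("S1", "S2")) - 1L))
}

#' Prior specification for a model's free parameters
#'
#' Priors are placed on the unconstrained fitting scale (logit for rates
#' and probabilities, log for inverse temperatures, identity for the
#' discrimination bias): standard normal by default, `N(0, 2)` for
#' `b_disc`. Override location/scale by name.
#'
#' @param spec A [model_spec()].
#' @param mean,sd Optional named numeric vectors overriding prior location
#'   or scale for specific free parameters (transformed scale).
#' @return A data.frame with columns `name`, `transform`, `prior_mean`,
#'   `prior_sd` (one row per free parameter).
#' @export
prior_spec <- function(spec, mean = NULL, sd = NULL) {
  pr <- spec$params[c("name", "transform", "prior_mean", "prior_sd")]
  if (!is.null(mean)) pr$prior_mean[match(names(mean), pr$name)] <- mean
  if (!is.null(sd)) pr$prior_sd[match(names(sd), pr$name)] <- sd
  if (any(pr$prior_sd <= 0) || any(!is.finite(pr$prior_mean))) {
    stop("priors must be proper: finite means, positive scales")
  }
  pr
}

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in seq(i + 1L, d)) {
      ej <- numeric(d); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' MAP optimisation of a generic objective with Gaussian priors
#'
#' Minimises `negloglik(theta) + neglogprior(theta)` on an unconstrained
#' scale with multiple random restarts drawn from the prior, and returns
#' the curvature at the optimum. This is the core behind [fit_map()]; it
#' is exported so simple conjugate models can exercise the same machinery.
#'
#' @param negloglik Function of the transformed parameter vector returning
#'   a negative log-likelihood (0 for a no-data problem).
#' @param prior_mean,prior_sd Gaussian prior location/scale per parameter
#'   (transformed scale).
#' @param n_restarts Number of optimisation restarts (first start at the
#'   prior mode, the rest drawn from the prior). At least 10 by default.
#' @param seed RNG seed for the restart draws.
#' @param hessian_step Central finite-difference step for the Hessian.
#' @return A list: `theta_hat`, `value` (neg log posterior at optimum),
#'   `nll`, `log_prior`, `hessian`, `hessian_logdet`, `hessian_pd`,
#'   `grad_norm`, `n_restarts`, `seed`, `convergence`.
#' @export
map_optimize <- function(negloglik, prior_mean, prior_sd, n_restarts = 10L,
                         seed = 1L, hessian_step = 1e-4) {
  d <- length(prior_mean)
  obj <- function(theta) {
    nll <- negloglik(theta)
    z <- (theta - prior_mean) / prior_sd
    nll + sum(0.5 * z^2 + log(prior_sd) + 0.5 * log(2 * pi))
  }
  set.seed(seed)
  n_extra <- max(0L, n_restarts - 1L)
  starts <- cbind(prior_mean,
                  matrix(stats::rnorm(d * n_extra, prior_mean, prior_sd),
                         nrow = d, ncol = n_extra))
  best <- NULL
  for (k in seq_len(ncol(starts))) {
    v0 <- try(obj(starts[, k]), silent = TRUE)
    if (inherits(v0, "try-error") || !is.finite(v0)) next
    o <- try(stats::optim(starts[, k], obj, method = "BFGS",
                          control = list(maxit = 300, reltol = 1e-10)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop(structure(class = c("twostagerl_fit_failure", "error", "condition"),
                   list(message = "objective non-finite at every start",
                        call = sys.call(-1))))
  }
  theta_hat <- unname(best$par)
  nll_hat <- negloglik(theta_hat)
  H <- fd_hessian(obj, theta_hat, hessian_step)
  ch <- try(chol(H), silent = TRUE)
  pd <- !inherits(ch, "try-error")
  logdet <- if (pd) 2 * sum(log(diag(ch))) else NA_real_
  list(theta_hat = theta_hat, value = best$value, nll = nll_hat,
       log_prior = -(best$value - nll_hat), hessian = H,
       hessian_logdet = logdet, hessian_pd = pd,
       grad_norm = sqrt(sum(fd_gradient(obj, theta_hat)^2)),
       n_restarts = n_restarts, seed = seed, convergence = best$convergence)
}

#' Fit one model specification to one subject's trials by MAP
#'
#' Maximises log-likelihood plus log-prior on the transformed scale with
#' random restarts, then records the curvature needed for the Laplace
#' model evidence. Aborted trials contribute neither likelihood nor
#' learning. A subject with no usable trials returns the prior mode with
#' `nll = 0` and log evidence 0.
#'
#' @param spec A [model_spec()].
#' @param trials Trial data.frame for one subject (may span sessions;
#'   learned values persist across them).
#' @param priors A [prior_spec()] table (default: the spec's).
#' @param n_restarts,seed Passed to [map_optimize()].
#' @param contingency Contingency orienting the initial transition
#'   estimate.
#' @return An object of class `fit_result`: MAP estimates on both scales,
#'   `nll`, `log_prior`, Hessian log-determinant, `n_choices`,
#'   `log_evidence` (per-subject Laplace), `p_r2`, and diagnostics.
#' @export
fit_map <- function(spec, trials, priors = NULL, n_restarts = 10L, seed = 1L,
                    contingency = c(L = "S2", R = "S1")) {
  if (is.null(priors)) priors <- prior_spec(spec)
  stopifnot(identical(priors$name, spec$params$name))
  cspec <- make_cpp_spec(spec, priors)
  cdata <- make_cpp_data(trials, contingency)
  nll_fn <- function(theta) cpp_neg_log_post(theta, cdata, cspec, FALSE)
  core <- map_optimize(nll_fn, priors$prior_mean, priors$prior_sd,
                       n_restarts = n_restarts, seed = seed)
  n_choices <- if (nrow(trials)) 2L * sum(trials$aborted == 0) else 0L
  est <- to_natural(core$theta_hat, priors$transform)
  names(est) <- priors$name
  fit <- structure(
    c(core,
      list(spec = spec, priors = priors, estimates = est,
           params_hat = resolve_params(spec, est), df = spec$df,
           n_choices = n_choices,
           p_r2 = if (n_choices > 0) pseudo_r2(core$nll, n_choices) else NA_real_)),
    class = "fit_result")
  ev <- laplace_evidence(fit)
  fit$log_evidence <- ev$log_evidence
  fit$evidence_method <- ev$method
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("MAP fit of %s: nll %.2f over %d choices (pseudo-r2 %.3f)\n",
              x$spec$id, x$nll, x$n_choices,
              if (is.na(x$p_r2)) NA else x$p_r2))
  cat(sprintf("  log evidence %.2f (%s), grad norm %.2g, %d restarts\n",
              x$log_evidence, x$evidence_method, x$grad_norm, x$n_restarts))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Laplace-approximated per-subject log model evidence
#'
#' `log p(D|M) ~ -nll + log prior + (d/2) log(2 pi) - (1/2) log|H|`, with
#' `H` the Hessian of the negative log posterior at the MAP on the
#' transformed scale. If the Hessian is not positive definite the evidence
#' falls back to `-nll - (d/2) log(n_choices)` (a BIC-style penalty),
#' flagged in the result. Group evidence is the sum over subjects; a
#' log-Bayes factor between specs is the difference of group log
#' evidences.
#'
#' @param fit A [fit_map()] result (or any list with fields `nll`,
#'   `log_prior`, `hessian_logdet`, `hessian_pd`, `n_choices`).
#' @param d Free-parameter count (defaults to `fit$df` or the length of
#'   `theta_hat`).
#' @return A list with `log_evidence` and `method` (`"laplace"` or
#'   `"bic"`).
#' @export
laplace_evidence <- function(fit, d = NULL) {
  if (is.null(d)) d <- if (!is.null(fit$df)) fit$df else length(fit$theta_hat)
  if (isTRUE(fit$hessian_pd)) {
    list(log_evidence = -fit$nll + fit$log_prior + d / 2 * log(2 * pi) -
           0.5 * fit$hessian_logdet,
         method = "laplace")
  } else {
    n <- max(1L, fit$n_choices)
    list(log_evidence = -fit$nll - d / 2 * log(n), method = "bic")
  }
}

#' Pseudo-r-squared of a choice model
#'
#' `1 - nll / (n_choices * log 2)`: the likelihood improvement over a
#' random-choice model, where `n_choices` counts modelled binary decisions
#' (two per non-aborted trial). 0 at chance, 1 for a perfect model.
#'
#' @param nll Negative log-likelihood at the estimate (nats).
#' @param n_choices Number of modelled binary decisions (> 0).
#' @return Numeric value `<= 1`.
#' @export
pseudo_r2 <- function(nll, n_choices) {
  stopifnot(n_choices > 0)
  1 - nll / (n_choices * log(2))
}

applicable_toggles <- function(family) {
  traits <- family_traits(family)
  c("lapse",
    if (traits$has_seq) "interruption",
    if (traits$uses_mf) "eligibility",
    if (!traits$is_flat) "disc_bias",
    if (!family %in% c("FLAT", "MB")) "separate_rates")
}

#' Enumerate model specifications over a toggle grid
#'
#' Builds the Cartesian product of the supplied toggle settings for a
#' family, deduplicated by spec identity. An empty grid yields the
#' family's base model. Requesting a toggle the family cannot carry (e.g.
#' `interruption` for `MB`) is a spec error.
#'
#' @param family An agent family name.
#' @param grid Named list of logical vectors, e.g.
#'   `list(eligibility = c(FALSE, TRUE))`.
#' @return List of [model_spec()] objects.
#' @export
enumerate_models <- function(family, grid = list()) {
  family <- match.arg(family, FAMILIES)
  if (length(grid)) {
    bad <- setdiff(names(grid), applicable_toggles(family))
    if (length(bad)) {
      stop("toggles inapplicable to family ", family, ": ",
           paste(bad, collapse = ", "))
    }
    settings <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    settings <- data.frame(row.names = 1L)
  }
  specs <- lapply(seq_len(max(1L, nrow(settings))), function(i) {
    args <- as.list(settings[i, , drop = FALSE])
    do.call(model_spec, c(list(family = family), args))
  })
  specs[!duplicated(vapply(specs, `[[`, "", "id"))]
}

#' Fit and compare model specifications across subjects
#'
#' Fits every spec to every subject by MAP, aggregates the per-subject
#' Laplace log evidences into a group negative log model-evidence (sum
#' over subjects) and a mean pseudo-r-squared, marks the best spec per
#' family, and sorts ascending by group negative log evidence (lower is
#' better). Subject-level fit failures are flagged, never raised.
#'
#' @param specs A list of [model_spec()] objects (or a single spec).
#' @param trials Trial data.frame covering all subjects.
#' @param n_restarts,seed Fitting controls; each (spec, subject) pair gets
#'   a deterministic seed derived from `seed`.
#' @param priors Optional function `function(spec)` returning a
#'   [prior_spec()] table.
#' @return An `evidence_table` data.frame: `spec_id`, `family`, `df`,
#'   `group_neg_log_evidence`, `mean_pseudo_r2`, `n_subjects`,
#'   `n_fit_failures`, `best_in_family`; per-subject fits in
#'   `attr(, "fits")`.
#' @export
compare_models <- function(specs, trials, n_restarts = 10L, seed = 1L,
                           priors = NULL) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  subjects <- unique(trials$subject)
  all_fits <- list()
  rows <- lapply(seq_along(specs), function(si) {
    spec <- specs[[si]]
    pr <- if (is.null(priors)) NULL else priors(spec)
    fits <- lapply(seq_along(subjects), function(sj) {
      sub <- trials[trials$subject == subjects[sj], , drop = FALSE]
      fseed <- (seed * 7919L + si * 101L + sj) %% .Machine$integer.max
      tryCatch(fit_map(spec, sub, priors = pr, n_restarts = n_restarts,
                       seed = fseed),
               error = function(e) structure(list(error = conditionMessage(e)),
                                             class = "fit_failure"))
    })
    all_fits[[spec$id]] <<- fits
    ok <- !vapply(fits, inherits, TRUE, "fit_failure")
    data.frame(
      spec_id = spec$id, family = spec$family, df = spec$df,
      group_neg_log_evidence =
        if (all(ok)) -sum(vapply(fits[ok], `[[`, 0, "log_evidence")) else NA_real_,
      mean_pseudo_r2 = mean(vapply(fits[ok], `[[`, 0, "p_r2")),
      n_subjects = length(subjects), n_fit_failures = sum(!ok),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$group_neg_log_evidence), , drop = FALSE]
  best <- !duplicated(tab$family)  # first (lowest) row per family
  tab$best_in_family <- best & is.finite(tab$group_neg_log_evidence)
  rownames(tab) <- NULL
  attr(tab, "fits") <- all_fits
  class(tab) <- c("evidence_table", "data.frame")
  tab
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("Model comparison (group negative log model-evidence; lower is better)\n")
  print.data.frame(x, digits = 5)
  invisible(x)
}

#' Write an evidence table to CSV
#'
#' @param tab An `evidence_table` from [compare_models()].
#' @param path Output file path.
#' @export
write_evidence_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
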