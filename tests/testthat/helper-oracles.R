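# Independent oracles, coded from first principles and kept free of the
# package's own policy/update helpers.

# Brute-force likelihood of an observed trial sequence by exhaustive
# enumeration over every latent-mode assignment (single action /
# sequence-completed / sequence-interrupted per trial). The learned-state
# recursion is deterministic given the observed data (marginal
# responsibility weighting), so the path probabilities share one state
# trajectory; summing the product of per-trial mode probabilities over
# all mode paths must equal the package's likelihood exactly.
brute_force_loglik <- function(traits, par, trials) {
  soft <- function(u, eps) {
    p <- exp(u - max(u)); p <- p / sum(p)
    (1 - eps) * p + eps / length(p)
  }
  disc <- function(s2) if (s2 == "S2") "R" else "L"
  second <- function(a1) if (a1 == "L") "R" else "L"
  q0 <- par[["q0"]]
  Q2 <- matrix(q0, 2, 2, dimnames = list(c("S1", "S2"), c("L", "R")))
  Q1 <- c(L = q0, R = q0)
  Tm <- matrix(c(1 - par[["t_common0"]], par[["t_common0"]],
                 par[["t_common0"]], 1 - par[["t_common0"]]),
               2, 2, byrow = TRUE, dimnames = list(c("L", "R"), c("S1", "S2")))
  Qs <- c(L = q0, R = q0)  # sequence value keyed by its first press
  Qf <- c(L = q0, R = q0)
  n <- nrow(trials)
  # per-trial probability of each latent mode, under the shared state path
  pm <- matrix(0, n, 3, dimnames = list(NULL, c("single", "complete", "interrupt")))
  for (i in seq_len(n)) {
    a1 <- trials$a1[i]; s2 <- trials$s2[i]; a2 <- trials$a2[i]
    r <- trials$outcome[i]
    if (traits$is_flat) {
      p1 <- soft(par[["beta1"]] * Qf, par[["eps"]])
      Qf[a1] <- Qf[a1] * (1 - par[["alpha1"]])
      p2 <- soft(par[["beta1"]] * Qf, par[["eps"]])
      pm[i, "single"] <- p1[[a1]] * p2[[a2]]
      Qf[a2] <- Qf[a2] + par[["alpha1"]] * (r - Qf[a2])
      next
    }
    vals <- c()
    if (traits$has_single) {
      for (a in c("L", "R")) {
        vmb <- if (traits$uses_mb) {
          sum(Tm[a, ] * c(max(Q2["S1", ]), max(Q2["S2", ])))
        } else 0
        vals[a] <- par[["w"]] * vmb + (1 - par[["w"]]) * Q1[[a]]
      }
    }
    if (traits$has_seq) for (a in c("L", "R")) vals[paste0("seq", a)] <- Qs[[a]]
    p1 <- soft(par[["beta1"]] * vals, par[["eps"]])
    u <- par[["beta2"]] * Q2[s2, ]
    u[disc(s2)] <- u[disc(s2)] + par[["b_disc"]]
    p2 <- soft(u, par[["eps"]])
    if (traits$has_single) pm[i, "single"] <- p1[[a1]] * p2[[a2]]
    if (traits$has_seq) {
      ps <- p1[[paste0("seq", a1)]]
      pm[i, "complete"] <- ps * (1 - par[["p_int"]]) * (a2 == second(a1))
      pm[i, "interrupt"] <- ps * par[["p_int"]] * p2[[a2]]
    }
    # data-deterministic updates (marginal responsibility for the sequence)
    ptot <- sum(pm[i, ])
    resp <- if (ptot > 0) (pm[i, "complete"] + pm[i, "interrupt"]) / ptot else 0
    q2pre <- Q2[s2, a2]
    Q2[s2, a2] <- q2pre + par[["alpha2"]] * (r - q2pre)
    if (traits$uses_mf) {
      Q1[a1] <- Q1[[a1]] + par[["alpha1"]] * (q2pre - Q1[[a1]]) +
        par[["alpha1"]] * par[["lam"]] * (r - q2pre)
    }
    if (traits$uses_mb) {
      Tm[a1, s2] <- Tm[a1, s2] + par[["alpha_T"]] * (1 - Tm[a1, s2])
      Tm[a1, setdiff(c("S1", "S2"), s2)] <- 1 - Tm[a1, s2]
    }
    if (traits$has_seq) Qs[a1] <- Qs[[a1]] + resp * par[["alpha_seq"]] * (r - Qs[[a1]])
  }
  # enumerate every mode path and sum the path products
  mode_opts <- rep(list(c(if (traits$has_single || traits$is_flat) 1L,
                          if (traits$has_seq) 2:3)), n)
  paths <- expand.grid(mode_opts)
  total <- 0
  for (k in seq_len(nrow(paths))) {
    total <- total + prod(pm[cbind(seq_len(n), as.integer(paths[k, ]))])
  }
  log(total)
}

# Random small trial sets; any action/state/outcome combination (aborted
# trials excluded), so the likelihood must marginalise correctly even for
# observations the agent would rarely produce.
random_trials <- function(n) {
  data.frame(subject = "s1", session = 1L, phase = "probe",
             trial = seq_len(n) - 1L,
             a1 = sample(c("L", "R"), n, TRUE),
             s2 = sample(c("S1", "S2"), n, TRUE),
             a2 = sample(c("L", "R"), n, TRUE),
             outcome = sample(0:1, n, TRUE),
             transition = sample(c("common", "rare"), n, TRUE),
             aborted = 0L, rt = NA_real_, stringsAsFactors = FALSE)
}

# Random parameter draw with every support respected and p_int/eps kept
# positive so all observations have positive probability.
random_free_params <- function(spec) {
  draw <- function(name) {
    base <- sub("[0-9]+$", "", name)
    switch(base,
           alpha = , alpha_seq = , alpha_T = , lam = , w = runif(1),
           beta = runif(1, 0, 8),
           p_int = runif(1, 0.02, 0.98),
           b_disc = rnorm(1, 0, 2),
           eps = runif(1, 0.01, 0.49),
           stop(name))
  }
  stats::setNames(vapply(spec$params$name, draw, 0), spec$params$name)
}

# Closed-form log marginal likelihood of the conjugate Gaussian model
# y_i ~ N(theta, s2), theta ~ N(m0, s02).
gaussian_log_marginal <- function(y, s2, m0, s02) {
  n <- length(y)
  prec <- n / s2 + 1 / s02
  mu <- (sum(y) / s2 + m0 / s02) / prec
  -n / 2 * log(2 * pi * s2) - 0.5 * log(2 * pi * s02) +
    0.5 * log(2 * pi / prec) -
    0.5 * (sum(y^2) / s2 + m0^2 / s02 - mu^2 * prec)
}

make_trials <- function(a1, s2, a2, outcome, aborted = 0L, subject = "s1",
                        session = 1L, transition = NULL) {
  n <- length(a1)
  if (is.null(transition)) {
    cont <- c(L = "S2", R = "S1")
    transition <- ifelse(cont[a1] == s2, "common", "rare")
  }
  data.frame(subject = subject, session = session, phase = "training",
             trial = seq_len(n) - 1L, a1 = a1, s2 = s2, a2 = a2,
             outcome = as.integer(outcome), transition = transition,
             aborted = as.integer(aborted), rt = NA_real_,
             stringsAsFactors = FALSE)
}
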