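test_that("pseudo-r2 anchors at chance, perfection and the midpoint", {
  n <- 40L
  expect_equal(pseudo_r2(n * log(2), n), 0)
  expect_equal(pseudo_r2(0, n), 1)
  expect_equal(pseudo_r2(0.5 * n * log(2), n), 0.5)
  expect_error(pseudo_r2(1, 0))
})

test_that("MAP of a flat-prior Bernoulli model equals the empirical proportion", {
  k <- 13L; n <- 40L
  nll <- function(theta) {
    p <- plogis(theta)
    -(k * log(p) + (n - k) * log(1 - p))
  }
  core <- map_optimize(nll, prior_mean = 0, prior_sd = 1e6,
                       n_restarts = 10, seed = 1)
  expect_equal(plogis(core$theta_hat), k / n, tolerance = 1e-5)
  expect_lt(core$grad_norm, 1e-3)
})

test_that("Laplace evidence is exact for the conjugate Gaussian model", {
  set.seed(3)
  y <- rnorm(12, 0.4, 0.7)
  s2 <- 0.7^2; m0 <- 0.1; s02 <- 1.3
  nll <- function(theta) sum(0.5 * (y - theta)^2 / s2 + 0.5 * log(2 * pi * s2))
  core <- map_optimize(nll, prior_mean = m0, prior_sd = sqrt(s02),
                       n_restarts = 10, seed = 2)
  ev <- laplace_evidence(c(core, list(df = 1L)))
  expect_identical(ev$method, "laplace")
  expect_equal(ev$log_evidence, gaussian_log_marginal(y, s2, m0, s02),
               tolerance = 1e-8)
})

test_that("Laplace evidence of a 2-parameter agent matches grid quadrature", {
  spec <- model_spec("FLAT")
  set.seed(4)
  co <- simulate_probe_cohort(spec, n_subjects = 1, n_trials = 20, seed = 4)
  fit <- fit_map(spec, co$trials, n_restarts = 10, seed = 5)
  # dense trapezoid quadrature of the 2-d unnormalised posterior
  cdata <- twostagerl:::make_cpp_data(co$trials)
  cspec <- twostagerl:::make_cpp_spec(spec, prior_spec(spec))
  h <- 0.05
  g <- seq(-7, 7, by = h)
  lp <- outer(g, g, Vectorize(function(a, b)
    -twostagerl:::cpp_neg_log_post(c(a, b), cdata, cspec, TRUE)))
  m <- max(lp)
  quad <- m + log(sum(exp(lp - m))) + 2 * log(h)
  expect_equal(fit$log_evidence, quad, tolerance = 0.1)
})

test_that("evidence is invariant to a reparameterisation of the transform", {
  k <- 9L; n <- 30L
  nll_logit <- function(theta) {
    p <- plogis(theta); -(k * log(p) + (n - k) * log(1 - p))
  }
  # same model under theta' = 1.5 * theta with the prior mapped along
  nll_scaled <- function(theta) nll_logit(theta / 1.5)
  e1 <- laplace_evidence(c(map_optimize(nll_logit, 0, 1, 10, seed = 6),
                           list(df = 1L)))
  e2 <- laplace_evidence(c(map_optimize(nll_scaled, 0, 1.5, 10, seed = 7),
                           list(df = 1L)))
  expect_equal(e1$log_evidence, e2$log_evidence, tolerance = 1e-6)
  # and both land on the quadrature value up to the (small) skew error of
  # the Laplace approximation itself
  h <- 1e-3
  g <- seq(-9, 9, by = h)
  dens <- exp(-vapply(g, nll_logit, 0) + dnorm(g, 0, 1, log = TRUE))
  expect_lt(abs(e1$log_evidence - log(sum(dens) * h)), 0.02)
})

test_that("a zero-trial subject returns the prior mode with unit evidence", {
  spec <- model_spec("H-MB")
  fit <- fit_map(spec, empty <- twostagerl:::empty_trials(), seed = 8)
  expect_equal(fit$nll, 0)
  expect_equal(unname(fit$theta_hat), rep(0, spec$df), tolerance = 1e-6)
  expect_equal(fit$log_evidence, 0, tolerance = 1e-6)
  expect_identical(fit$n_choices, 0L)
  expect_true(is.na(fit$p_r2))
})

test_that("simulated parameters are recovered within loose bounds", {
  spec <- model_spec("H-MB")
  gen <- c(alpha = 0.6, beta1 = 3, beta2 = 4, p_int = 0.25)
  co <- simulate_probe_cohort(spec, n_subjects = 1, n_trials = 500, seed = 9,
                              params = list(gen))
  fit <- fit_map(spec, co$trials, n_restarts = 10, seed = 10)
  # 95%-interval-scale agreement via the Laplace curvature
  se <- sqrt(diag(solve(fit$hessian)))
  theta_gen <- twostagerl:::to_transformed(gen, spec$params$transform)
  expect_true(all(abs(fit$theta_hat - theta_gen) < 2.5 * se + 0.3))
})

test_that("fit failures are classed conditions, not silent NaNs", {
  expect_error(map_optimize(function(theta) NaN, 0, 1, n_restarts = 3, seed = 1),
               class = "twostagerl_fit_failure")
})

test_that("the BIC fallback is flagged when curvature is not positive definite", {
  fake <- list(nll = 100, log_prior = -2, hessian_logdet = NA_real_,
               hessian_pd = FALSE, n_choices = 200L, df = 3L)
  ev <- laplace_evidence(fake)
  expect_identical(ev$method, "bic")
  expect_equal(ev$log_evidence, -100 - 1.5 * log(200))
})

test_that("model comparison tables are well-formed and symmetric for duplicates", {
  spec <- model_spec("MB")
  co <- simulate_probe_cohort(spec, n_subjects = 2, n_trials = 120, seed = 11)
  one <- compare_models(spec, co$trials, n_restarts = 5, seed = 12)
  expect_s3_class(one, "evidence_table")
  expect_identical(nrow(one), 1L)
  expect_true(one$best_in_family)

  two <- compare_models(list(spec, model_spec("MB")), co$trials,
                        n_restarts = 5, seed = 13)
  expect_equal(two$group_neg_log_evidence[1], two$group_neg_log_evidence[2],
               tolerance = 1e-4)
  expect_true(!is.unsorted(two$group_neg_log_evidence))
})
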