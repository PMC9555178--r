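test_that("identical seed and config give bit-identical chains for both samplers", {
  ds <- quick_cohort(n = 60)
  pr <- prior_spec(dpm = list(M = 5, alpha_shape = 2, alpha_rate = 2,
                              kappa0 = 0.1, m0 = NULL, a0 = 2, b0 = 1))
  a <- fit_lognormal(ds, pr, quick_config(seed = 3))
  b <- fit_lognormal(ds, pr, quick_config(seed = 3))
  expect_identical(a$draws, b$draws)
  expect_identical(a$deviance, b$deviance)
  c1 <- fit_dpm(ds, pr, quick_config(seed = 4, n_iter = 600, n_burnin = 200))
  c2 <- fit_dpm(ds, pr, quick_config(seed = 4, n_iter = 600, n_burnin = 200))
  expect_identical(c1$draws, c2$draws)
  # a different seed moves the chain
  d <- fit_lognormal(ds, pr, quick_config(seed = 5))
  expect_false(identical(a$draws$theta, d$draws$theta))
})

test_that("retained draw count and deviance recomputation honour the config", {
  ds <- quick_cohort(n = 50)
  cfg <- quick_config(seed = 2, n_iter = 700, n_burnin = 250, thin = 3)
  fit <- fit_lognormal(ds, config = cfg)
  expect_equal(n_draws(fit), floor((700 - 250) / 3))
  for (m in c(1, 37, n_draws(fit)))
    expect_identical(fit$deviance[m],
                     -2 * loglik_total(ds, params_at_draw(fit, m),
                                       fit$min_sojourn))
})

test_that("with all events observed and no frailty the model collapses to Gaussian regression on logs", {
  # single binary covariate entering transition 1 only; OLS is the
  # closed-form limit of the posterior mean under flat priors
  man <- covariate_manifest(cov_binary("x", levels = c(0, 1),
                                       transitions = 1))
  set.seed(61)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t1 <- exp(1.5 + 0.8 * x + rnorm(n, 0, 0.7))
  soj <- exp(1.0 + rnorm(n, 0, 0.5))
  t2 <- t1 + soj
  ds <- scr_dataset(data.frame(subject_id = as.character(1:n),
                               y1 = t1, d1 = 1, y2 = t2, d2 = 1, x = x),
                    man)
  # every subject recurs and dies, so transition 2 is event-free by design
  fit <- suppressWarnings(
    fit_lognormal(ds, config = mcmc_config(n_iter = 3000, n_burnin = 500,
                                           thin = 2, seed = 9,
                                           fix_theta = 0)))
  ols <- stats::lm(log(t1) ~ x)
  bhat <- unname(stats::coef(ols)["x"])
  se <- summary(ols)$coefficients["x", "Std. Error"]
  post_mean <- mean(fit$draws$beta[[1]][, "x:1"])
  expect_lt(abs(post_mean - bhat), 3 * se / sqrt(10))  # MC error margin
  # the error-variance posterior matches its closed-form conditional family:
  # flat (mu, beta) + IG(a, b) prior gives sigma2 | data ~ IG(a + (n-p)/2,
  # b + RSS/2)
  rss <- sum(stats::resid(ols)^2)
  qs <- stats::quantile(fit$draws$sigma2[, 1], c(0.1, 0.25, 0.5, 0.75, 0.9))
  theo <- 1 / stats::qgamma(1 - c(0.1, 0.25, 0.5, 0.75, 0.9),
                            shape = 0.7 + (n - 2) / 2,
                            rate = 0.7 + rss / 2)
  expect_equal(unname(qs), theo, tolerance = 0.04)
})

test_that("the frailty-variance block follows its conjugate inverse-gamma form", {
  # zero-information data: every draw of theta | gamma is IG(a + n/2,
  # b + sum(gamma^2)/2), and the chain's stationary theta marginal is the
  # IG(a, b) prior; here just check the sampled marginal's quantiles
  # against the prior at modest length (the full-length check lives in
  # the acceptance suite)
  man <- covariate_manifest(cov_numeric("x"))
  n <- 4
  ds <- scr_dataset(data.frame(subject_id = as.character(1:n), y1 = 1e-4,
                               d1 = 0, y2 = 1e-4, d2 = 0, x = 0), man)
  pr <- prior_spec(a_theta = 0.7, b_theta = 0.7)
  fit <- suppressWarnings(
    fit_lognormal(ds, pr, mcmc_config(n_iter = 82000, n_burnin = 2000,
                                      thin = 16, seed = 11)))
  probs <- c(0.25, 0.5, 0.75)
  emp <- stats::quantile(fit$draws$theta, probs, names = FALSE)
  theo <- 1 / stats::qgamma(1 - probs, shape = 0.7, rate = 0.7)
  expect_equal(emp, theo, tolerance = 0.12)
  # probability-integral transform of the draws is uniform
  u <- stats::pgamma(1 / fit$draws$theta, 0.7, rate = 0.7,
                     lower.tail = FALSE)
  expect_lt(abs(mean(u) - 0.5), 0.03)
  expect_lt(abs(stats::sd(u) - sqrt(1 / 12)), 0.02)
})

test_that("sparse transitions trigger a warning, not an error", {
  man <- covariate_manifest(cov_numeric("x"))
  ds <- scr_dataset(data.frame(subject_id = as.character(1:8),
                               y1 = 2:9, d1 = 0, y2 = 2:9, d2 = 0, x = 0),
                    man)
  expect_warning(fit_lognormal(ds, config = quick_config(n_iter = 200,
                                                         n_burnin = 50)),
                 "no observed events")
})

test_that("DPM truncation below two components is fatal", {
  ds <- quick_cohort(n = 30)
  expect_error(prior_spec(dpm = list(M = 1, alpha_shape = 2, alpha_rate = 2,
                                     kappa0 = 0.1, m0 = NULL,
                                     a0 = 2, b0 = 1)))
  pr2 <- prior_spec()
  pr2$dpm$M <- 1
  expect_error(fit_dpm(ds, pr2, quick_config()), "at least 2")
})

test_that("DPM on single-normal data concentrates on few clusters and matches the parametric predictive", {
  man <- covariate_manifest(cov_numeric("x"))
  cfg <- simulation_config(
    n = 150, manifest = man, generators = list(x = function(m) rnorm(m)),
    beta = list(b1 = c(x = -0.3), b2 = c(x = 0.2), b3 = c(x = 0)),
    mu = c(3, 4, 2), sigma2 = c(0.8, 0.8, 0.8), theta = 0,
    censoring = c(30, 200))
  ds <- simulate_cohort(cfg, seed = 14)$dataset
  pr <- prior_spec(dpm = list(M = 8, alpha_shape = 2, alpha_rate = 2,
                              kappa0 = 0.1, m0 = NULL, a0 = 2, b0 = 1))
  mc <- mcmc_config(n_iter = 2500, n_burnin = 1000, thin = 3, seed = 6,
                    fix_theta = 0)
  fd <- fit_dpm(ds, pr, mc)
  fl <- fit_lognormal(ds, pr, mc)
  expect_lt(mean(fd$draws$mixture$n_occ[, 1]), 4)
  # posterior-mean error density of transition 1 vs the parametric fit
  grid <- seq(-3, 3, length.out = 61)
  dens_mix <- rowMeans(vapply(seq_len(n_draws(fd)), function(m) {
    mix <- params_at_draw(fd, m)$mixture[[1]]
    vapply(grid, function(u)
      sum(mix$w * stats::dnorm(u, mix$mu, sqrt(mix$sigma2))), numeric(1))
  }, numeric(length(grid))))
  dens_par <- rowMeans(vapply(seq_len(n_draws(fl)), function(m)
    stats::dnorm(grid, mean(0) + fl$draws$mu[m, 1],
                 sqrt(fl$draws$sigma2[m, 1])) , numeric(length(grid))))
  # same support and shape: compare on the common scale of the parametric fit
  expect_lt(max(abs(dens_mix - dens_par)), 0.12)
})

test_that("split-PSRF diagnostics separate healthy and divergent chains", {
  ds <- quick_cohort(n = 60)
  f1 <- fit_lognormal(ds, config = quick_config(seed = 1))
  f2 <- fit_lognormal(ds, config = quick_config(seed = 2))
  dg <- diagnostics(list(f1, f2))
  expect_true(all(c("parameter", "psrf", "ess", "flagged") %in% names(dg)))
  expect_true("theta" %in% dg$parameter)
  # two identical chains: no between-chain component, PSRF stays below the
  # flagging threshold for every parameter (split halves keep a small
  # within-chain drift term)
  dg_same <- diagnostics(list(f1, f1))
  expect_true(all(dg_same$psrf < 1.1))
  expect_true(all(abs(dg_same$psrf - 1) < 0.1))
  # one chain offset by a large constant is flagged
  f3 <- f2
  f3$draws$theta <- f3$draws$theta + 50
  dg_off <- diagnostics(list(f1, f3))
  expect_true(dg_off$flagged[dg_off$parameter == "theta"])
  expect_gt(dg_off$psrf[dg_off$parameter == "theta"], 1.1)
  # unequal chain lengths are fatal
  f4 <- fit_lognormal(ds, config = quick_config(seed = 3, n_iter = 900,
                                                n_burnin = 300))
  expect_error(diagnostics(list(f1, f4)), "unequal length")
})
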