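# craft a minimal one-subject chain whose per-draw likelihoods are known
# in closed form: subject censored for both events at t = 1, no
# covariates; draw 1 has S1(1)S2(1) = 0.25, draw 2 drives S1 -> 1 so the
# likelihood is 0.5 up to ~1e-23
crafted_samples <- function() {
  man <- covariate_manifest(cov_numeric("x"))
  ds <- scr_dataset(data.frame(subject_id = "s1", y1 = 1, d1 = 0, y2 = 1,
                               d2 = 0, x = 0), man)
  draws <- list(
    mu = rbind(c(0, 0, 0), c(40, 0, 0)),
    beta = list(matrix(0, 2, 1, dimnames = list(NULL, "x")),
                matrix(0, 2, 1, dimnames = list(NULL, "x")),
                matrix(0, 2, 1, dimnames = list(NULL, "x"))),
    sigma2 = rbind(c(1, 1, 1), c(1, 1, 1)),
    theta = c(0.1, 0.1), gamma = matrix(0, 2, 1))
  s <- structure(list(model = "lognormal", draws = draws,
                      colnames = list("x", "x", "x"),
                      dropped = list(character(0), character(0), character(0)),
                      n = 1L, subject_id = "s1",
                      priors = prior_spec(), config = NULL, min_sojourn = 0.5,
                      deviance = NULL),
                 class = "posterior_samples")
  s$deviance <- -2 * rowSums(loglik_draws(s, ds))
  list(samples = s, dataset = ds)
}

test_that("CPO is the harmonic mean of per-draw likelihoods, in closed form", {
  cs <- crafted_samples()
  out <- compute_lpml(cs$samples, cs$dataset)
  # harmonic mean of 0.5 and 0.25 is 1/3
  expect_equal(out$cpo, 1 / 3, tolerance = 1e-10)
  expect_equal(out$LPML, log(1 / 3), tolerance = 1e-10)
  expect_identical(out$zero_likelihood_subjects, character(0))
})

test_that("DIC and LPML match an independent two-pass computation on a real chain", {
  ds <- quick_cohort(n = 40)
  fit <- fit_lognormal(ds, config = quick_config(seed = 8, n_iter = 450,
                                                 n_burnin = 150, thin = 3))
  expect_equal(n_draws(fit), 100)
  # --- brute-force pass 1: per-draw deviance from first principles
  S <- n_draws(fit)
  ll <- matrix(NA_real_, S, fit$n)
  for (m in seq_len(S)) {
    p <- params_at_draw(fit, m)
    for (i in seq_len(fit$n)) {
      rec <- as.list(ds$records[i, ])
      xr <- lapply(1:3, function(g) expand_design(ds, g)[i, ])
      ll[m, i] <- loglik_subject(rec, xr, p, frailty = p$gamma[i])
    }
  }
  D_bar <- mean(-2 * rowSums(ll))
  # --- brute-force pass 2: deviance at the posterior-mean state
  pbar <- aft_params(
    beta = list(b1 = stats::setNames(colMeans(fit$draws$beta[[1]]),
                                     fit$colnames[[1]]),
                b2 = stats::setNames(colMeans(fit$draws$beta[[2]]),
                                     fit$colnames[[2]]),
                b3 = stats::setNames(colMeans(fit$draws$beta[[3]]),
                                     fit$colnames[[3]])),
    mu = colMeans(fit$draws$mu), sigma2 = colMeans(fit$draws$sigma2),
    theta = mean(fit$draws$theta), gamma = colMeans(fit$draws$gamma))
  D_hat <- -2 * sum(vapply(seq_len(fit$n), function(i)
    loglik_subject(as.list(ds$records[i, ]),
                   lapply(1:3, function(g) expand_design(ds, g)[i, ]),
                   pbar, frailty = pbar$gamma[i]), numeric(1)))
  dic <- compute_dic(fit, ds)
  expect_equal(dic$D_bar, D_bar, tolerance = 1e-10)
  expect_equal(dic$D_at_mean, D_hat, tolerance = 1e-10)
  expect_equal(dic$pD, D_bar - D_hat, tolerance = 1e-10)
  expect_equal(dic$DIC, 2 * D_bar - D_hat, tolerance = 1e-10)
  # --- brute-force LPML: log-space result equals naive arithmetic on this
  # well-scaled fixture
  cpo_naive <- 1 / colMeans(1 / exp(ll))
  lp <- compute_lpml(fit, ds)
  expect_equal(lp$cpo, cpo_naive, tolerance = 1e-12)
  expect_equal(lp$LPML, sum(log(cpo_naive)), tolerance = 1e-12)
})

test_that("log-space CPO stays finite where naive arithmetic underflows", {
  cs <- crafted_samples()
  s <- cs$samples
  # shift both draws into a regime with likelihoods around exp(-800)
  s$draws$mu[, 1] <- c(-40, -40)
  s$draws$mu[, 2] <- c(-40, -40)
  s$deviance <- -2 * rowSums(loglik_draws(s, cs$dataset))
  out <- compute_lpml(s, cs$dataset)
  expect_true(is.finite(out$LPML))
  expect_lt(out$LPML, -700)
  expect_identical(exp(out$LPML), 0)  # the naive scale has already underflowed
})

test_that("a degenerate chain has zero effective parameters", {
  cs <- crafted_samples()
  s <- cs$samples
  s$draws$mu <- rbind(c(0, 0, 0), c(0, 0, 0))
  s$deviance <- -2 * rowSums(loglik_draws(s, cs$dataset))
  dic <- compute_dic(s, cs$dataset)
  expect_equal(dic$pD, 0, tolerance = 1e-10)
  expect_equal(dic$DIC, dic$D_bar, tolerance = 1e-10)
})

test_that("draw order does not change DIC or LPML", {
  ds <- quick_cohort(n = 30)
  fit <- suppressWarnings(
    fit_lognormal(ds, config = quick_config(seed = 4, n_iter = 400,
                                            n_burnin = 100, thin = 2)))
  perm <- sample(n_draws(fit))
  fitp <- fit
  fitp$draws$mu <- fit$draws$mu[perm, , drop = FALSE]
  fitp$draws$sigma2 <- fit$draws$sigma2[perm, , drop = FALSE]
  fitp$draws$theta <- fit$draws$theta[perm]
  fitp$draws$gamma <- fit$draws$gamma[perm, , drop = FALSE]
  for (g in 1:3)
    fitp$draws$beta[[g]] <- fit$draws$beta[[g]][perm, , drop = FALSE]
  fitp$deviance <- fit$deviance[perm]
  expect_equal(compute_dic(fitp, ds), compute_dic(fit, ds), tolerance = 1e-12)
  expect_equal(compute_lpml(fitp, ds)$LPML, compute_lpml(fit, ds)$LPML,
               tolerance = 1e-12)
})

test_that("model selection follows lowest DIC, with LPML and name tie-breaks", {
  mk <- function(name, dic, lpml)
    list(name = name, DIC = dic, D_bar = dic, D_at_mean = dic, pD = 0,
         LPML = lpml, cpo = numeric(0),
         zero_likelihood_subjects = character(0))
  # the published comparison: log-normal (DIC 1633, LPML -811) beats
  # DPM (DIC 1759, LPML -816)
  sel <- select_model(list(mk("lognormal", 1633, -811),
                           mk("dpm", 1759, -816)))
  expect_identical(sel$selected, "lognormal")
  expect_false(sel$dic_lpml_disagree)
  # equal DICs: higher LPML wins
  sel2 <- select_model(list(mk("A", 100, -60), mk("B", 100, -50)))
  expect_identical(sel2$selected, "B")
  # equal DIC and LPML: first by name order given
  sel3 <- select_model(list(mk("A", 100, -50), mk("B", 100, -50)))
  expect_identical(sel3$selected, "A")
  # disagreement is flagged and DIC governs
  sel4 <- select_model(list(mk("A", 100, -60), mk("B", 120, -40)))
  expect_identical(sel4$selected, "A")
  expect_true(sel4$dic_lpml_disagree)
  expect_error(select_model(list(mk("A", 1, -1))), "at least two")
})
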