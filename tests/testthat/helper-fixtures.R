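# shared fixtures, built in code

fixture_manifest <- function() {
  covariate_manifest(cov_numeric("x1"),
                     cov_binary("x2", levels = c(0, 1)))
}

# five subjects covering all four observation paths (the last has a
# same-month-scale sojourn that exercises the 0.5-month floor)
fixture_records <- function() {
  data.frame(
    subject_id = c("A", "B", "C", "D", "E"),
    y1 = c(7, 12, 30, 55, 10),
    d1 = c(1, 1, 0, 0, 1),
    y2 = c(47, 60, 30, 55, 10.2),
    d2 = c(1, 0, 1, 0, 1),
    x1 = c(0.5, -1.2, 2.0, 0.0, 1.0),
    x2 = c(1, 0, 1, 0, 1),
    stringsAsFactors = FALSE)
}

fixture_dataset <- function() scr_dataset(fixture_records(), fixture_manifest())

fixture_params <- function(gamma = c(0.15, -0.3, 0.05, 0.2, -0.1)) {
  aft_params(
    beta = list(b1 = c(x1 = 0.3, `x2:1` = -0.5),
                b2 = c(x1 = -0.2, `x2:1` = 0.4),
                b3 = c(x1 = 0.6, `x2:1` = 0.1)),
    mu = c(1.2, 2.0, 0.8), sigma2 = c(0.9, 1.44, 0.64),
    theta = 0.25, gamma = gamma)
}

# per-subject log likelihoods for fixture_dataset()/fixture_params(),
# frozen from an independent 50-digit closed-form computation
fixture_oracle_ll <- c(
  -12.37894565739920, -22.23949037676346, -9.31608402370145,
  -8.52874729070720, -8.52435811457625)

# quick small cohort for sampler tests
quick_cohort <- function(n = 120, seed = 42) {
  simulate_cohort(recovery_scenario(n = n), seed = seed)$dataset
}

quick_config <- function(seed = 1, n_iter = 1200, n_burnin = 400, thin = 2,
                         ...) {
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, thin = thin, seed = seed,
              ...)
}

expect_all_valid <- function(dataset) {
  r <- dataset$records
  expect_equal(nrow(dataset$rejected), 0)
  expect_true(all(r$y1 > 0 & r$y2 > 0))
  expect_true(all(r$y1 <= r$y2 + 1e-12))
  expect_true(all(r$d1 %in% c(0, 1) & r$d2 %in% c(0, 1)))
  expect_true(all(r$y1[r$d1 == 0] == r$y2[r$d1 == 0]))
}

# total probability over all outcomes, by quadrature on log scales, using
# only the likelihood under test as density evaluator; a vanishing sojourn
# floor removes the tie-handling convention from the mathematical check
total_path_probability <- function(par, xr, frail, rel.tol = 1e-7) {
  eps <- 1e-12
  # recurrence path: 2-D over (log t1, log sojourn) of f1(t1) S2(t1) f3(s)
  inner <- function(t1) {
    stats::integrate(function(u) {
      s <- exp(u)
      vapply(s, function(si)
        exp(loglik_subject(list(y1 = t1, d1 = 1, y2 = t1 + si, d2 = 1),
                           xr, par, frail, min_sojourn = eps)) * si,
        numeric(1))
    }, lower = -30, upper = 30, rel.tol = rel.tol)$value
  }
  p_rec <- stats::integrate(function(a) {
    t1 <- exp(a)
    vapply(t1, function(t) inner(t) * t, numeric(1))
  }, lower = -30, upper = 30, rel.tol = rel.tol)$value
  # direct path: 1-D over log t2 of S1(t2) f2(t2)
  p_dir <- stats::integrate(function(a) {
    t2 <- exp(a)
    vapply(t2, function(t)
      exp(loglik_subject(list(y1 = t, d1 = 0, y2 = t, d2 = 1),
                         xr, par, frail, min_sojourn = eps)) * t,
      numeric(1))
  }, lower = -30, upper = 30, rel.tol = rel.tol)$value
  p_rec + p_dir
}

# random parameter/frailty settings for the conservation checks
random_conservation_setting <- function() {
  par <- aft_params(
    beta = list(b1 = c(x = stats::rnorm(1)), b2 = c(x = stats::rnorm(1)),
                b3 = c(x = stats::rnorm(1))),
    mu = stats::runif(3, -0.5, 1.5), sigma2 = stats::runif(3, 0.3, 1.5))
  list(par = par,
       xr = list(stats::rnorm(1), stats::rnorm(1), stats::rnorm(1)),
       frail = stats::rnorm(1, 0, 0.4))
}

# exact path-count fixture encoding the printed cohort profile
printed_profile_cohort <- function() {
  n <- 284; n_rec <- 131; n_rec_died <- 105; n_direct <- 16; n_male <- 150
  man <- covariate_manifest(cov_binary("gender", levels = c(1, 2),
                                       labels = c("Female", "Male"),
                                       reference = 1))
  d1 <- c(rep(1, n_rec), rep(0, n - n_rec))
  d2 <- c(rep(1, n_rec_died), rep(0, n_rec - n_rec_died),
          rep(1, n_direct), rep(0, n - n_rec - n_direct))
  y1 <- ifelse(d1 == 1, 7, 46)
  y2 <- ifelse(d1 == 1, ifelse(d2 == 1, 17, 60), 46)
  gender <- rep(c(2, 1), c(n_male, n - n_male))
  scr_dataset(data.frame(subject_id = sprintf("P%03d", 1:n),
                         y1 = y1, d1 = d1, y2 = y2, d2 = d2,
                         gender = gender), man)
}

# hand-generated bimodal-error illness-death cohort (no frailty)
bimodal_cohort <- function(n = 250, seed = 5) {
  man <- covariate_manifest(cov_binary("x", levels = c(0, 1)))
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  reps <- function(m) ifelse(stats::runif(m) < 0.5,
                             stats::rnorm(m, -1.2, 0.3),
                             stats::rnorm(m, 1.2, 0.3))
  mu <- c(3.0, 3.8, 2.0); b <- c(-0.4, -0.3, 0.2)
  T1 <- exp(mu[1] + b[1] * x + reps(n))
  T2 <- exp(mu[2] + b[2] * x + reps(n))
  soj <- exp(mu[3] + b[3] * x + reps(n))
  C <- stats::runif(n, 20, 150)
  y1 <- y2 <- numeric(n); d1 <- d2 <- numeric(n)
  for (i in seq_len(n)) {
    if (T1[i] < T2[i]) {
      if (T1[i] > C[i]) y1[i] <- y2[i] <- C[i]
      else {
        y1[i] <- T1[i]; d1[i] <- 1
        td <- T1[i] + soj[i]
        if (td <= C[i]) { y2[i] <- td; d2[i] <- 1 } else y2[i] <- C[i]
      }
    } else {
      if (T2[i] <= C[i]) { y1[i] <- y2[i] <- T2[i]; d2[i] <- 1 }
      else y1[i] <- y2[i] <- C[i]
    }
  }
  scr_dataset(data.frame(subject_id = as.character(seq_len(n)),
                         y1 = y1, d1 = d1, y2 = y2, d2 = d2, x = x), man)
}
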