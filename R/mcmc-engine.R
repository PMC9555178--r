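#' MCMC run configuration
#'
#' All sampler blocks (data augmentation, transition regressions, error
#' variances / mixture components, frailties, frailty variance) are
#' conjugate Gibbs updates, so there are no proposal scales to tune.
#'
#' @param n_iter total sweeps.
#' @param n_burnin discarded initial sweeps (`n_iter > n_burnin >= 0`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer RNG seed; identical `(data, priors, config)` give
#'   bit-identical chains.
#' @param fix_theta `NULL` to sample the frailty variance, or a fixed
#'   value (0 collapses the model to independent transitions).
#' @return an `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000, n_burnin = 10000, thin = 5,
                        seed = 1L, fix_theta = NULL) {
  stopifnot(n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  if (!is.null(fix_theta)) stopifnot(fix_theta >= 0)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), fix_theta = fix_theta),
            class = "mcmc_config")
}

# drop design columns that are constant or collinear (QR pivoting, as lm
# does for aliased terms); intercept is appended by the caller afterwards
drop_aliased <- function(X) {
  if (ncol(X) == 0L) return(list(X = X, dropped = character(0)))
  q <- qr(cbind(`(Intercept)` = 1, X))
  keep <- sort(q$pivot[seq_len(q$rank)])
  keep <- setdiff(keep, 1L) - 1L
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  list(X = X[, keep, drop = FALSE], dropped = dropped)
}

# augmented-data bounds shared by both samplers: z1/z2 on the log event
# clocks, z3 on the log sojourn clock for recurrence-path subjects
prepare_augmentation <- function(dataset, min_sojourn) {
  r <- dataset$records
  list(
    lo1 = log(r$y1),
    obs1 = as.integer(r$d1 == 1),
    lo2 = ifelse(r$d1 == 1, log(r$y1), log(r$y2)),
    obs2 = as.integer(r$d1 == 0 & r$d2 == 1),
    lo3 = ifelse(r$d1 == 1, log(pmax(r$y2 - r$y1, min_sojourn)), 0),
    obs3 = as.integer(r$d2 == 1),
    idx3 = which(r$d1 == 1) - 1L)
}

prepare_designs <- function(dataset) {
  out <- lapply(1:3, function(g) drop_aliased(expand_design(dataset, g)))
  list(X = lapply(out, `[[`, "X"), dropped = lapply(out, `[[`, "dropped"))
}

colnames0 <- function(X) {
  cn <- colnames(X)
  if (is.null(cn)) character(0) else cn
}

default_inits <- function(dataset, aug) {
  r <- dataset$records
  z1 <- log(r$y1)[aug$obs1 == 1]
  z2 <- log(r$y2)[aug$obs2 == 1]
  z3 <- aug$lo3[r$d1 == 1 & r$d2 == 1]
  mu0 <- c(if (length(z1)) mean(z1) else mean(aug$lo1),
           if (length(z2)) mean(z2) else mean(aug$lo2),
           if (length(z3)) mean(z3) else 0)
  s0 <- c(if (length(z1) > 1) stats::var(z1) else 1,
          if (length(z2) > 1) stats::var(z2) else 1,
          if (length(z3) > 1) stats::var(z3) else 1)
  s0[!is.finite(s0) | s0 <= 0] <- 1
  list(mu = mu0, sigma2 = s0)
}

warn_sparse_events <- function(dataset) {
  r <- dataset$records
  ev <- c(sum(r$d1), sum(r$d1 == 0 & r$d2 == 1), sum(r$d1 == 1 & r$d2 == 1))
  for (g in which(ev == 0))
    warning("no observed events for transition ", g,
            "; the corresponding regression is prior-driven", call. = FALSE)
}

new_posterior_samples <- function(model, draws, colnames3, dropped, dataset,
                                  priors, config, min_sojourn) {
  obj <- structure(list(
    model = model, draws = draws, colnames = colnames3, dropped = dropped,
    n = nrow(dataset$records), subject_id = dataset$records$subject_id,
    priors = priors, config = config, min_sojourn = min_sojourn,
    acceptance = list(augmentation = 1, regression = 1, variance = 1,
                      frailty = 1, frailty_variance = 1),
    deviance = NULL), class = "posterior_samples")
  obj$deviance <- -2 * rowSums(loglik_draws(obj, dataset))
  obj
}

#' Number of retained draws
#' @param samples a `posterior_samples` object.
#' @export
n_draws <- function(samples) length(samples$draws$theta)

#' Extract the parameter state of one retained draw
#'
#' @param samples a `posterior_samples` object.
#' @param m draw index.
#' @return an [aft_params()] reproducing draw `m` exactly.
#' @export
params_at_draw <- function(samples, m) {
  d <- samples$draws
  beta <- lapply(1:3, function(g)
    stats::setNames(d$beta[[g]][m, ], samples$colnames[[g]]))
  names(beta) <- c("b1", "b2", "b3")
  if (samples$model == "lognormal") {
    aft_params(beta = beta, mu = d$mu[m, ], sigma2 = d$sigma2[m, ],
               theta = d$theta[m], gamma = d$gamma[m, ])
  } else {
    mixture <- lapply(1:3, function(g) {
      w <- d$mixture$w[[g]][m, ]
      list(w = w / sum(w), mu = d$mixture$mu[[g]][m, ],
           sigma2 = d$mixture$sigma2[[g]][m, ])
    })
    aft_params(beta = beta, mu = c(0, 0, 0), sigma2 = c(1, 1, 1),
               theta = d$theta[m], gamma = d$gamma[m, ], mixture = mixture)
  }
}

#' Per-draw, per-subject observed-data log likelihood
#'
#' @param samples a `posterior_samples` object.
#' @param dataset the dataset the samples were fitted to.
#' @return matrix (draws x subjects) of conditional log likelihoods; row
#'   sums times -2 are the stored per-draw deviances.
#' @export
loglik_draws <- function(samples, dataset) {
  S <- n_draws(samples)
  out <- matrix(NA_real_, S, nrow(dataset$records))
  for (m in seq_len(S))
    out[m, ] <- loglik_by_subject(dataset, params_at_draw(samples, m),
                                  samples$min_sojourn)
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %s model, %d draws (n_iter %d, burn-in %d, thin %d), n = %d\n",
              x$model, n_draws(x), x$config$n_iter, x$config$n_burnin,
              x$config$thin, x$n))
  cat(sprintf("  theta posterior median %.3f; mean deviance %.1f\n",
              stats::median(x$draws$theta), mean(x$deviance)))
  invisible(x)
}

#' Fit the log-normal AFT illness-death model by Gibbs sampling
#'
#' Data augmentation draws every censored log time from its truncated
#' normal full conditional; given complete data, each transition's
#' `(mu_g, beta_g)` has a conjugate normal full conditional (flat prior),
#' `sigma2_g` an inverse-gamma one, each frailty a normal one, and the
#' frailty variance `theta ~ IG(a + n/2, b + sum(gamma^2)/2)`.
#'
#' @param dataset a validated [scr_dataset()].
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param min_sojourn sojourn floor in months (see [loglik_subject()]).
#' @return a `posterior_samples` object with per-draw deviance.
#' @export
fit_lognormal <- function(dataset, priors = prior_spec(),
                          config = mcmc_config(), min_sojourn = 0.5) {
  stopifnot(inherits(dataset, "scr_dataset"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  warn_sparse_events(dataset)
  aug <- prepare_augmentation(dataset, min_sojourn)
  des <- prepare_designs(dataset)
  ini <- default_inits(dataset, aug)
  fix <- !is.null(config$fix_theta)
  set.seed(config$seed)
  raw <- .gibbs_lognormal(
    cbind(1, des$X[[1]]), cbind(1, des$X[[2]]), cbind(1, des$X[[3]]),
    aug$lo1, aug$lo2, aug$lo3, aug$obs1, aug$obs2, aug$obs3, aug$idx3,
    priors$a_theta, priors$b_theta, priors$a_sigma, priors$b_sigma,
    config$n_iter, config$n_burnin, config$thin,
    fix, if (fix) config$fix_theta else 0, ini$mu, ini$sigma2,
    if (fix) config$fix_theta else 0.1)
  draws <- list(
    mu = cbind(raw$beta1[, 1], raw$beta2[, 1], raw$beta3[, 1]),
    beta = list(raw$beta1[, -1, drop = FALSE], raw$beta2[, -1, drop = FALSE],
                raw$beta3[, -1, drop = FALSE]),
    sigma2 = raw$sigma2, theta = as.numeric(raw$theta), gamma = raw$gamma)
  for (g in 1:3) colnames(draws$beta[[g]]) <- colnames0(des$X[[g]])
  new_posterior_samples("lognormal", draws,
                        lapply(des$X, colnames0), des$dropped,
                        dataset, priors, config, min_sojourn)
}

#' Fit the DPM AFT illness-death model
#'
#' Replaces each transition's single normal error with a truncated
#' stick-breaking Dirichlet process mixture of at most `M` normals;
#' extra Gibbs blocks update cluster assignments (multinomial, ties to
#' the lowest index), stick weights (beta), cluster location/variance
#' pairs (conjugate normal-inverse-gamma) and the concentration
#' parameter (gamma, conjugate under the truncated stick representation).
#' All other blocks are as in [fit_lognormal()].
#'
#' @inheritParams fit_lognormal
#' @return a `posterior_samples` object (model `"dpm"`).
#' @export
fit_dpm <- function(dataset, priors = prior_spec(), config = mcmc_config(),
                    min_sojourn = 0.5) {
  stopifnot(inherits(dataset, "scr_dataset"), inherits(priors, "prior_spec"),
            inherits(config, "mcmc_config"))
  if (priors$dpm$M < 2)
    stop("DPM truncation level M must be at least 2; use fit_lognormal for a single normal")
  warn_sparse_events(dataset)
  aug <- prepare_augmentation(dataset, min_sojourn)
  des <- prepare_designs(dataset)
  ini <- default_inits(dataset, aug)
  m0 <- if (is.null(priors$dpm$m0)) ini$mu else rep_len(priors$dpm$m0, 3)
  fix <- !is.null(config$fix_theta)
  set.seed(config$seed)
  raw <- .gibbs_dpm(
    des$X[[1]], des$X[[2]], des$X[[3]],
    aug$lo1, aug$lo2, aug$lo3, aug$obs1, aug$obs2, aug$obs3, aug$idx3,
    priors$a_theta, priors$b_theta,
    as.integer(priors$dpm$M), priors$dpm$alpha_shape, priors$dpm$alpha_rate,
    priors$dpm$kappa0, m0, priors$dpm$a0, priors$dpm$b0,
    config$n_iter, config$n_burnin, config$thin,
    fix, if (fix) config$fix_theta else 0, ini$mu, ini$sigma2,
    if (fix) config$fix_theta else 0.1)
  draws <- list(
    mu = NULL,
    beta = {
      b <- list(raw$beta1, raw$beta2, raw$beta3)
      for (g in 1:3) colnames(b[[g]]) <- colnames0(des$X[[g]])
      b
    },
    sigma2 = NULL, theta = as.numeric(raw$theta), gamma = raw$gamma,
    mixture = list(w = list(raw$w1, raw$w2, raw$w3),
                   mu = list(raw$mu1, raw$mu2, raw$mu3),
                   sigma2 = list(raw$s2_1, raw$s2_2, raw$s2_3),
                   alpha = raw$alpha, n_occ = raw$n_occ))
  new_posterior_samples("dpm", draws, lapply(des$X, colnames0), des$dropped,
                        dataset, priors, config, min_sojourn)
}

# scalar chains worth monitoring, as a named matrix (draws x params)
scalar_chain_matrix <- function(s) {
  d <- s$draws
  cols <- list(theta = d$theta)
  if (s$model == "lognormal") {
    for (g in 1:3) {
      cols[[paste0("mu", g)]] <- d$mu[, g]
      cols[[paste0("sigma2_", g)]] <- d$sigma2[, g]
    }
  }
  for (g in 1:3) {
    B <- d$beta[[g]]
    if (ncol(B))
      for (j in seq_len(ncol(B)))
        cols[[paste0("g", g, ":", s$colnames[[g]][j])]] <- B[, j]
  }
  do.call(cbind, cols)
}

split_rhat <- function(chains) {
  # chains: iterations x chains matrix for one scalar parameter
  S <- nrow(chains)
  half <- floor(S / 2)
  sub <- cbind(chains[seq_len(half), , drop = FALSE],
               chains[(S - half + 1):S, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  W <- mean(apply(sub, 2, stats::var))
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_geyer <- function(x) {
  # effective sample size by Geyer's initial positive sequence
  S <- length(x)
  if (stats::var(x) == 0) return(S)
  ac <- stats::acf(x, lag.max = min(S - 1, 500), plot = FALSE)$acf[-1]
  rho_sum <- 0
  k <- 1
  while (k < length(ac)) {
    pair <- ac[k] + if (k + 1 <= length(ac)) ac[k + 1] else 0
    if (pair < 0) break
    rho_sum <- rho_sum + pair
    k <- k + 2
  }
  max(1, S / (1 + 2 * rho_sum))
}

#' Convergence diagnostics across chains
#'
#' Split potential-scale-reduction factors and effective sample sizes for
#' every monitored scalar parameter; parameters with split-PSRF above 1.1
#' are flagged.
#'
#' @param samples_list list of at least two `posterior_samples` from
#'   independent chains of the same model/config length.
#' @return data frame with columns `parameter`, `psrf`, `ess`, `flagged`.
#' @export
diagnostics <- function(samples_list) {
  stopifnot(is.list(samples_list), length(samples_list) >= 2)
  mats <- lapply(samples_list, scalar_chain_matrix)
  S <- vapply(mats, nrow, integer(1))
  if (length(unique(S)) != 1L) stop("chains have unequal length")
  pars <- colnames(mats[[1]])
  out <- data.frame(parameter = pars, psrf = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(pars)) {
    ch <- vapply(mats, function(m) m[, j], numeric(S[1]))
    out$psrf[j] <- split_rhat(ch)
    out$ess[j] <- sum(apply(ch, 2, ess_geyer))
  }
  out$flagged <- out$psrf > 1.1
  out
}
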