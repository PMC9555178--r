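#' Prior specification
#'
#' Inverse-gamma priors on the frailty variance `theta` and on each
#' transition error variance `sigma2_g`; improper flat priors on the
#' regression coefficients and location parameters (encoded as flags, and
#' contributing zero to the log prior). The defaults IG(0.7, 0.7) are
#' weakly informative: no finite prior mean, but enough mass near zero to
#' keep posteriors proper under diffuse data.
#'
#' DPM settings govern the truncated stick-breaking mixture used by
#' [fit_dpm()]: truncation level `M` per transition, Gamma prior on the
#' concentration parameter, and a conjugate normal-inverse-gamma base
#' measure `mu_r ~ N(m0, sigma2_r / kappa0)`, `sigma2_r ~ IG(a0, b0)`
#' (with `m0 = NULL` meaning "centre at the empirical mean of the
#' observed log times for that transition").
#'
#' @param a_theta,b_theta IG shape/rate for the frailty variance.
#' @param a_sigma,b_sigma length-3 IG shapes/rates for the error variances.
#' @param flat_beta,flat_mu flags for improper flat priors (always TRUE in
#'   this release; kept explicit in the state).
#' @param dpm list of DPM hyperparameters (see Details).
#' @return a `prior_spec`.
#' @export
prior_spec <- function(a_theta = 0.7, b_theta = 0.7,
                       a_sigma = rep(0.7, 3), b_sigma = rep(0.7, 3),
                       flat_beta = TRUE, flat_mu = TRUE,
                       dpm = list(M = 20, alpha_shape = 2, alpha_rate = 2,
                                  kappa0 = 0.1, m0 = NULL,
                                  a0 = 2, b0 = 1)) {
  stopifnot(a_theta > 0, b_theta > 0, all(a_sigma > 0), all(b_sigma > 0),
            length(a_sigma) == 3, length(b_sigma) == 3)
  stopifnot(dpm$M >= 2, dpm$alpha_shape > 0, dpm$alpha_rate > 0,
            dpm$kappa0 > 0, dpm$a0 > 0, dpm$b0 > 0)
  structure(list(a_theta = a_theta, b_theta = b_theta,
                 a_sigma = as.numeric(a_sigma), b_sigma = as.numeric(b_sigma),
                 flat_beta = isTRUE(flat_beta), flat_mu = isTRUE(flat_mu),
                 dpm = dpm),
            class = "prior_spec")
}

#' Full parameter state of the AFT illness-death model
#'
#' @param beta named list `b1`, `b2`, `b3` of coefficient vectors (names =
#'   design columns of the corresponding transition).
#' @param mu length-3 error locations (log-month scale).
#' @param sigma2 length-3 positive error variances.
#' @param theta nonnegative frailty variance.
#' @param gamma per-subject frailties (length n, or empty).
#' @param mixture `NULL` for the parametric log-normal state, else a list
#'   of three `list(w, mu, sigma2)` mixture descriptions, one per
#'   transition; the single-normal state is the length-1 special case.
#' @return an `aft_params`.
#' @export
aft_params <- function(beta, mu = rep(0, 3), sigma2 = rep(1, 3), theta = 0,
                       gamma = numeric(0), mixture = NULL) {
  stopifnot(all(c("b1", "b2", "b3") %in% names(beta)),
            length(mu) == 3, length(sigma2) == 3)
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (theta < 0) stop("theta must be nonnegative")
  if (!is.null(mixture)) {
    stopifnot(length(mixture) == 3)
    for (m in mixture) {
      stopifnot(all(c("w", "mu", "sigma2") %in% names(m)),
                length(m$w) == length(m$mu),
                length(m$w) == length(m$sigma2), all(m$sigma2 > 0),
                abs(sum(m$w) - 1) < 1e-8)
    }
  }
  structure(list(beta = lapply(beta[c("b1", "b2", "b3")], as.numeric),
                 beta_names = lapply(beta[c("b1", "b2", "b3")], names),
                 mu = as.numeric(mu), sigma2 = as.numeric(sigma2),
                 theta = theta, gamma = as.numeric(gamma),
                 mixture = mixture),
            class = "aft_params")
}

# error-distribution description for transition g: component locations are
# absolute (they include mu_g in the parametric case)
error_mix <- function(params, g) {
  if (is.null(params$mixture))
    list(w = 1, mu = params$mu[g], sigma2 = params$sigma2[g])
  else params$mixture[[g]]
}

row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- mx[bad]
  out
}

# log density of the event time T at t, AFT location shift eta (x'beta +
# frailty), mixture-of-normals error on the log scale
lnorm_logf <- function(t, eta, mix) {
  R <- length(mix$w)
  lt <- log(t)
  m <- vapply(seq_len(R), function(r)
    log(mix$w[r]) + stats::dnorm(lt, eta + mix$mu[r],
                                 sqrt(mix$sigma2[r]), log = TRUE),
    numeric(length(t)))
  m <- matrix(m, nrow = length(t))
  row_logsumexp(m) - lt
}

# log survival of T at t under the same model
lnorm_logS <- function(t, eta, mix) {
  R <- length(mix$w)
  lt <- log(t)
  m <- vapply(seq_len(R), function(r)
    log(mix$w[r]) + stats::pnorm(lt, eta + mix$mu[r], sqrt(mix$sigma2[r]),
                                 lower.tail = FALSE, log.p = TRUE),
    numeric(length(t)))
  m <- matrix(m, nrow = length(t))
  row_logsumexp(m)
}

#' Observed-data log likelihood for one subject, conditional on its frailty
#'
#' With `f_g`/`S_g` the (mixture of) log-normal density/survival whose
#' log-scale location is `x_g' beta_g + mu_g + frailty`, the contribution
#' by path is:
#' \describe{
#'   \item{recurrence then death}{`log f1(y1) + log S2(y1) + log f3(y2 - y1)`}
#'   \item{recurrence, then censored}{`log f1(y1) + log S2(y1) + log S3(y2 - y1)`}
#'   \item{death without recurrence}{`log S1(y2) + log f2(y2)`}
#'   \item{censored for both}{`log S1(y2) + log S2(y2)`}
#' }
#' The direct-death clock survives past the recurrence time on the
#' recurrence path (`S2(y1)`), after which the semi-Markov sojourn model
#' takes over. The sojourn `y2 - y1` is floored at `min_sojourn` so that
#' same-month recurrence and death keep a finite log time.
#'
#' @param record list or one-row data frame with `y1`, `d1`, `y2`, `d2`.
#' @param X_rows list of three numeric covariate rows (design scale), one
#'   per transition; an empty vector means "no covariates".
#' @param params an [aft_params()].
#' @param frailty the subject frailty `gamma_i`.
#' @param min_sojourn positive sojourn floor in months.
#' @return the subject log likelihood (a scalar).
#' @export
loglik_subject <- function(record, X_rows, params, frailty = 0,
                           min_sojourn = 0.5) {
  stopifnot(min_sojourn > 0)
  y1 <- record$y1; y2 <- record$y2
  d1 <- record$d1; d2 <- record$d2
  eta <- vapply(1:3, function(g) {
    x <- X_rows[[g]]
    if (length(x)) sum(x * params$beta[[g]]) + frailty else frailty
  }, numeric(1))
  mix <- lapply(1:3, error_mix, params = params)
  if (d1 == 1) {
    s <- max(y2 - y1, min_sojourn)
    if (s <= 0) stop("nonpositive sojourn after flooring")
    ll <- lnorm_logf(y1, eta[1], mix[[1]]) + lnorm_logS(y1, eta[2], mix[[2]]) +
      if (d2 == 1) lnorm_logf(s, eta[3], mix[[3]])
      else lnorm_logS(s, eta[3], mix[[3]])
  } else {
    ll <- lnorm_logS(y2, eta[1], mix[[1]]) +
      if (d2 == 1) lnorm_logf(y2, eta[2], mix[[2]])
      else lnorm_logS(y2, eta[2], mix[[2]])
  }
  as.numeric(ll)
}

# vectorized per-subject log likelihood for a whole dataset
loglik_by_subject <- function(dataset, params, min_sojourn = 0.5) {
  r <- dataset$records
  n <- nrow(r)
  if (n == 0L) return(numeric(0))
  gam <- params$gamma
  if (length(gam) == 0L) gam <- rep(0, n)
  if (length(gam) == 1L) gam <- rep(gam, n)
  if (length(gam) != n) stop("gamma has length ", length(gam), ", need ", n)
  eta <- lapply(1:3, function(g) {
    X <- expand_design(dataset, g)
    b <- params$beta[[g]]
    nb <- params$beta_names[[g]]
    if (!is.null(nb) && !identical(colnames0(X), nb)) {
      if (!all(nb %in% colnames(X)))
        stop("beta for transition ", g, " names coefficient(s) absent from ",
             "the design: ", paste(setdiff(nb, colnames(X)), collapse = ", "))
      X <- X[, nb, drop = FALSE]
    }
    if (ncol(X) != length(b))
      stop("beta for transition ", g, " has ", length(b),
           " coefficients but the design has ", ncol(X), " columns")
    if (ncol(X)) drop(X %*% b) + gam else gam
  })
  mix <- lapply(1:3, error_mix, params = params)
  rec <- r$d1 == 1
  ll <- numeric(n)
  if (any(rec)) {
    s <- pmax(r$y2[rec] - r$y1[rec], min_sojourn)
    a3 <- ifelse(r$d2[rec] == 1,
                 lnorm_logf(s, eta[[3]][rec], mix[[3]]),
                 lnorm_logS(s, eta[[3]][rec], mix[[3]]))
    ll[rec] <- lnorm_logf(r$y1[rec], eta[[1]][rec], mix[[1]]) +
      lnorm_logS(r$y1[rec], eta[[2]][rec], mix[[2]]) + a3
  }
  if (any(!rec)) {
    a2 <- ifelse(r$d2[!rec] == 1,
                 lnorm_logf(r$y2[!rec], eta[[2]][!rec], mix[[2]]),
                 lnorm_logS(r$y2[!rec], eta[[2]][!rec], mix[[2]]))
    ll[!rec] <- lnorm_logS(r$y2[!rec], eta[[1]][!rec], mix[[1]]) + a2
  }
  ll
}

#' Total observed-data log likelihood
#'
#' Sum of [loglik_subject()] over the dataset, each subject evaluated at
#' its own frailty `params$gamma[i]`. The model deviance is `-2` times
#' this value.
#'
#' @param dataset an [scr_dataset()].
#' @inheritParams loglik_subject
#' @return scalar log likelihood (0 for an empty dataset).
#' @export
loglik_total <- function(dataset, params, min_sojourn = 0.5)
  sum(loglik_by_subject(dataset, params, min_sojourn))

ldinvgamma <- function(x, a, b)
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)

#' Log prior density of a parameter state
#'
#' Inverse-gamma terms for `theta` and each `sigma2_g`, the `N(0, theta)`
#' log density of the frailty vector, and zero for the flat terms. A
#' degenerate state (`theta = 0` with a nonzero frailty) returns `-Inf`
#' rather than raising an error.
#'
#' @inheritParams loglik_subject
#' @param priors a [prior_spec()].
#' @return scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  if (!is.null(params$mixture))
    stop("log_prior is defined for the parametric (single-normal) state")
  if (any(params$sigma2 <= 0) || params$theta < 0) return(-Inf)
  lp <- ldinvgamma(params$theta, priors$a_theta, priors$b_theta) +
    sum(ldinvgamma(params$sigma2, priors$a_sigma, priors$b_sigma))
  g <- params$gamma
  if (length(g)) {
    if (params$theta == 0)
      return(if (all(g == 0)) lp else -Inf)
    lp <- lp + sum(stats::dnorm(g, 0, sqrt(params$theta), log = TRUE))
  }
  lp
}

#' Serialize / restore a parameter state as flat JSON
#'
#' @inheritParams loglik_subject
#' @param path file path for the JSON document.
#' @export
write_params <- function(params, path) {
  doc <- list(beta = lapply(1:3, function(g)
                as.list(stats::setNames(params$beta[[g]],
                                        params$beta_names[[g]]))),
              mu = params$mu, sigma2 = params$sigma2, theta = params$theta,
              gamma = params$gamma, mixture = params$mixture)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  beta <- lapply(doc$beta, function(b) unlist(b))
  names(beta) <- c("b1", "b2", "b3")
  mixture <- doc$mixture
  if (!is.null(mixture))
    mixture <- lapply(mixture, function(m)
      list(w = as.numeric(unlist(m$w)), mu = as.numeric(unlist(m$mu)),
           sigma2 = as.numeric(unlist(m$sigma2))))
  aft_params(beta = beta, mu = as.numeric(doc$mu),
             sigma2 = as.numeric(doc$sigma2), theta = doc$theta,
             gamma = if (is.null(doc$gamma)) numeric(0)
                     else as.numeric(doc$gamma),
             mixture = mixture)
}
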