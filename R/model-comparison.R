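#' Deviance information criterion from a fitted chain
#'
#' Uses the conditional (frailty-level) deviance, i.e. the likelihood the
#' sampler itself exposes: `D_bar` is the mean of the stored per-draw
#' deviances, `D_at_mean` the deviance at the plug-in state built from
#' posterior means of all continuous parameters (plain means of `beta`,
#' `mu`, `sigma2`, mixture components, and the per-subject mean frailty),
#' `pD = D_bar - D_at_mean`, and `DIC = D_bar + pD`.
#'
#' @param samples a `posterior_samples` object (>= 2 draws).
#' @param dataset the dataset the model was fitted to.
#' @return list with `DIC`, `D_bar`, `D_at_mean`, `pD`.
#' @export
compute_dic <- function(samples, dataset) {
  stopifnot(inherits(samples, "posterior_samples"), n_draws(samples) >= 2)
  dev <- samples$deviance
  if (any(!is.finite(dev)))
    stop("non-finite deviance at draw ", which(!is.finite(dev))[1])
  D_bar <- mean(dev)
  D_at_mean <- -2 * loglik_total(dataset, posterior_mean_params(samples),
                                 samples$min_sojourn)
  pD <- D_bar - D_at_mean
  list(DIC = D_bar + pD, D_bar = D_bar, D_at_mean = D_at_mean, pD = pD)
}

#' Plug-in state at the posterior mean
#'
#' @inheritParams compute_dic
#' @return an [aft_params()] at the posterior mean of every continuous
#'   parameter (for mixtures: per-component means with weights
#'   renormalized).
#' @export
posterior_mean_params <- function(samples) {
  d <- samples$draws
  beta <- lapply(1:3, function(g)
    stats::setNames(colMeans(d$beta[[g]]), samples$colnames[[g]]))
  names(beta) <- c("b1", "b2", "b3")
  if (samples$model == "lognormal") {
    aft_params(beta = beta, mu = colMeans(d$mu), sigma2 = colMeans(d$sigma2),
               theta = mean(d$theta), gamma = colMeans(d$gamma))
  } else {
    mixture <- lapply(1:3, function(g) {
      w <- colMeans(d$mixture$w[[g]])
      list(w = w / sum(w), mu = colMeans(d$mixture$mu[[g]]),
           sigma2 = colMeans(d$mixture$sigma2[[g]]))
    })
    aft_params(beta = beta, mu = c(0, 0, 0), sigma2 = c(1, 1, 1),
               theta = mean(d$theta), gamma = colMeans(d$gamma),
               mixture = mixture)
  }
}

#' Log pseudo marginal likelihood and conditional predictive ordinates
#'
#' `CPO_i` is the harmonic mean over draws of subject i's conditional
#' likelihood, computed stably in log space; `LPML = sum_i log CPO_i`.
#' A subject with a zero likelihood in some draw gets `CPO_i = 0` and
#' drives `LPML` to `-Inf` (reported, not raised).
#'
#' @inheritParams compute_dic
#' @return list with `LPML`, `cpo` (per-subject vector), and
#'   `zero_likelihood_subjects` (ids with `CPO = 0`, usually empty).
#' @export
compute_lpml <- function(samples, dataset) {
  stopifnot(inherits(samples, "posterior_samples"))
  ll <- loglik_draws(samples, dataset)          # draws x subjects
  M <- nrow(ll)
  # log CPO_i = -( logsumexp_m(-ll_mi) - log M )
  neg <- -ll
  mx <- apply(neg, 2, max)
  log_cpo <- -(mx + log(colSums(exp(sweep(neg, 2, mx)))) - log(M))
  log_cpo[!is.finite(mx)] <- -Inf
  cpo <- exp(log_cpo)
  zero <- samples$subject_id[!is.finite(log_cpo)]
  list(LPML = sum(log_cpo), cpo = cpo, zero_likelihood_subjects = zero)
}

#' Assemble a per-model comparison entry
#'
#' @param name model label.
#' @inheritParams compute_dic
#' @return list with the model name, DIC decomposition, LPML and CPO
#'   vector.
#' @export
comparison_entry <- function(name, samples, dataset) {
  dic <- compute_dic(samples, dataset)
  lpml <- compute_lpml(samples, dataset)
  list(name = name, DIC = dic$DIC, D_bar = dic$D_bar,
       D_at_mean = dic$D_at_mean, pD = dic$pD,
       LPML = lpml$LPML, cpo = lpml$cpo,
       zero_likelihood_subjects = lpml$zero_likelihood_subjects)
}

#' Select the best-fitting model
#'
#' Lowest DIC wins; when DIC and LPML disagree on the ordering, DIC
#' governs and the disagreement is flagged. Exact DIC ties fall back to
#' the higher LPML, then to the first name.
#'
#' @param reports list of [comparison_entry()] results (>= 2 models).
#' @return list with `selected`, `rule`, `dic_lpml_disagree`, and a
#'   summary data frame `table`.
#' @export
select_model <- function(reports) {
  if (length(reports) < 2) stop("select_model needs at least two models")
  tab <- data.frame(
    name = vapply(reports, `[[`, character(1), "name"),
    DIC = vapply(reports, `[[`, numeric(1), "DIC"),
    LPML = vapply(reports, `[[`, numeric(1), "LPML"),
    pD = vapply(reports, `[[`, numeric(1), "pD"),
    stringsAsFactors = FALSE)
  ord <- order(tab$DIC, -tab$LPML, seq_len(nrow(tab)))
  best <- ord[1]
  disagree <- which.min(tab$DIC) != which.max(tab$LPML)
  list(selected = tab$name[best],
       rule = "lowest DIC; ties by highest LPML, then first name",
       dic_lpml_disagree = disagree, table = tab[ord, ])
}
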