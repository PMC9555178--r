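transition_labels <- c("Recurrence", "Death without recurrence",
                       "Death after recurrence")

#' Summarize a fit as time ratios with credible intervals
#'
#' The point estimate of each time ratio is `exp` of the posterior median
#' of the coefficient (the median commutes with the monotone `exp`, so
#' coefficient and TR summaries stay consistent); the interval is `exp`
#' of the 2.5/97.5 posterior percentiles. A covariate column that was
#' empty or collinear in a transition (dropped before fitting) is
#' reported as not computable (`NC`). "Significant" marks a 95% interval
#' excluding 1.
#'
#' @param samples a `posterior_samples` with at least 100 retained draws.
#' @param manifest the [covariate_manifest()] the model was fitted with.
#' @param conf_level credible level for the intervals.
#' @return a `fit_summary`: data frame `table` (transition, term, TR,
#'   lower, upper, significant, nc), frailty-variance summary `theta`,
#'   and optional `DIC`/`LPML` fields filled by the caller.
#' @export
summarize_fit <- function(samples, manifest, conf_level = 0.95) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (n_draws(samples) < 100)
    stop("summarize_fit needs at least 100 retained draws")
  a <- (1 - conf_level) / 2
  all_terms <- lapply(1:3, function(g)
    colnames(expand_design(empty_dataset_for(manifest), g)))
  rows <- list()
  for (g in 1:3) {
    for (term in all_terms[[g]]) {
      j <- match(term, samples$colnames[[g]])
      if (is.na(j)) {
        rows[[length(rows) + 1L]] <- data.frame(
          transition = transition_labels[g], term = term, TR = NA_real_,
          lower = NA_real_, upper = NA_real_, significant = NA, nc = TRUE,
          stringsAsFactors = FALSE)
      } else {
        b <- samples$draws$beta[[g]][, j]
        q <- stats::quantile(b, c(a, 0.5, 1 - a), names = FALSE, type = 7)
        tr <- exp(q[2]); lo <- exp(q[1]); hi <- exp(q[3])
        rows[[length(rows) + 1L]] <- data.frame(
          transition = transition_labels[g], term = term, TR = tr,
          lower = lo, upper = hi, significant = (lo > 1) || (hi < 1),
          nc = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  tq <- stats::quantile(samples$draws$theta, c(a, 0.5, 1 - a), names = FALSE)
  structure(list(table = do.call(rbind, rows),
                 theta = c(lower = tq[1], median = tq[2], upper = tq[3]),
                 conf_level = conf_level, model = samples$model,
                 DIC = NULL, LPML = NULL),
            class = "fit_summary")
}

empty_dataset_for <- function(manifest) {
  rec <- data.frame(subject_id = character(0), y1 = numeric(0),
                    d1 = numeric(0), y2 = numeric(0), d2 = numeric(0),
                    stringsAsFactors = FALSE)
  for (e in manifest)
    rec[[e$name]] <- if (is.null(e$levels)) numeric(0)
                     else vector(mode = typeof(e$levels), 0)
  structure(list(records = rec, manifest = manifest, rejected = NULL),
            class = "scr_dataset")
}

#' @export
print.fit_summary <- function(x, digits = 3, ...) {
  cat("Time ratios (", x$model, " model, ",
      round(100 * x$conf_level), "% credible intervals)\n", sep = "")
  t <- x$table
  for (tr in unique(t$transition)) {
    cat(tr, "\n")
    sub <- t[t$transition == tr, ]
    for (i in seq_len(nrow(sub))) {
      if (sub$nc[i])
        cat(sprintf("  %-22s NC\n", sub$term[i]))
      else
        cat(sprintf("  %-22s %.3f (%.3f-%.3f)%s\n", sub$term[i], sub$TR[i],
                    sub$lower[i], sub$upper[i],
                    if (isTRUE(sub$significant[i])) " *" else ""))
    }
  }
  cat(sprintf("Variance of frailties: %.3f, %d%% CI (%.3f-%.3f)\n",
              x$theta["median"], round(100 * x$conf_level),
              x$theta["lower"], x$theta["upper"]))
  if (!is.null(x$DIC)) cat(sprintf("DIC = %.0f, LPML = %.0f\n", x$DIC, x$LPML))
  invisible(x)
}

#' Model-based adjusted survival curve with credible band
#'
#' For every retained draw the transition-g survival function
#' `S_g(t | x, gamma = 0)` of the log-normal (or mixture) AFT model is
#' evaluated on the grid; the pointwise posterior median and the
#' credible band are returned.
#'
#' @param samples a `posterior_samples`.
#' @param covariate_profile named numeric vector on the design-column
#'   scale covering the transition's fitted columns.
#' @param transition 1, 2 or 3.
#' @param eval_times strictly positive evaluation times (months).
#' @param conf_level band level.
#' @return data frame `time`, `survival` (pointwise median), `lower`,
#'   `upper`.
#' @export
adjusted_survival <- function(samples, covariate_profile, transition,
                              eval_times, conf_level = 0.95) {
  stopifnot(transition %in% 1:3)
  if (any(eval_times <= 0)) stop("eval times must be positive")
  cols <- samples$colnames[[transition]]
  if (!all(cols %in% names(covariate_profile)))
    stop("covariate profile missing design column(s): ",
         paste(setdiff(cols, names(covariate_profile)), collapse = ", "))
  x <- as.numeric(covariate_profile[cols])
  S <- n_draws(samples)
  a <- (1 - conf_level) / 2
  surv <- matrix(NA_real_, S, length(eval_times))
  for (m in seq_len(S)) {
    p <- params_at_draw(samples, m)
    eta <- if (length(x)) sum(x * p$beta[[transition]]) else 0
    mix <- error_mix(p, transition)
    surv[m, ] <- exp(lnorm_logS(eval_times, eta, mix))
  }
  data.frame(time = eval_times,
             survival = apply(surv, 2, stats::median),
             lower = apply(surv, 2, stats::quantile, probs = a),
             upper = apply(surv, 2, stats::quantile, probs = 1 - a))
}

fmt_ci <- function(lo, hi) {
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  sprintf("%.3f-%.3f", lo, hi)
}

#' Render fitted models as publication-style text tables
#'
#' One block per fitted model: a row per covariate term with 3-decimal
#' time ratios per transition, an interval in each cell, asterisks for
#' intervals excluding 1, `NC` for non-computable cells, and a footer
#' carrying DIC, LPML and the frailty-variance summary. Interval bounds
#' are sorted before printing; an out-of-order input pair is flagged in
#' the returned anomaly list rather than reproduced.
#'
#' @param summaries named list of [summarize_fit()] results (with their
#'   `DIC`/`LPML` fields set if available).
#' @param comparison optional [select_model()] result appended as a
#'   comparison footer.
#' @return a `rendered_tables` list: `lines` (the text document),
#'   `cells` (long data frame of all cells), `anomalies`.
#' @export
render_tables <- function(summaries, comparison = NULL) {
  lines <- character(0)
  cells <- list()
  anomalies <- character(0)
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    lines <- c(lines, sprintf("== %s model ==", nm),
               sprintf("%-24s %-28s %-28s %-28s", "Term",
                       transition_labels[1], transition_labels[2],
                       transition_labels[3]))
    terms <- unique(s$table$term)
    for (term in terms) {
      cell_txt <- character(3)
      for (g in 1:3) {
        row <- s$table[s$table$transition == transition_labels[g] &
                         s$table$term == term, ]
        if (nrow(row) == 0 || row$nc[1]) {
          cell_txt[g] <- "NC"
          cells[[length(cells) + 1L]] <- data.frame(
            model = nm, term = term, transition = transition_labels[g],
            text = "NC", stringsAsFactors = FALSE)
        } else {
          if (row$lower[1] > row$upper[1])
            anomalies <- c(anomalies, sprintf(
              "%s / %s / %s: interval bounds out of order, sorted",
              nm, term, transition_labels[g]))
          txt <- sprintf("%.3f %s%s", row$TR[1],
                         fmt_ci(row$lower[1], row$upper[1]),
                         if (isTRUE(row$significant[1])) " *" else "")
          cell_txt[g] <- txt
          cells[[length(cells) + 1L]] <- data.frame(
            model = nm, term = term, transition = transition_labels[g],
            text = txt, stringsAsFactors = FALSE)
        }
      }
      lines <- c(lines, sprintf("%-24s %-28s %-28s %-28s", term,
                                cell_txt[1], cell_txt[2], cell_txt[3]))
    }
    lines <- c(lines, sprintf(
      "Variance of frailties: %.3f, 95%% CI (%s)", s$theta["median"],
      fmt_ci(s$theta["lower"], s$theta["upper"])))
    if (!is.null(s$DIC))
      lines <- c(lines, sprintf("DIC = %.0f, LPML = %.0f", s$DIC, s$LPML))
    lines <- c(lines, "")
  }
  if (!is.null(comparison)) {
    lines <- c(lines, sprintf("Selected model: %s (%s)%s",
                              comparison$selected, comparison$rule,
                              if (isTRUE(comparison$dic_lpml_disagree))
                                "; DIC and LPML disagree - DIC governs"
                              else ""))
  }
  structure(list(lines = lines,
                 cells = if (length(cells)) do.call(rbind, cells)
                         else data.frame(),
                 anomalies = anomalies),
            class = "rendered_tables")
}

#' @export
print.rendered_tables <- function(x, ...) {
  cat(paste(x$lines, collapse = "\n"), "\n")
  invisible(x)
}
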