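pct1 <- function(num, den) if (den > 0) round(100 * num / den, 1) else 0.0

#' Cohort profile by outcome path
#'
#' Counts and percentages for the illness-death outcome paths, each with
#' its denominator stated: recurrence and death out of all subjects,
#' death after recurrence out of the recurrent, death without recurrence
#' out of the non-recurrent, censored-for-both out of all subjects.
#' Percentages are rounded to one decimal place. Also returns covariate
#' frequency tables within outcome strata and follow-up summaries.
#'
#' @param dataset an [scr_dataset()].
#' @return a `cohort_profile` list with elements `paths` (data frame:
#'   outcome, count, denominator, percent), `covariates`, `followup`.
#' @export
profile_cohort <- function(dataset) {
  r <- dataset$records
  n <- nrow(r)
  rec <- r$d1 == 1
  died <- r$d2 == 1
  paths <- data.frame(
    outcome = c("recurred", "died", "died_after_recurrence",
                "died_without_recurrence", "censored_for_both"),
    count = c(sum(rec), sum(died), sum(rec & died), sum(!rec & died),
              sum(!rec & !died)),
    denominator = c(n, n, sum(rec), sum(!rec), n),
    stringsAsFactors = FALSE)
  paths$percent <- mapply(pct1, paths$count, paths$denominator)
  strata <- list(all = rep(TRUE, n), recurred = rec, died = died)
  covariates <- lapply(dataset$manifest, function(e) {
    if (is.null(e$levels)) {
      do.call(rbind, lapply(names(strata), function(s) {
        v <- r[[e$name]][strata[[s]]]
        data.frame(stratum = s, n = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    } else {
      do.call(rbind, lapply(names(strata), function(s) {
        v <- r[[e$name]][strata[[s]]]
        den <- length(v)
        cnt <- vapply(e$levels, function(l) sum(v == l), numeric(1))
        data.frame(stratum = s, level = e$labels, count = cnt,
                   denominator = den,
                   percent = vapply(cnt, pct1, numeric(1), den = den),
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    }
  })
  followup <- data.frame(
    quantity = c("median_y2_all", "median_y1_recurrent",
                 "median_sojourn_recurrent_dead"),
    months = c(stats::median(r$y2),
               if (any(rec)) stats::median(r$y1[rec]) else NA_real_,
               if (any(rec & died)) stats::median(r$y2[rec & died] -
                                                  r$y1[rec & died])
               else NA_real_),
    stringsAsFactors = FALSE)
  structure(list(n = n, paths = paths, covariates = covariates,
                 followup = followup), class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("cohort profile, n =", x$n, "\n")
  p <- x$paths
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-24s %4d / %4d  (%.1f%%)\n", p$outcome[i], p$count[i],
                p$denominator[i], p$percent[i]))
  invisible(x)
}

#' Kaplan-Meier survival at chosen times
#'
#' Product-limit estimate with Greenwood variance and log-log confidence
#' limits, evaluated at `eval_times`. Events precede censorings at tied
#' times (the standard convention).
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param eval_times evaluation grid (defaults to the event times).
#' @param conf_level confidence level for the band.
#' @return data frame `time`, `survival`, `lower`, `upper`, plus an
#'   attribute `all_censored` flagging the degenerate all-censored input
#'   (curve identically 1, CI undefined).
#' @export
km_curve <- function(times, events, eval_times = NULL, conf_level = 0.95) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  if (is.null(eval_times)) eval_times <- sort(unique(times[events == 1]))
  all_cens <- !any(events == 1)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  sm <- summary(fit, times = eval_times, extend = TRUE)
  out <- data.frame(time = sm$time, survival = sm$surv,
                    lower = sm$lower, upper = sm$upper)
  if (all_cens) {
    out$survival <- 1
    out$lower <- NA_real_
    out$upper <- NA_real_
  }
  attr(out, "all_censored") <- all_cens
  out
}

#' Log-rank test across groups
#'
#' @param groups list of `list(times, events)` per group (>= 2 groups,
#'   each nonempty, with at least one event overall).
#' @return list `statistic` (chi-square), `df` (groups - 1), `p`.
#' @export
logrank <- function(groups) {
  stopifnot(length(groups) >= 2)
  sizes <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(sizes == 0)) stop("log-rank test requires every group nonempty")
  df <- data.frame(
    time = unlist(lapply(groups, `[[`, "times")),
    event = unlist(lapply(groups, `[[`, "events")),
    group = rep(seq_along(groups), sizes))
  if (sum(df$event) == 0) stop("log-rank test requires at least one event")
  k <- length(groups)
  if (length(unique(df$group[df$event == 1])) == 0)
    stop("no events observed")
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- as.numeric(sd0$chisq)
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Event rate per 1000
#'
#' Person-time incidence (events per 1000 person-months of follow-up to
#' the relevant event or censoring) and, because "per 1000 persons" is
#' ambiguous, also the crude per-1000-persons proportion; both labelled.
#'
#' @param dataset an [scr_dataset()].
#' @param event `"recurrence"` (clock `y1`, indicator `d1`) or `"death"`
#'   (clock `y2`, indicator `d2`).
#' @param stratum optional logical vector selecting a nonempty stratum.
#' @return list `rate_per_1000_person_months`, `per_1000_persons`,
#'   `events`, `person_months`, `n`, `undefined` (TRUE when person-time
#'   is zero).
#' @export
event_rate_per_1000 <- function(dataset, event = c("recurrence", "death"),
                                stratum = NULL) {
  event <- match.arg(event)
  r <- dataset$records
  if (is.null(stratum)) stratum <- rep(TRUE, nrow(r))
  stopifnot(length(stratum) == nrow(r))
  r <- r[stratum, , drop = FALSE]
  if (nrow(r) == 0) stop("stratum is empty")
  t <- if (event == "recurrence") r$y1 else r$y2
  d <- if (event == "recurrence") r$d1 else r$d2
  pt <- sum(t)
  und <- pt <= 0
  list(rate_per_1000_person_months = if (und) NA_real_ else 1000 * sum(d) / pt,
       per_1000_persons = 1000 * sum(d) / nrow(r),
       events = sum(d), person_months = pt, n = nrow(r), undefined = und)
}
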