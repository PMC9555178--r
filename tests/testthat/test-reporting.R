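# a hand-built chain over a two-covariate manifest, used to control the
# coefficient draws exactly
made_samples <- function(b1_draws, S = nrow(b1_draws),
                         manifest = fixture_manifest()) {
  zeros <- matrix(0, S, 2, dimnames = list(NULL, c("x1", "x2:1")))
  structure(list(
    model = "lognormal",
    draws = list(mu = matrix(0, S, 3),
                 beta = list(b1_draws, zeros, zeros),
                 sigma2 = matrix(1, S, 3),
                 theta = stats::runif(S, 0.2, 0.3),
                 gamma = matrix(0, S, 1)),
    colnames = list(colnames(b1_draws), colnames(zeros), colnames(zeros)),
    dropped = list(character(0), character(0), character(0)),
    n = 1L, subject_id = "s1", priors = prior_spec(), config = NULL,
    min_sojourn = 0.5, deviance = rep(0, S)),
    class = "posterior_samples")
}

test_that("time ratios are exp of coefficient medians with percentile intervals", {
  set.seed(70)
  S <- 1000
  b1 <- cbind(x1 = rnorm(S, 0.5, 0.1), `x2:1` = rep(0, S))
  s <- made_samples(b1)
  fs <- summarize_fit(s, fixture_manifest())
  row <- fs$table[fs$table$transition == "Recurrence" &
                    fs$table$term == "x1", ]
  expect_equal(row$TR, exp(0.5), tolerance = 0.02)
  expect_equal(row$lower, exp(0.5 - 1.96 * 0.1), tolerance = 0.05)
  expect_equal(row$upper, exp(0.5 + 1.96 * 0.1), tolerance = 0.05)
  expect_true(row$significant)
  # all-zero draws: TR exactly 1, not significant
  row0 <- fs$table[fs$table$transition == "Recurrence" &
                     fs$table$term == "x2:1", ]
  expect_equal(row0$TR, 1)
  expect_equal(c(row0$lower, row0$upper), c(1, 1))
  expect_false(row0$significant)
  # exp commutes with the percentile summary (monotone transform), exactly
  q <- stats::quantile(b1[, "x1"], c(0.025, 0.5, 0.975), names = FALSE)
  expect_identical(c(row$lower, row$TR, row$upper), exp(q))
  # exact on order statistics (type-1 quantiles pick the same draw)
  for (pq in c(0.025, 0.5, 0.975))
    expect_identical(stats::quantile(exp(b1[, "x1"]), pq, names = FALSE,
                                     type = 1),
                     exp(stats::quantile(b1[, "x1"], pq, names = FALSE,
                                         type = 1)))
})

test_that("a constant coefficient column prints on the published 3-decimal scale", {
  S <- 200
  b1 <- cbind(x1 = rep(log(0.764), S), `x2:1` = rep(0, S))
  s <- made_samples(b1)
  fs <- summarize_fit(s, fixture_manifest())
  rt <- render_tables(list(lognormal = fs))
  cell <- rt$cells[rt$cells$term == "x1" &
                     rt$cells$transition == "Recurrence", "text"]
  expect_match(cell, "^0\\.764 ")
})

test_that("dropped design columns surface as NC cells", {
  S <- 150
  b1 <- cbind(x1 = rnorm(S, 0, 0.05))
  s <- made_samples(matrix(b1, S, 1, dimnames = list(NULL, "x1")))
  s$colnames <- list("x1", "x1", "x1")
  zeros1 <- matrix(0, S, 1, dimnames = list(NULL, "x1"))
  s$draws$beta <- list(s$draws$beta[[1]][, 1, drop = FALSE], zeros1, zeros1)
  s$dropped <- list("x2:1", "x2:1", "x2:1")
  fs <- summarize_fit(s, fixture_manifest())
  nc <- fs$table[fs$table$term == "x2:1", ]
  expect_true(all(nc$nc))
  rt <- render_tables(list(lognormal = fs))
  expect_true(all(rt$cells$text[rt$cells$term == "x2:1"] == "NC"))
})

test_that("summarize_fit refuses chains shorter than 100 retained draws", {
  s <- made_samples(matrix(0, 50, 2,
                           dimnames = list(NULL, c("x1", "x2:1"))))
  expect_error(summarize_fit(s, fixture_manifest()), "at least 100")
})

test_that("fit summaries carry the frailty-variance percentile summary", {
  S <- 400
  s <- made_samples(matrix(0, S, 2, dimnames = list(NULL, c("x1", "x2:1"))))
  s$draws$theta <- exp(rnorm(S, log(0.245), 0.05))
  fs <- summarize_fit(s, fixture_manifest())
  expect_equal(unname(fs$theta["median"]), 0.245, tolerance = 0.03)
  expect_lt(fs$theta["lower"], fs$theta["median"])
  expect_gt(fs$theta["upper"], fs$theta["median"])
})

test_that("adjusted survival curves are model-consistent and banded", {
  S <- 500
  set.seed(71)
  b1 <- cbind(x1 = rnorm(S, -0.2, 0.05), `x2:1` = rnorm(S, 0.1, 0.05))
  s <- made_samples(b1)
  prof <- c(x1 = 1, `x2:1` = 1)
  # early-time limit: survival tends to 1 for every draw
  early <- adjusted_survival(s, prof, transition = 1, eval_times = 1e-8)
  expect_gt(early$survival, 1 - 1e-6)
  expect_gt(early$lower, 1 - 1e-4)
  # single known draw: S(1) at the log-normal median is 1/2
  s1 <- made_samples(matrix(0, 120, 2,
                            dimnames = list(NULL, c("x1", "x2:1"))))
  flat <- adjusted_survival(s1, c(x1 = 0, `x2:1` = 0), 1, eval_times = 1)
  expect_equal(flat$survival, 0.5, tolerance = 1e-10)
  # band equals the direct per-draw evaluation
  ts <- c(2, 10, 40)
  curve <- adjusted_survival(s, prof, 1, eval_times = ts)
  direct <- vapply(seq_len(S), function(m) {
    eta <- sum(prof * b1[m, ])
    stats::pnorm((log(ts) - eta) / 1, lower.tail = FALSE)
  }, numeric(length(ts)))
  expect_equal(curve$survival, apply(direct, 1, stats::median),
               tolerance = 1e-10)
  expect_equal(curve$lower, apply(direct, 1, stats::quantile, 0.025),
               tolerance = 1e-10)
  # pointwise monotone nonincreasing in t
  expect_true(all(diff(curve$survival) < 0))
  expect_error(adjusted_survival(s, prof, 1, eval_times = c(1, 0)),
               "positive")
})

test_that("rendered tables carry significance stars, DIC/LPML footer and sorted bounds", {
  S <- 150
  b1 <- cbind(x1 = rep(log(0.7), S) + rnorm(S, 0, 0.01),
              `x2:1` = rnorm(S, 0, 0.2))
  s <- made_samples(b1)
  fs <- summarize_fit(s, fixture_manifest())
  fs$DIC <- 1633; fs$LPML <- -811
  rt <- render_tables(list(lognormal = fs))
  expect_true(any(grepl("DIC = 1633, LPML = -811", rt$lines)))
  star_cell <- rt$cells[rt$cells$term == "x1" &
                          rt$cells$transition == "Recurrence", "text"]
  expect_match(star_cell, "\\*$")
  # inverted interval bounds are sorted and flagged, not reproduced
  fs2 <- fs
  i <- which(fs2$table$term == "x1" &
               fs2$table$transition == "Recurrence")
  tmp <- fs2$table$lower[i]
  fs2$table$lower[i] <- fs2$table$upper[i]
  fs2$table$upper[i] <- tmp
  rt2 <- render_tables(list(lognormal = fs2))
  expect_equal(length(rt2$anomalies), 1L)
  cell2 <- rt2$cells[rt2$cells$term == "x1" &
                       rt2$cells$transition == "Recurrence", "text"]
  expect_identical(cell2, star_cell)
  # comparison footer
  sel <- list(selected = "lognormal", rule = "lowest DIC",
              dic_lpml_disagree = TRUE)
  rt3 <- render_tables(list(lognormal = fs), comparison = sel)
  expect_true(any(grepl("Selected model: lognormal", rt3$lines)))
  expect_true(any(grepl("DIC governs", rt3$lines)))
})
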