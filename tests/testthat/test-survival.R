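test_that("identical time multisets in both groups give beta 0, HR 1", {
  rec <- tibble::tibble(
    time = rep(c(0.1, 0.2, 0.3), 2),
    dp = rep(c(0L, 1L), each = 3)
  )
  fit <- cox_fit(rec)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-8)
})

test_that("Newton solution matches grid-search partial-likelihood maximisation", {
  # a small interleaved six-record case first (fully separated groups have
  # a monotone partial likelihood and no finite maximiser)
  rec <- tibble::tibble(
    time = c(0.10, 0.20, 0.30, 0.40, 0.50, 0.60),
    dp = c(1L, 0L, 1L, 1L, 0L, 0L)
  )
  fit <- cox_fit(rec)
  expect_lt(abs(fit$beta - cox_grid_oracle(rec$time, rec$dp)), 1e-3)
  # then 20 random tie-free datasets
  set.seed(61)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    r <- tibble::tibble(
      time = runif(n, 0.01, 1),
      dp = c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    )
    f <- tryCatch(cox_fit(r), error = function(e) NULL)
    # monotone-likelihood draws and maximisers beyond the oracle's grid
    # range are legitimately rejected
    if (is.null(f) || abs(f$beta) > 5.5) next
    expect_lt(abs(f$beta - cox_grid_oracle(r$time, r$dp)), 1e-3,
      label = paste("dataset", i, "|newton - grid|")
    )
  }
})

test_that("hazard ratio and excess-hazard conversions are exact", {
  expect_equal(hazard_ratio(0), 1)
  expect_equal(hazard_ratio(log(2)), 2)
  expect_equal(hazard_ratio(log(1.58)), 1.58)
  expect_equal(round(excess_hazard_percent(1.58)), 58)
  expect_equal(excess_hazard_percent(1), 0)
  expect_equal(excess_hazard_percent(0.5), -50)
})

test_that("label swap negates beta and rescaling times leaves it unchanged", {
  set.seed(67)
  rec <- simulate_retention_dataset(400, 0.4, 1, 1.6, c(0, 2), seed = 5)$records
  rec <- rec[, c("time", "dp")]
  fit <- cox_fit(rec)
  swap <- cox_fit(dplyr::mutate(rec, dp = 1L - dp))
  expect_equal(swap$beta, -fit$beta, tolerance = 1e-7)
  expect_equal(swap$hazard_ratio, 1 / fit$hazard_ratio, tolerance = 1e-7)
  scaled <- cox_fit(dplyr::mutate(rec, time = time * 3.7))
  expect_equal(scaled$beta, fit$beta, tolerance = 1e-9)
})

test_that("Efron and Breslow agree on tie-free data", {
  set.seed(71)
  rec <- tibble::tibble(
    time = sample(seq(0.001, 1, 0.001), 300),
    dp = sample(0:1, 300, replace = TRUE)
  )
  fe <- cox_fit(rec, ties = "efron")
  fb <- cox_fit(rec, ties = "breslow")
  expect_equal(fe$beta, fb$beta, tolerance = 1e-9)
  expect_equal(fe$se, fb$se, tolerance = 1e-9)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(
    cox_fit(tibble::tibble(time = c(0.1, 0.2), dp = c(1L, 1L))),
    "both covariate groups"
  )
  expect_error(
    cox_fit(tibble::tibble(time = rep(0.1, 4), dp = c(0L, 0L, 1L, 1L))),
    "distinct event times"
  )
  # complete separation of times: monotone likelihood must be flagged
  expect_error(
    cox_fit(tibble::tibble(
      time = c(1:20 / 100, 21:40 / 10),
      dp = rep(c(1L, 0L), each = 20)
    )),
    "did not converge"
  )
})

test_that("tidy and glance expose the fit in broom shape", {
  rec <- simulate_retention_dataset(300, 0.5, 1, 2, c(0, 5), seed = 9)$records
  fit <- cox_fit(rec[, c("time", "dp")])
  td <- tidy(fit)
  expect_equal(td$estimate, fit$beta)
  expect_equal(td$hazard.ratio, exp(td$estimate))
  expect_equal(c(td$conf.low, td$conf.high), fit$ci95)
  gl <- glance(fit)
  expect_equal(gl$n, 300)
  expect_equal(gl$ties, "efron")
})

test_that("window table rows are nested, starred, and NA-safe", {
  set.seed(73)
  sim <- simulate_retention_dataset(3000, 0.4, 2, 3, c(0, 1), seed = 13)
  pairs <- tibble::tibble(
    ks = sim$records$time, valid = TRUE, status = sim$records$status
  )
  tab <- ks_window_hazard_table(pairs)
  expect_equal(nrow(tab), 6)
  expect_true(all(diff(tab$n0 + tab$n1) >= 0)) # nested windows grow
  expect_equal(
    tab$stars,
    ifelse(tab$p_value < 0.001, "**", ifelse(tab$p_value < 0.05, "*", ""))
  )
  # equal-rate groups: HR near 1, no star on the full window
  null <- simulate_retention_dataset(2000, 0.5, 2, 2, c(0, 1), seed = 17)
  ptab <- ks_window_hazard_table(
    tibble::tibble(
      ks = null$records$time, valid = TRUE, status = null$records$status
    ),
    windows = list(c(0, 1))
  )
  fitn <- cox_fit(null$records[, c("time", "dp")])
  expect_lt(abs(fitn$beta), 3 * fitn$se)
  # a window with one empty group gives an NA row and a warning
  onesided <- tibble::tibble(
    ks = c(0.1, 0.2, 0.6, 0.7),
    valid = TRUE,
    status = c("RELOCALIZED", "RELOCALIZED", "NONRELOCALIZED", "NONRELOCALIZED")
  )
  expect_warning(
    natab <- ks_window_hazard_table(onesided, windows = list(c(0, 0.5))),
    "window"
  )
  expect_true(is.na(natab$hazard_ratio))
  expect_equal(natab$stars, "")
})

test_that("ks_min drops highly similar duplicates from every window", {
  pairs <- tibble::tibble(
    ks = c(0.005, 0.02, 0.3, 0.004, 0.4, 0.08),
    valid = TRUE,
    status = rep(c("RELOCALIZED", "NONRELOCALIZED"), 3)
  )
  tab <- suppressWarnings(
    ks_window_hazard_table(pairs, windows = list(c(0, 1)), ks_min = 0.01)
  )
  expect_equal(tab$n0 + tab$n1, 4L)
})

test_that("Cox-Snell residuals are nonnegative, sum to the event count, and fit well", {
  sim <- simulate_retention_dataset(5000, 0.3, 1, 1.5, c(0, 10), seed = 19)
  fit <- cox_fit(sim$records[, c("time", "dp")])
  cs <- cox_snell_residuals(fit)
  expect_true(all(cs$residuals$residual >= 0))
  expect_equal(sum(cs$residuals$residual), 5000, tolerance = 1e-6)
  expect_lt(cs$ks_distance, 0.05)
})

test_that("the fitted model matches the survival package on the same data", {
  skip_if_not_installed("survival")
  sim <- simulate_retention_dataset(1500, 0.35, 1, 1.8, c(0, 1), seed = 23)
  rec <- sim$records
  fit <- cox_fit(rec[, c("time", "dp")])
  ref <- survival::coxph(
    survival::Surv(time, rep(1, nrow(rec))) ~ dp,
    data = rec, ties = "efron"
  )
  expect_equal(fit$beta, unname(stats::coef(ref)), tolerance = 1e-7)
  expect_equal(fit$se, sqrt(unname(stats::vcov(ref)[1, 1])), tolerance = 1e-7)
})
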