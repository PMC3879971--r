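#' Build survival records from classified, dated pairs
#'
#' Encodes relocalization status as the Cox covariate: `dp = 0` for
#' relocalized pairs (reference group) and `dp = 1` for nonrelocalized
#' pairs, with the pair's Ks as the survival time. Every record is an
#' observed event (no censoring mechanism is modelled).
#'
#' @param pairs Tibble with `ks` and `status` columns.
#' @return A tibble `time`, `dp`.
#' @export
survival_records <- function(pairs) {
  tibble::tibble(
    time = pairs$ks,
    dp = ifelse(pairs$status == "NONRELOCALIZED", 1L, 0L)
  )
}

cox_sums <- function(beta, time, x) {
  ord <- order(time)
  time <- time[ord]
  x <- x[ord]
  ex <- exp(beta * x)
  # risk-set sums: reverse cumulative sums down to each index
  rc <- function(v) rev(cumsum(rev(v)))
  S0 <- rc(ex)
  S1 <- rc(x * ex)
  S2 <- rc(x^2 * ex)
  first <- !duplicated(time)
  list(
    time = time, x = x, ex = ex,
    ut = time[first],
    S0 = S0[first], S1 = S1[first], S2 = S2[first],
    groups = split(seq_along(time), match(time, time[first]))
  )
}

cox_derivatives <- function(beta, time, x, ties = "efron") {
  ord <- order(time)
  time <- time[ord]
  x <- x[ord]
  ex <- exp(beta * x)
  rc <- function(v) rev(cumsum(rev(v)))
  S0a <- rc(ex)
  S1a <- rc(x * ex)
  S2a <- rc(x^2 * ex)
  first <- !duplicated(time)
  grp <- cumsum(first)
  d <- tabulate(grp)
  S0 <- S0a[first]
  S1 <- S1a[first]
  S2 <- S2a[first]
  sx <- rowsum(x, grp)[, 1]
  lpl <- beta * sum(sx)
  U <- sum(sx)
  I <- 0
  if (ties == "breslow") {
    lpl <- lpl - sum(d * log(S0))
    U <- U - sum(d * S1 / S0)
    I <- sum(d * (S2 / S0 - (S1 / S0)^2))
  } else {
    # Efron: untied event times vectorised, tied groups looped
    single <- d == 1
    lpl <- lpl - sum(log(S0[single]))
    U <- U - sum(S1[single] / S0[single])
    I <- sum(S2[single] / S0[single] - (S1[single] / S0[single])^2)
    if (any(!single)) {
      s0d <- rowsum(ex, grp)[, 1]
      s1d <- rowsum(x * ex, grp)[, 1]
      s2d <- rowsum(x^2 * ex, grp)[, 1]
      for (j in which(!single)) {
        for (l in seq_len(d[j]) - 1) {
          den <- S0[j] - (l / d[j]) * s0d[j]
          num1 <- S1[j] - (l / d[j]) * s1d[j]
          num2 <- S2[j] - (l / d[j]) * s2d[j]
          lpl <- lpl - log(den)
          U <- U - num1 / den
          I <- I + num2 / den - (num1 / den)^2
        }
      }
    }
  }
  list(lpl = unname(lpl), U = unname(U), I = unname(I))
}

#' Fit the Cox proportional-hazards model for a binary covariate
#'
#' Maximises the Cox partial likelihood for the single covariate `dp` by
#' Newton-Raphson from beta = 0 (convergence when the step falls below
#' 1e-9, at most 100 iterations), with Efron (default) or Breslow tie
#' handling. The standard error comes from the observed information; the
#' Wald test gives the p-value. All records are treated as events.
#'
#' @param records Tibble with `time` (> 0) and `dp` (0/1) columns.
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `psr_cox`: a list with `beta`, `se`,
#'   `hazard_ratio`, `ci95`, `p_value`, `n0`, `n1`, `ties_method`,
#'   `loglik`, `iterations`, and the data used.
#' @examples
#' rec <- tibble::tibble(
#'   time = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
#'   dp = c(1, 1, 1, 0, 0, 0)
#' )
#' fit <- cox_fit(rec)
#' fit$hazard_ratio
#' @export
cox_fit <- function(records, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(records$time > 0), all(records$dp %in% c(0, 1)))
  n0 <- sum(records$dp == 0)
  n1 <- sum(records$dp == 1)
  if (n0 == 0 || n1 == 0) {
    stop("both covariate groups must be represented")
  }
  if (length(unique(records$time)) < 2) {
    stop("at least two distinct event times are required")
  }
  # a finite maximiser exists only if the groups' event times interleave:
  # when every event of one group strictly precedes the other group's,
  # the partial likelihood is monotone in beta
  t0 <- records$time[records$dp == 0]
  t1 <- records$time[records$dp == 1]
  if (max(t1) < min(t0) || max(t0) < min(t1)) {
    stop(
      "monotone partial likelihood (complete separation of times): ",
      "fit did not converge"
    )
  }
  beta <- 0
  iter <- 0
  repeat {
    iter <- iter + 1
    dv <- cox_derivatives(beta, records$time, records$dp, ties)
    if (!is.finite(dv$I) || dv$I <= 0) {
      stop("information matrix not positive: fit did not converge")
    }
    step <- dv$U / dv$I
    beta <- beta + step
    if (abs(beta) > 50) {
      stop(
        "monotone partial likelihood (complete separation of times): ",
        "fit did not converge"
      )
    }
    if (abs(step) < 1e-9 || iter >= 100) break
  }
  if (abs(step) >= 1e-9) {
    stop("Newton-Raphson did not converge in 100 iterations")
  }
  dv <- cox_derivatives(beta, records$time, records$dp, ties)
  se <- 1 / sqrt(dv$I)
  z <- beta / se
  structure(
    list(
      beta = beta, se = se,
      hazard_ratio = exp(beta),
      ci95 = exp(beta + c(-1, 1) * 1.96 * se),
      p_value = 2 * stats::pnorm(-abs(z)),
      n0 = n0, n1 = n1,
      ties_method = ties,
      loglik = dv$lpl,
      iterations = iter,
      records = records
    ),
    class = "psr_cox"
  )
}

#' @export
print.psr_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties_method, " ties)\n", sep = "")
  cat(sprintf(
    "  beta = %.4f (se %.4f), HR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$beta, x$se, x$hazard_ratio, x$ci95[1], x$ci95[2], x$p_value
  ))
  cat(sprintf(
    "  n = %d (dp=0: %d, dp=1: %d), all events\n",
    x$n0 + x$n1, x$n0, x$n1
  ))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `psr_cox` object.
#' @param ... Unused.
#' @return A one-row tibble with term, estimate, std.error, statistic,
#'   p.value, hazard.ratio, conf.low, conf.high.
#' @exportS3Method generics::tidy
tidy.psr_cox <- function(x, ...) {
  tibble::tibble(
    term = "dp",
    estimate = x$beta,
    std.error = x$se,
    statistic = x$beta / x$se,
    p.value = x$p_value,
    hazard.ratio = x$hazard_ratio,
    conf.low = x$ci95[1],
    conf.high = x$ci95[2]
  )
}

#' Glance at a Cox fit
#'
#' @param x A `psr_cox` object.
#' @param ... Unused.
#' @return A one-row tibble with n, n.reference, n.comparison, logLik,
#'   ties, iterations.
#' @exportS3Method generics::glance
glance.psr_cox <- function(x, ...) {
  tibble::tibble(
    n = x$n0 + x$n1,
    n.reference = x$n0,
    n.comparison = x$n1,
    logLik = x$loglik,
    ties = x$ties_method,
    iterations = x$iterations
  )
}

#' Hazard ratio from a Cox coefficient
#'
#' @param beta Cox coefficient.
#' @return `exp(beta)`, the death rate of the dp = 1 group relative to the
#'   dp = 0 group.
#' @export
hazard_ratio <- function(beta) {
  stopifnot(is.finite(beta))
  exp(beta)
}

#' Excess hazard as a percentage
#'
#' A hazard ratio of 1.58 means a 58% higher death rate in the comparison
#' group.
#'
#' @param hr Hazard ratio (> 0).
#' @return `(hr - 1) * 100` (report writers round to the nearest integer).
#' @export
excess_hazard_percent <- function(hr) {
  stopifnot(all(hr > 0))
  (hr - 1) * 100
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Hazard-ratio table over nested Ks windows
#'
#' Fits one Cox model per Ks window on the pairs falling strictly inside
#' it, with significance stars at P < 0.05 (`*`) and P < 0.001 (`**`).
#' Windows where a group is empty (or the fit fails) produce a row of NAs
#' with a warning.
#'
#' @param pairs Tibble with `ks`, `valid`, `status` columns.
#' @param windows List of `c(lo, hi)` windows; the default is the nested
#'   ladder (0, 0.05), (0, 0.1), (0, 0.25), (0, 0.5), (0, 0.75), (0, 1).
#' @param ties Tie-handling method for [cox_fit()].
#' @param ks_min Optional extra lower bound (e.g. 0.01 to drop highly
#'   similar duplicates as a sensitivity analysis).
#' @return A tibble with one row per window: `window_lo`, `window_hi`,
#'   `n0`, `n1`, `hazard_ratio`, `ci_lo`, `ci_hi`, `p_value`, `stars`.
#' @export
ks_window_hazard_table <- function(pairs,
                                   windows = list(
                                     c(0, 0.05), c(0, 0.1), c(0, 0.25),
                                     c(0, 0.5), c(0, 0.75), c(0, 1)
                                   ),
                                   ties = "efron", ks_min = 0) {
  stopifnot(length(windows) >= 1)
  purrr::map_dfr(windows, function(w) {
    sub <- ks_window_filter(pairs, lo = max(w[1], ks_min), hi = w[2])
    fit <- tryCatch(
      cox_fit(survival_records(sub), ties = ties),
      error = function(e) {
        warning(
          "window (", w[1], ", ", w[2], "): ", conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (is.null(fit)) {
      tibble::tibble(
        window_lo = w[1], window_hi = w[2],
        n0 = sum(sub$status == "RELOCALIZED"),
        n1 = sum(sub$status == "NONRELOCALIZED"),
        hazard_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        p_value = NA_real_, stars = ""
      )
    } else {
      tibble::tibble(
        window_lo = w[1], window_hi = w[2],
        n0 = fit$n0, n1 = fit$n1,
        hazard_ratio = fit$hazard_ratio,
        ci_lo = fit$ci95[1], ci_hi = fit$ci95[2],
        p_value = fit$p_value,
        stars = significance_stars(fit$p_value)
      )
    }
  })
}

#' Cox-Snell residuals and goodness-of-fit statistic
#'
#' Residual for record i is `Lambda0(t_i) * exp(beta * dp_i)` with the
#' Breslow estimate of the baseline cumulative hazard. Under a
#' well-specified model the residuals follow a unit exponential; the
#' Kolmogorov-Smirnov distance from Exp(1) is returned as a numeric
#' counterpart of the usual diagnostic plot.
#'
#' @param fit A converged [cox_fit()].
#' @return A list with `residuals` (tibble `time`, `dp`, `residual`) and
#'   `ks_distance`.
#' @export
cox_snell_residuals <- function(fit) {
  rec <- fit$records
  s <- cox_sums(fit$beta, rec$time, rec$dp)
  d <- lengths(s$groups)
  lambda0 <- cumsum(d / s$S0) # baseline cumulative hazard at unique times
  # map each record to its time's cumulative hazard
  idx <- match(rec$time, s$ut)
  res <- lambda0[idx] * exp(fit$beta * rec$dp)
  ksd <- suppressWarnings(
    stats::ks.test(res, stats::pexp)$statistic
  )
  list(
    residuals = tibble::tibble(
      time = rec$time, dp = rec$dp, residual = res
    ),
    ks_distance = unname(ksd)
  )
}
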