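#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] into a tidy step-function table. Censored
#' subjects leave the risk set without a drop; events are processed before
#' censorings tied at the same time (the standard convention).
#'
#' @param times Non-negative follow-up times (months).
#' @param events 0/1 event indicators (1 = progression observed).
#' @return A tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival`, starting with the implicit S(0) = 1 row.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) abort("empty input")
  if (any(times < 0)) abort("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- tibble::tibble(
    time = c(0, fit$time),
    n_risk = c(fit$n, fit$n.risk),
    n_event = c(0, fit$n.event),
    survival = c(1, fit$surv)
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param group Two-level grouping vector.
#' @return A one-row tibble: `statistic` (chi-square, 1 df), `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2) abort("exactly two non-empty groups required")
  if (any(tapply(as.integer(events), group, sum) == 0)) {
    warn("a group has zero events; the log-rank statistic may be degenerate")
  }
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  tibble::tibble(statistic = sd$chisq,
                 p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Restricted mean survival time
#'
#' Exact area under the Kaplan-Meier step function from 0 to `t_max` -- no
#' numeric quadrature. When `t_max` exceeds the last follow-up time the
#' curve is extended flat, with a warning.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t_max Truncation horizon (months), > 0.
#' @return RMST in months.
#' @export
rmst <- function(curve, t_max = 32) {
  if (t_max <= 0) abort("t_max must be positive")
  if (max(curve$time) < t_max) {
    warn("t_max beyond last follow-up; survival curve extended flat")
  }
  times <- c(curve$time, Inf)
  surv <- c(curve$survival, curve$survival[nrow(curve)])
  area <- 0
  for (i in seq_len(length(times) - 1)) {
    t0 <- min(times[i], t_max)
    t1 <- min(times[i + 1], t_max)
    area <- area + (t1 - t0) * surv[i]
  }
  area
}

#' RMST contrast between two groups
#'
#' @param curve_a,curve_b `km_curve` objects (e.g. predicted responders and
#'   non-responders).
#' @param t_max Truncation horizon (months).
#' @return A one-row tibble of class `rmst_result`: `t_max`, `rmst_a`,
#'   `rmst_b`, `difference` (= a - b).
#' @export
rmst_difference <- function(curve_a, curve_b, t_max = 32) {
  ra <- rmst(curve_a, t_max)
  rb <- rmst(curve_b, t_max)
  out <- tibble::tibble(t_max = t_max, rmst_a = ra, rmst_b = rb,
                        difference = ra - rb)
  class(out) <- c("rmst_result", class(out))
  out
}

#' Survival contrast of predicted response groups
#'
#' Splits subjects by thresholded predicted probability, estimates both
#' Kaplan-Meier curves, runs the log-rank test and the RMST contrast.
#'
#' @param data Tibble with `pfs_months`, `pfs_event` and `prob` per subject.
#' @param threshold Probability threshold defining predicted responders.
#' @param t_max RMST horizon (months).
#' @return A list of class `survival_contrast`: `curves` (named), `logrank`
#'   tibble, `rmst` tibble.
#' @export
survival_contrast <- function(data, threshold = 0.5, t_max = 32) {
  pred <- ifelse(data$prob >= threshold, "predicted_responder",
                 "predicted_nonresponder")
  if (length(unique(pred)) < 2) {
    abort("all subjects fall in one predicted group; no contrast possible")
  }
  grp <- split(data, pred)
  curves <- lapply(grp, function(g) km_estimate(g$pfs_months, g$pfs_event))
  lr <- logrank_test(data$pfs_months, data$pfs_event, pred)
  rd <- rmst_difference(curves$predicted_responder,
                        curves$predicted_nonresponder, t_max)
  structure(list(curves = curves, logrank = lr, rmst = rd),
            class = "survival_contrast")
}

#' @export
print.survival_contrast <- function(x, ...) {
  cat(sprintf("<survival_contrast> log-rank chi-sq %.2f (p = %.3g); RMST gain %.2f months at %g months\n",
              x$logrank$statistic, x$logrank$p_value,
              x$rmst$difference, x$rmst$t_max))
  invisible(x)
}
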