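# Kaplan-Meier and log-rank analyses of classifier-assigned groups, via the
# survival package (product-limit estimator, Greenwood variance, log-log
# median confidence bounds, Mantel-Haenszel log-rank).

#' Kaplan-Meier fit with median and 95% CI
#'
#' Product-limit estimate of the survival function; the median is the
#' smallest event time at which the curve reaches 0.5 or below, with a 95%
#' confidence interval from inverted log(-log) pointwise bands
#' (Brookmeyer-Crowley style). Events precede censorings at tied times, the
#' conventional treatment.
#'
#' @param records a data frame with columns `time_months` (> 0) and `event`
#'   (1 observed, 0 censored), as produced by [simulate_survival()].
#' @return a list of class `km_curve`: `time` (event times), `surv`,
#'   `n_risk`, `median`, `median_ci` (lower, upper; `NA` when the curve
#'   never reaches 0.5), `n`, and the underlying `survival::survfit` object
#'   as `fit`.
#' @export
#' @examples
#' km <- km_fit(data.frame(time_months = 1:5, event = 1))
#' km$median
km_fit <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$time_months > 0),
            all(records$event %in% 0:1))
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "log-log")
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  ci <- stats::quantile(fit, probs = 0.5)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 median = med,
                 median_ci = c(lower = unname(ci$lower), upper = unname(ci$upper)),
                 n = fit$n, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d distinct times\n", x$n, length(x$time)))
  if (is.na(x$median)) cat("  median: not reached\n")
  else cat(sprintf("  median %.1f months (95%% CI %.1f to %.1f)\n",
                   x$median, x$median_ci["lower"], x$median_ci["upper"]))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "months", ylab = "survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel log-rank: at each distinct event time the observed minus
#' hypergeometric-expected events in one group are accumulated;
#' chi-square = (sum O - sum E)^2 / sum V on 1 degree of freedom.
#'
#' @param records a data frame with `time_months`, `event` and `group`
#'   (exactly two levels, e.g. classifier-assigned labels).
#' @return a list of class `logrank_result`: `chi_square`, `p_value`,
#'   `n_per_group`.
#' @export
#' @examples
#' rec <- data.frame(time_months = c(1, 3, 2, 4), event = 1,
#'                   group = c("a", "a", "b", "b"))
#' logrank_test(rec)
logrank_test <- function(records) {
  stopifnot(all(records$time_months > 0), all(records$event %in% 0:1))
  if (length(unique(records$group)) != 2L) stop("exactly two groups required")
  if (sum(records$event) == 0L) stop("no events observed")
  sd1 <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = records)
  structure(list(chi_square = unname(sd1$chisq),
                 p_value = stats::pchisq(sd1$chisq, df = 1, lower.tail = FALSE),
                 n_per_group = as.vector(sd1$n)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.2f (1 df), p = %.3g (n = %s)\n",
              x$chi_square, x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Survival analysis of classifier-assigned groups
#'
#' Convenience wrapper reproducing the endpoint analysis: per-group
#' Kaplan-Meier medians with 95% CIs and the two-group log-rank test, with
#' groups taken from a prediction vector rather than the true labels.
#'
#' @param records survival records (`sample_id`, `time_months`, `event`).
#' @param predicted_labels classifier-assigned group per record.
#' @return a list of class `km_comparison`: `curves` (per group), `logrank`.
#' @export
compare_survival <- function(records, predicted_labels) {
  stopifnot(length(predicted_labels) == nrow(records))
  records$group <- as.character(predicted_labels)
  curves <- lapply(split(records, records$group), km_fit)
  structure(list(curves = curves, logrank = logrank_test(records)),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat("Survival by classifier-assigned group\n")
  for (g in names(x$curves)) {
    k <- x$curves[[g]]
    if (is.na(k$median))
      cat(sprintf("  %-12s n = %2d, median not reached\n", g, k$n))
    else
      cat(sprintf("  %-12s n = %2d, median %.1f months (95%% CI %.1f-%.1f)\n",
                  g, k$n, k$median, k$median_ci["lower"], k$median_ci["upper"]))
  }
  print(x$logrank)
  invisible(x)
}
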