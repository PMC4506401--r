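#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve via `survival::survfit`. The returned
#' step function satisfies S(0) = 1 and is non-increasing.
#'
#' @param time follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) < 1) stop_invalid("need at least one subject")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events with hypergeometric variance at each
#' distinct event time (via `survival::survdiff`), chi-square with 1
#' degree of freedom.
#'
#' @param groups two-level group labels.
#' @param time follow-up times.
#' @param event event indicator.
#' @return list with `chisq`, `p`, `obs`, `exp` per group.
#' @export
logrank_test <- function(groups, time, event) {
  g <- factor(groups)
  if (nlevels(g) != 2)
    stop_invalid("log-rank test needs exactly 2 groups (got %d)", nlevels(g))
  if (any(table(g) == 0)) stop_invalid("a group has zero subjects")
  if (sum(event) < 1) stop_invalid("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}
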