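#' Generate a synthetic survival training cohort
#'
#' Draws a patient cohort with log-normal expression for the same gene
#' universe as the single-cell generator and exponential event times whose
#' hazard follows a planted log-linear model on the risk-program genes:
#' `h_i = baseline_hazard * exp(sum_g beta_g (x_gi - mu_g))` with
#' `beta_g = cohort_beta` for risk genes (0 when `risk_effect = 0`, so a
#' null risk program is null everywhere) and 0 elsewhere (covariates are
#' centered at their generative means, which only rescales the baseline
#' hazard). Censoring is an independent exponential with rate
#' `censor_rate`.
#'
#' @param config a [sim_config()]; requires `cohort_n >= 20` and
#'   `n_risk_genes >= 1`.
#' @return An object of class `survival_cohort`: list with `expression`
#'   (genes x samples, log2(TPM+1)-like array scale), `time`, `event`
#'   (1 = event, 0 = censored), `samples`, `batch`, and attribute
#'   `planted_beta` (ground truth, for benchmarking only — analysis code
#'   must not read it).
#' @examples
#' co <- generate_survival_cohort(sim_config(cohort_n = 50, seed = 3))
#' table(co$event)
#' @export
generate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$baseline_hazard <= 0)
    stop_invalid("'baseline_hazard' must be positive")
  if (config$cohort_n < 20L)
    stop_invalid("'cohort_n' must be at least 20")
  if (config$n_risk_genes < 1L)
    stop_invalid("'n_risk_genes' must be at least 1")

  gm <- gene_model(config)
  set.seed(config$seed + 1001L)
  n <- config$cohort_n
  samples <- sprintf("P%03d", seq_len(n))

  x <- matrix(stats::rnorm(config$n_genes * n, mean = gm$mu, sd = 1),
              nrow = config$n_genes, ncol = n,
              dimnames = list(gm$genes, samples))
  x[x < 0] <- 0  # expression floor

  # risk_effect is the global strength of the risk program: it shifts the
  # program's expression in high-risk cells and scales its hazard effect
  # here, so risk_effect = 0 switches the program off everywhere.
  beta <- stats::setNames(numeric(config$n_genes), gm$genes)
  beta[gm$risk_genes] <- config$cohort_beta * (config$risk_effect != 0)

  lp <- drop(crossprod(x - gm$mu, beta))
  hazard <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- if (config$censor_rate > 0)
    stats::rexp(n, rate = config$censor_rate) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  out <- list(expression = x, time = time, event = event,
              samples = samples, batch = rep("training", n))
  attr(out, "planted_beta") <- beta
  class(out) <- "survival_cohort"
  out
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("Survival cohort: %d samples, %d genes, %d events (%.0f%% censored)\n",
              length(x$time), nrow(x$expression), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}
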