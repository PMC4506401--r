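#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Breslow-tie partial likelihood for a single covariate
#' by Newton-Raphson (convergence tolerance 1e-8 on the score, at most
#' 50 iterations). The Wald p-value uses `z = beta / se`, two-sided.
#' Monotone-likelihood divergence is flagged (`converged = FALSE`) once
#' `|beta| > 20`.
#'
#' @param x numeric covariate, one value per subject.
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param tol Newton-Raphson score tolerance.
#' @param max_iter iteration cap.
#' @return list with `beta`, `se`, `z`, `p`, `loglik`, `iter`,
#'   `converged`.
#' @examples
#' set.seed(1)
#' x <- rnorm(100)
#' t <- rexp(100, exp(0.5 * x))
#' fit_univariate_cox(x, t, rep(1, 100))$beta
#' @export
fit_univariate_cox <- function(x, time, event, tol = 1e-8, max_iter = 50L) {
  n <- length(x)
  if (length(time) != n || length(event) != n)
    stop_invalid("x, time, event must have equal length")
  if (any(time <= 0)) stop_invalid("times must be positive")
  if (!all(event %in% c(0, 1))) stop_invalid("event must be 0/1")
  if (sum(event) < 2) stop_invalid("need at least 2 events")
  if (stats::sd(x) == 0)
    stop_invalid("degenerate covariate: constant across subjects")

  ord <- order(time, decreasing = TRUE)
  x <- x[ord]; time <- time[ord]; event <- event[ord]

  score_info <- function(beta) {
    # sweep times in decreasing order, accumulating risk-set sums
    s0 <- 0; s1 <- 0; s2 <- 0
    U <- 0; I <- 0; ll <- 0
    i <- 1L
    while (i <= n) {
      t_cur <- time[i]
      # add all subjects entering the risk set at this time
      j <- i
      while (j <= n && time[j] == t_cur) {
        w <- exp(beta * x[j])
        s0 <- s0 + w; s1 <- s1 + w * x[j]; s2 <- s2 + w * x[j]^2
        j <- j + 1L
      }
      d_idx <- i:(j - 1L)
      d_idx <- d_idx[event[d_idx] == 1]
      d <- length(d_idx)
      if (d > 0) {
        sx <- sum(x[d_idx])
        ll <- ll + beta * sx - d * log(s0)
        U <- U + sx - d * s1 / s0
        I <- I + d * (s2 / s0 - (s1 / s0)^2)
      }
      i <- j
    }
    list(U = U, I = I, ll = ll)
  }

  beta <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    si <- score_info(beta)
    if (si$I <= 0) break
    step <- si$U / si$I
    beta <- beta + step
    if (abs(beta) > 20) break
    if (abs(si$U) < tol || abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  si <- score_info(beta)
  se <- if (si$I > 0) 1 / sqrt(si$I) else NA_real_
  z <- beta / se
  list(beta = beta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       loglik = si$ll, iter = iter,
       converged = converged && abs(beta) <= 20)
}
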