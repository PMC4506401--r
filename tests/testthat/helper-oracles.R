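# Independent oracles, written directly from the defining formulas and
# kept free of any package internals.

# Breslow partial log-likelihood, direct double loop over event times
oracle_breslow_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d_idx]) -
      length(d_idx) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force maximizer of the Breslow partial likelihood on a grid
oracle_grid_cox <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  W <- exp(outer(x, grid))  # n x G
  ll <- numeric(length(grid))
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    risk <- which(time >= t)
    s0 <- colSums(W[risk, , drop = FALSE])
    ll <- ll + grid * sum(x[d_idx]) - length(d_idx) * log(s0)
  }
  grid[which.max(ll)]
}

# adjusted R^2 from the normal equations, N = number of genes
oracle_adj_r2 <- function(X, y, n_regressors) {
  X1 <- cbind(1, X)
  b <- solve(t(X1) %*% X1, t(X1) %*% y)
  res <- y - X1 %*% b
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  N <- length(y)
  1 - (1 - r2) * (N - 1) / (N - n_regressors - 1)
}

# exhaustive pool enumeration for the SNV union saturation statistic
oracle_union_saturation_mean <- function(sets, bulk, n) {
  pools <- utils::combn(length(sets), n, simplify = FALSE)
  mean(vapply(pools, function(idx) {
    pooled <- unique(unlist(sets[idx]))
    length(intersect(pooled, bulk)) / length(unique(bulk))
  }, numeric(1)))
}

# cluster filter by enumeration of all index pairs (i, j): a record is
# removed iff it lies inside some i..j run of >= cluster consecutive
# sorted variants spanning <= window bases
oracle_cluster_filter <- function(pos, window = 35, cluster = 3) {
  ord <- order(pos)
  p <- pos[ord]
  bad <- logical(length(p))
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (j - i + 1 >= cluster && p[j] - p[i] <= window && p[j] >= p[i])
      bad[i:j] <- TRUE
  }
  sort(p[!bad])
}

# product-limit estimator, direct loop
oracle_km <- function(time, event) {
  s <- 1
  out <- NULL
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n_risk <- sum(time >= t)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# two-group log-rank chi-square, direct hypergeometric accumulation
oracle_logrank_chisq <- function(groups, time, event) {
  g <- as.integer(factor(groups)) == 1L
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & g)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# equal-variance two-sample t statistic, textbook formula
oracle_t_stat <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
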