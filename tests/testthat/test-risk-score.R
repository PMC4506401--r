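test_that("Newton-Raphson Cox fit matches the grid-search oracle", {
  for (fx in cox_fixtures()) {
    fit <- fit_univariate_cox(fx$x, fx$time, fx$event)
    grid_beta <- oracle_grid_cox(fx$x, fx$time, fx$event)
    expect_lt(abs(fit$beta - grid_beta), 1e-3)
    # the log-likelihood at the optimum matches the direct formula
    expect_equal(fit$loglik,
                 oracle_breslow_loglik(fit$beta, fx$x, fx$time, fx$event),
                 tolerance = 1e-10)
  }
})

test_that("Cox fit agrees with survival::coxph (Breslow ties)", {
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    x <- rnorm(n)
    t <- round(rexp(n, exp(0.4 * x)), 2) + 0.01  # induce ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) next
    fit <- fit_univariate_cox(x, t, ev)
    ref <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "breslow")
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("Cox fit recovers a planted effect and is unbiased under the null", {
  cfg <- sim_config(n_genes = 50L, n_risk_genes = 1L, n_zero_markers = 5L,
                    cohort_n = 500L, cohort_beta = 0.8, seed = 31L)
  co <- generate_survival_cohort(cfg)
  risk_gene <- names(which(attr(co, "planted_beta") != 0))
  fit <- fit_univariate_cox(co$expression[risk_gene, ], co$time, co$event)
  expect_lt(abs(fit$beta - 0.8), 0.15)

  null_gene <- setdiff(rownames(co$expression),
                       c(risk_gene, "G0001"))[1]
  fit0 <- fit_univariate_cox(co$expression[null_gene, ], co$time, co$event)
  expect_lt(abs(fit0$beta), 0.1)
})

test_that("Cox fit rejects degenerate inputs and flags divergence", {
  expect_error(fit_univariate_cox(rep(1, 10), 1:10, rep(1, 10)),
               "degenerate covariate")
  expect_error(fit_univariate_cox(rnorm(10), 1:10, rep(0, 10)), "2 events")
  # perfectly separated risk: monotone likelihood
  fit <- fit_univariate_cox(c(1, 2, 3, 4, 5, 6), c(6, 5, 4, 3, 2, 1),
                            rep(1, 6))
  expect_false(fit$converged)
})

test_that("marker filtering mirrors the zero-expression rule", {
  cells <- matrix(c(1, 5, 0, 0, 0, 0), nrow = 3,
                  dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  expect_identical(filter_marker_genes(c("gA", "gB", "gC", "gZ"), cells),
                   c("gA", "gB"))
  expect_error(filter_marker_genes(c("gC", "gZ"), cells), "no usable")

  # 100-marker panel with 31 all-zero decoys leaves 69
  set.seed(1)
  m <- matrix(rexp(100 * 5), nrow = 100,
              dimnames = list(sprintf("m%03d", 1:100), paste0("c", 1:5)))
  m[1:31, ] <- 0
  expect_length(filter_marker_genes(rownames(m), m), 69)
})

test_that("risk scores are the stated linear combination", {
  model <- structure(list(genes = c("g1", "g2", "g3"),
                          beta = c(g1 = 0.5, g2 = -1, g3 = 2)),
                     class = "risk_model")
  x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(unname(compute_risk_scores(x, model)),
               c(0.5 * 1 - 2 + 2 * 3, 0.5 * 4 - 5 + 2 * 6))
  # linearity in expression
  expect_equal(compute_risk_scores(3 * x, model),
               3 * compute_risk_scores(x, model))
  model0 <- structure(list(genes = "g1", beta = c(g1 = 0)),
                      class = "risk_model")
  expect_equal(unname(compute_risk_scores(x, model0)), c(0, 0))
  expect_error(compute_risk_scores(x[1:2, ], model), "g3")
})

test_that("percentile normalization labels the top 40% high risk", {
  res <- normalize_and_classify(stats::setNames(1:10, letters[1:10]))
  expect_equal(attr(res, "offset"), 6.4)  # type-7 Q60 of 1..10
  expect_identical(res$sample[res$label == "HIGH"], letters[7:10])

  same <- normalize_and_classify(rep(2, 5))
  expect_true(all(same$label == "LOW"))
  expect_true(all(same$normalized == 0))

  raw <- normalize_and_classify(c(a = -1, b = 2), offset_source = 0)
  expect_identical(raw$label, c("LOW", "HIGH"))
})

test_that("high-risk fraction is exact for distinct scores divisible by 5", {
  set.seed(2)
  for (n in c(10, 50, 100)) {
    sc <- sample(seq_len(1000), n)
    res <- normalize_and_classify(sc)
    expect_equal(sum(res$label == "HIGH"), 0.4 * n)
  }
})

test_that("batch adjustment harmonizes location and scale", {
  set.seed(3)
  a <- matrix(rnorm(50 * 20, 5), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), paste0("a", 1:20)))
  adj_same <- batch_adjust(a, a)
  expect_equal(adj_same$a, adj_same$b, tolerance = 1e-10)
  expect_equal(adj_same$a, a, tolerance = 1e-10)

  shift <- a + rnorm(50)  # per-gene constant shift (recycled by column)
  colnames(shift) <- paste0("b", 1:20)
  adj <- batch_adjust(a, shift)
  expect_equal(rowMeans(adj$a), rowMeans(adj$b), tolerance = 1e-10)

  distorted <- (a - 5) * 3 + 9
  colnames(distorted) <- paste0("b", 1:20)
  adj2 <- batch_adjust(a, distorted)
  ks_pre <- ks.test(a[1, ], distorted[1, ])$statistic
  ks_post <- ks.test(adj2$a[1, ], adj2$b[1, ])$statistic
  expect_lt(ks_post, ks_pre)
})

test_that("Kaplan-Meier matches the closed form and the direct oracle", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2, 1, 0) / 3)

  km_c <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))

  t8 <- c(1, 2, 2, 3, 5, 6, 8, 9)
  e8 <- c(1, 1, 0, 1, 0, 1, 1, 0)
  km8 <- kaplan_meier(t8, e8)
  orc <- oracle_km(t8, e8)
  expect_equal(km8$surv[km8$n_event > 0], orc$surv, tolerance = 1e-12)
  expect_true(all(diff(km8$surv) <= 1e-12))
})

test_that("log-rank statistic matches manual O-E computation", {
  g <- rep(c("A", "B"), each = 4)
  t <- c(1, 3, 5, 7, 2, 4, 6, 8)
  e <- c(1, 1, 0, 1, 1, 0, 1, 1)
  res <- logrank_test(g, t, e)
  expect_equal(res$chisq, oracle_logrank_chisq(g, t, e), tolerance = 1e-10)
  # relabeling symmetry
  res_flip <- logrank_test(ifelse(g == "A", "B", "A"), t, e)
  expect_equal(res$chisq, res_flip$chisq, tolerance = 1e-12)
  expect_error(logrank_test(rep("A", 8), t, e), "2 groups")
})

test_that("trained model separates survival of high- and low-risk samples", {
  cfg <- sim_config(n_genes = 300L, n_risk_genes = 20L, n_zero_markers = 10L,
                    cohort_n = 300L, cohort_beta = 0.8, seed = 41L)
  co <- generate_survival_cohort(cfg)
  model <- train_risk_model(co)
  res <- normalize_and_classify(model$training_scores,
                                model$cutoff_percentile)
  lr <- logrank_test(res$label, co$time, co$event)
  expect_lt(lr$p, 0.01)
  # planted risk genes get positive coefficients
  planted <- names(which(attr(co, "planted_beta") > 0))
  expect_gt(mean(model$beta[planted] > 0), 0.9)
})

test_that("risk model round-trips through its TSV serialization", {
  cfg <- small_config(seed = 43L)
  co <- generate_survival_cohort(cfg)
  pop <- generate_cell_population(cfg)
  model <- train_risk_model(co, markers = pop$genes$marker_panel,
                            cells = pop$expr)
  path <- tempfile(fileext = ".tsv")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$beta, model$beta, tolerance = 1e-12)
  expect_equal(back$offset, unname(model$offset), tolerance = 1e-12)
  expect_identical(back$genes, model$genes)
})
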