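test_that("2x2 subgroup assignment is deterministic and policy-aware", {
  drv <- c(a = "MUT_EXPRESSED", b = "WT_EXPRESSED", c = "NO_CALL",
           d = "MUT_EXPRESSED")
  risk <- c(a = "HIGH", b = "LOW", c = "LOW", d = "LOW")
  res <- assign_subgroups(drv, risk)
  expect_identical(res$group, c("G4", "G1", "G1", "G2"))
  expect_identical(res$nocall_flag, c(FALSE, FALSE, TRUE, FALSE))

  res_ex <- assign_subgroups(drv, risk, nocall_policy = "exclude")
  expect_true(is.na(res_ex$group[3]))
  expect_identical(res_ex$group[c(1, 2, 4)], c("G4", "G1", "G2"))
  expect_error(assign_subgroups(drv, c("HIGH", "LOW")), "align")
})

test_that("discriminating genes require both fold and significance", {
  set.seed(4)
  n <- 12
  expr <- matrix(rexp(50 * 2 * n, 1 / 100), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%02d", 1:(2 * n))))
  groups <- rep(c("A", "B"), each = n)
  # g01: strong consistent up in A (passes fold and t-test)
  expr["g01", groups == "A"] <- rexp(n, 1 / 400) + 300
  expr["g01", groups == "B"] <- rexp(n, 1 / 50)
  # g02: tiny shift, fails the fold criterion
  expr["g02", ] <- 100 + rnorm(2 * n, 0, 1) + 10 * (groups == "A")
  sel <- select_discriminating_genes(expr, groups)
  expect_true("g01" %in% sel$gene[sel$group == "A"])
  expect_false("g02" %in% sel$gene)
  expect_true(all(sel$fold >= 2) && all(sel$p < 0.05))
})

test_that("null data yields few discriminating genes and skips tiny groups", {
  set.seed(5)
  expr <- matrix(rexp(200 * 30, 1 / 100), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200),
                                 sprintf("c%02d", 1:30)))
  groups <- rep(c("A", "B"), 15)
  sel <- select_discriminating_genes(expr, groups)
  # selection conditions on the fold screen, so the rate sits between
  # alpha * P(fold) and the fold-pass rate itself
  expect_lt(nrow(sel) / 200, 0.15)
  expect_true(all(sel$fold >= 2 & sel$p < 0.05))
  expect_warning(
    select_discriminating_genes(expr, c("solo", groups[-1])), "skipped")
})

test_that("planted G4 program genes are recovered as G4 discriminators", {
  recall <- vapply(1:5, function(s) {
    cfg <- small_config(seed = s, risk_effect = 1.5)
    pop <- generate_cell_population(cfg)
    sel <- suppressWarnings(
      select_discriminating_genes(pop$expr, pop$truth$cell_group))
    prog <- pop$genes$risk_genes
    high <- sel$gene[sel$group %in% c("G3", "G4")]
    mean(prog %in% high)
  }, numeric(1))
  expect_gte(median(recall), 0.8)
})

test_that("PCA conserves variance and matches eigendecomposition", {
  set.seed(6)
  x <- matrix(rnorm(6 * 4, 5), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  fit <- pca_expression(x, log_transform = FALSE)
  expect_equal(sum(fit$var_fraction), 1, tolerance = 1e-10)
  expect_equal(crossprod(fit$loadings), diag(ncol(fit$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)

  cx <- scale(t(x), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cx) / (nrow(cx) - 1))
  orc_scores <- cx %*% eig$vectors[, 1:3]
  for (k in 1:3)
    expect_equal(abs(fit$scores[, k]), abs(orc_scores[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)

  # collinear data: PC1 carries everything
  line <- outer(c(1, 2, 3), c(0, 1, 2, 3)) + 1
  dimnames(line) <- list(paste0("g", 1:3), paste0("s", 1:4))
  fit_line <- pca_expression(line, log_transform = FALSE)
  expect_equal(fit_line$var_fraction[1], 1, tolerance = 1e-10)

  flat <- matrix(1, 3, 4, dimnames = dimnames(line))
  expect_error(pca_expression(flat, log_transform = FALSE), "degenerate")
})

test_that("PCA sign convention makes scores reproducible", {
  set.seed(7)
  x <- matrix(rexp(40 * 10), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:10)))
  f1 <- pca_expression(x)
  f2 <- pca_expression(x)
  expect_identical(f1$scores, f2$scores)
  big <- apply(f1$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(big > 0))
})

test_that("gene-set rank score matches its closed-form extremes", {
  G <- 30; S <- 5
  expr <- matrix(seq_len(G), nrow = G, ncol = 2,
                 dimnames = list(sprintf("g%02d", 1:G), c("s1", "s2")))
  top <- rownames(expr)[(G - S + 1):G]
  sc <- gene_set_score(expr, top)
  expect_equal(as.numeric(sc),
               rep(((G - S) / 2) / sqrt((G^2 - 1) / (12 * S)), 2),
               tolerance = 1e-12)
  expect_equal(as.numeric(gene_set_score(expr, rownames(expr))), c(0, 0))
})

test_that("gene-set score is centered under random sets and rank-invariant", {
  set.seed(8)
  G <- 200
  expr <- matrix(rexp(G, 1 / 50), nrow = G, ncol = 1,
                 dimnames = list(sprintf("g%03d", 1:G), "s1"))
  draws <- vapply(1:1000, function(i)
    gene_set_score(expr, sample(rownames(expr), 10))[1], numeric(1))
  expect_lt(abs(mean(draws)), 0.1)

  set <- sample(rownames(expr), 10)
  mono <- expr^3 + 1  # strictly monotone transform preserves ranks
  expect_equal(gene_set_score(expr, set), gene_set_score(mono, set),
               tolerance = 1e-12)
  expect_error(gene_set_score(expr, "g001"), "fewer than 2")
})

test_that("group comparison reproduces the textbook t statistic", {
  a <- c(5.1, 4.8, 5.5, 5.0, 4.9)
  b <- c(6.2, 6.0, 5.8, 6.4, 6.1)
  vals <- c(a, b)
  grp <- rep(c("A", "B"), each = 5)
  res <- compare_groups(vals, grp, c("A", "B"))
  expect_equal(res$t, oracle_t_stat(a, b), tolerance = 1e-12)
  expect_equal(res$p, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  same <- compare_groups(rep(c(1, 1, 2, 2), 2), rep(c("A", "B"), 4),
                         c("A", "B"))
  expect_equal(same$t, 0)

  degen <- compare_groups(rep(3, 8), rep(c("A", "B"), 4), c("A", "B"))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("full assignment pipeline recovers planted groups", {
  runs <- lapply(1:5, function(s) subgroup_recovery_run(sim_config(seed = s)))
  expect_gte(median(vapply(runs, `[[`, numeric(1), "ari")), 0.9)
  tab <- table(runs[[1]]$assignment$group)
  expect_setequal(names(tab), c("G1", "G2", "G3", "G4"))
})

test_that("GMT gene sets round-trip and score end to end", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg01\tg02\tg03",
               "setB\tdesc\tg04\tg05"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g01", "g02", "g03"))

  set.seed(9)
  expr <- matrix(rexp(20 * 3), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
  sc <- gene_set_score(expr, sets$setA)
  expect_length(sc, 3)
})
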