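test_that("quality filter applies the Q >= 20 boundary", {
  calls <- toy_calls(pos = c(100, 200), qual = c(19, 20))
  kept <- filter_by_quality(calls)
  expect_identical(kept$pos, 200L)
  expect_identical(unname(attr(kept, "removed")["quality"]), 1L)

  expect_equal(nrow(filter_by_quality(calls[0, ])), 0)

  mixed <- toy_calls(pos = seq(100, 1000, by = 100),
                     qual = c(15, 30, 10, 40, 5, 50, 18, 60, 70, 80))
  expect_equal(nrow(filter_by_quality(mixed)), 6)
})

test_that("cluster filter removes runs of 3 within 35 bp", {
  expect_equal(nrow(filter_variant_clusters(toy_calls(c(100, 120, 134)))), 0)
  expect_equal(nrow(filter_variant_clusters(toy_calls(c(100, 150)))), 2)
  # 100,120,140 spans 40 > 35; 120,140,160 spans 40: nothing removed
  expect_equal(nrow(filter_variant_clusters(toy_calls(c(100, 120, 140, 160)))), 4)
  # contigs are independent
  two <- rbind(toy_calls(c(100, 110, 120), contig = "chr1"),
               toy_calls(c(100, 500, 900), contig = "chr2"))
  expect_identical(filter_variant_clusters(two)$contig, rep("chr2", 3))
})

test_that("cluster filter matches the brute-force window oracle", {
  for (s in 1:25) {
    set.seed(s)
    pos <- sort(sample.int(200, sample(3:10, 1)))
    kept <- filter_variant_clusters(toy_calls(pos))
    expect_identical(kept$pos, as.integer(oracle_cluster_filter(pos)),
                     info = paste("seed", s))
  }
})

test_that("site-annotation filter applies the FS/QD boundaries", {
  calls <- toy_calls(pos = c(1, 2, 3, 4) * 100,
                     fs = c(31, 30, 5, 5), qd = c(10, 10, 1.9, 2))
  kept <- filter_by_site_annotations(calls)
  expect_identical(kept$pos, c(200L, 400L))
  expect_equal(nrow(filter_by_site_annotations(calls[0, ])), 0)
  # records lacking annotations pass with a warning
  nofs <- toy_calls(100); nofs$fs <- NA_real_
  expect_warning(kept2 <- filter_by_site_annotations(nofs), "lacking")
  expect_equal(nrow(kept2), 1)
})

test_that("blacklist filter honors BED and site-list conventions", {
  calls <- toy_calls(pos = c(101, 250, 300))
  # BED [100, 101) covers 1-based position 101
  bed <- data.frame(contig = "chrS", start = 100L, end = 101L)
  expect_identical(filter_blacklists(calls, repeat_regions = bed)$pos,
                   c(250L, 300L))
  sites <- data.frame(contig = "chrS", pos = 250L)
  expect_identical(filter_blacklists(calls, editing_sites = sites)$pos,
                   c(101L, 300L))
  expect_identical(filter_blacklists(calls)$pos, calls$pos)
})

test_that("WES intersection keeps exactly the shared keys", {
  rna <- toy_calls(pos = c(1:5) * 100)
  expect_equal(nrow(intersect_with_wes(rna, rna[0, ])), 0)
  expect_identical(intersect_with_wes(rna, rna)$pos, rna$pos)
  expect_identical(intersect_with_wes(rna, rna[c(1, 3, 5), ])$pos,
                   c(100L, 300L, 500L))
})

test_that("somatic non-synonymous selection excludes germline and synonymous", {
  calls <- toy_calls(pos = (1:4) * 100,
                     effect = c("non_synonymous", "non_synonymous",
                                "synonymous", "non_synonymous"))
  tumor <- calls[1:3, ]
  normal <- calls[2, ]
  kept <- select_somatic_nonsynonymous(calls, tumor, normal)
  expect_identical(kept$pos, 100L)  # 200 germline, 300 synonymous, 400 not in WES
})

test_that("the cascade shrinks monotonically and matches stepwise filtering", {
  cfg <- small_config(seed = 19L)
  pop <- generate_cell_population(cfg)
  cs <- generate_variant_callset(pop$truth, cfg)
  step <- filter_by_quality(cs$rna)
  n1 <- nrow(step)
  step <- filter_variant_clusters(step)
  n2 <- nrow(step)
  step <- filter_by_site_annotations(step)
  n3 <- nrow(step)
  step <- filter_blacklists(step, cs$editing_sites, cs$repeats)
  n4 <- nrow(step)
  step <- intersect_with_wes(step, cs$wes_tumor)
  n5 <- nrow(step)
  step <- select_somatic_nonsynonymous(step, cs$wes_tumor, cs$wes_normal)
  expect_true(all(diff(c(nrow(cs$rna), n1, n2, n3, n4, n5, nrow(step))) <= 0))
  casc <- filter_cascade(cs)
  expect_identical(casc$id, step$id)
  # exact recovery of the planted somatic non-synonymous variants
  expect_identical(sort(casc$id), sort(grep("^SOM", cs$rna$id, value = TRUE)))
})

test_that("trinary genotype calls follow the depth/alt-fraction rule", {
  ref <- matrix(c(0, 0, 20, 5), 1, dimnames = list("v", paste0("c", 1:4)))
  alt <- matrix(c(0, 50, 1, 2), 1, dimnames = list("v", paste0("c", 1:4)))
  g <- call_cell_genotypes(ref, alt)
  expect_identical(unname(g$calls[1, ]),
                   c("NO_CALL", "MUT_EXPRESSED", "WT_EXPRESSED",
                     "MUT_EXPRESSED"))
  expect_error(call_cell_genotypes(ref, -alt), "nonnegative")
})

test_that("recurrence filter keeps variants mutant in >= 4 cells", {
  pat <- rbind(v1 = c(1, 1, 1, 0, 0), v2 = c(1, 1, 1, 1, 0))
  g <- call_cell_genotypes(matrix(10, 2, 5, dimnames = dimnames(pat)) * (1 - pat),
                           matrix(10, 2, 5, dimnames = dimnames(pat)) * pat)
  kept <- recurrence_filter(g)
  expect_identical(rownames(kept$calls), "v2")
  empty <- recurrence_filter(call_cell_genotypes(
    matrix(0, 0, 5, dimnames = list(NULL, paste0("c", 1:5))),
    matrix(0, 0, 5, dimnames = list(NULL, paste0("c", 1:5)))))
  expect_equal(nrow(empty$calls), 0)
})

test_that("mutation fraction counts NO_CALL cells in the denominator", {
  m <- toy_genotypes(matrix(rep(c(1, 0), c(27, 7)), 1, 34))
  expect_equal(unname(round(mutation_fraction(m), 3)), 0.794)
  m2 <- toy_genotypes(matrix(rep(c(1, 0), c(33, 10)), 1, 43))
  expect_equal(unname(round(mutation_fraction(m2), 3)), 0.767)
  m3 <- toy_genotypes(matrix(c(1, 1, NA, 0), 1, 4))  # NA -> NO_CALL
  expect_equal(unname(mutation_fraction(m3)), 2 / 4)
  expect_equal(unname(mutation_fraction(toy_genotypes(matrix(0, 1, 5)))), 0)
  expect_error(mutation_fraction(toy_genotypes(matrix(1, 1, 0))), "zero cells")
})

test_that("genotype concordance handles NO_CALL policies", {
  a <- toy_genotypes(matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 1, 10))
  b <- toy_genotypes(matrix(c(1, 1, 1, NA, NA, 0, 0, 0, 1, 1), 1, 10))
  res <- genotype_concordance(a, b, policy = "drop_nocall")
  expect_equal(res$overall, 6 / 8)
  res2 <- genotype_concordance(a, b, policy = "count_nocall")
  expect_equal(res2$overall, 6 / 10)
  expect_equal(genotype_concordance(a, a)$overall, 1)
  flip <- toy_genotypes(matrix(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), 1, 10))
  expect_equal(genotype_concordance(a, flip)$overall, 0)
})

test_that("ddPCR Poisson inversion and zygosity boundary are exact", {
  r <- ddpcr_quantify(500, 500, 1000)
  expect_equal(r$est_mut_copies, 1000 * log(2), tolerance = 1e-12)
  expect_equal(r$vaf, 0.5)
  expect_identical(r$zygosity, "het")

  r2 <- ddpcr_quantify(300, 0, 1000)
  expect_equal(r2$vaf, 1)
  expect_identical(r2$zygosity, "hom")

  expect_identical(ddpcr_zygosity(0.90), "het")     # strict inequality
  expect_identical(ddpcr_zygosity(0.90 + 1e-9), "hom")
  expect_error(ddpcr_quantify(1000, 10, 1000), "saturated")
  expect_true(is.na(ddpcr_quantify(0, 0, 1000)$vaf))
})

test_that("ddPCR estimator is consistent under simulated partitioning", {
  rel_err <- vapply(1:100, function(s) {
    sim <- simulate_ddpcr(5000, 3000, 20000, seed = s)
    est <- ddpcr_quantify(sim$mut_positive, sim$wt_positive, 20000)
    abs(est$est_mut_copies - 5000) / 5000
  }, numeric(1))
  expect_lt(mean(rel_err), 0.02)
})

test_that("homozygous variants never yield alt reads above depth", {
  pop <- generate_cell_population(small_config(seed = 23L, dropout_scale = 0.5))
  expect_true(all(pop$reads$alt <= pop$reads$alt + pop$reads$ref))
  expect_true(all(pop$reads$ref >= 0))
  hom <- pop$truth$dna_genotype == "hom"
  expect_true(all((pop$reads$alt + pop$reads$ref)[hom] >= pop$reads$alt[hom]))
})
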