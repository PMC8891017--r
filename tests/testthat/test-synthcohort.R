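# Synthetic two-cohort generators: panel structure, genotype/phenotype
# calibration, the summary-statistic fast path, and ICD code pairs.

test_that("variant panel satisfies its structural invariants", {
  panel <- generate_variant_panel(200, maf_range = c(1e-3, 0.1),
                                  enrichment_values = c(1, 2, 5),
                                  ld_block_size = 7, causal_fraction = 0.2,
                                  seed = 5)
  expect_equal(panel$maf_cohort2 / panel$maf_cohort1, panel$enrichment,
               tolerance = 1e-12)
  expect_true(all(diff(panel$position) > 0))
  expect_true(all(table(panel$ld_block_id) <= 7))
  expect_equal(sum(panel$true_beta != 0), 40)
  expect_true(all(panel$true_beta >= 0))
  # enrichment = 1 everywhere makes the cohorts' frequencies identical
  p1 <- generate_variant_panel(50, enrichment_values = 1, seed = 2)
  expect_identical(p1$maf_cohort1, p1$maf_cohort2)
  # determinism: same seed, byte-identical panels
  expect_identical(generate_variant_panel(50, seed = 9),
                   generate_variant_panel(50, seed = 9))
})

test_that("panel generation rejects impossible configurations", {
  expect_error(generate_variant_panel(0), ">= 1")
  expect_error(generate_variant_panel(10, maf_range = c(0.01, 0.5),
                                      enrichment_values = c(2)),
               "impossible")
})

test_that("cohort case fraction and allele frequencies are calibrated", {
  panel <- make_test_panel(n_variants = 30, seed = 21)
  coh <- generate_cohort(panel, "c1", 10000, prevalence = 0.1, seed = 3)
  # all true_beta are 0, so the case fraction is binomial around 0.1;
  # 4-SE band [0.088, 0.112]
  expect_gt(mean(coh$phenotype), 0.088)
  expect_lt(mean(coh$phenotype), 0.112)
  af <- colMeans(coh$dosage) / 2
  se4 <- 4 * sqrt(panel$maf_cohort1 * (1 - panel$maf_cohort1) / (2 * 10000))
  expect_true(all(abs(af - panel$maf_cohort1) < se4))
})

test_that("genotypes respect Hardy-Weinberg equilibrium at common MAF", {
  panel <- make_test_panel(n_variants = 10, maf_range = c(0.1, 0.4),
                           ld_rho = 0.3, seed = 31)
  coh <- generate_cohort(panel, "c1", 10000, prevalence = 0.2, seed = 32)
  for (j in seq_len(10)) {
    counts <- tabulate(coh$dosage[, j] + 1L, nbins = 3L)
    p_hat <- (2 * counts[3] + counts[2]) / (2 * sum(counts))
    expected <- sum(counts) * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
    chisq <- sum((counts - expected)^2 / expected)
    expect_gt(pchisq(chisq, df = 1, lower.tail = FALSE), 0.001)
  }
})

test_that("ld_rho controls within-block dosage correlation", {
  panel0 <- make_test_panel(n_variants = 10, maf_range = c(0.2, 0.4),
                            ld_rho = 0, seed = 41)
  coh0 <- generate_cohort(panel0, "c1", 10000, prevalence = 0.5, seed = 42)
  cm <- cor(coh0$dosage[, 1:5])
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)

  panel8 <- make_test_panel(n_variants = 10, maf_range = c(0.2, 0.4),
                            ld_rho = 0.8, seed = 41)
  coh8 <- generate_cohort(panel8, "c1", 10000, prevalence = 0.5, seed = 42)
  cm8 <- cor(coh8$dosage[, 1:5])
  expect_gt(mean(cm8[upper.tri(cm8)]), 0.3)
})

test_that("logistic fit recovers a simulated single-variant effect", {
  panel <- generate_variant_panel(1, maf_range = c(0.3, 0.3),
                                  enrichment_values = 1, causal_fraction = 1,
                                  effect_sampler = effect_sampler(0.5, "fixed"),
                                  seed = 51)
  coh <- generate_cohort(panel, "c1", 50000, prevalence = 0.1, seed = 52)
  fit <- glm(coh$phenotype ~ coh$dosage[, 1], family = binomial())
  expect_gt(coef(fit)[[2]], 0.4)
  expect_lt(coef(fit)[[2]], 0.6)
})

test_that("prevalence intercept calibration is exact in expectation", {
  panel <- generate_variant_panel(5, maf_range = c(0.1, 0.3),
                                  enrichment_values = 1, causal_fraction = 1,
                                  effect_sampler = effect_sampler(c(0.5, 1.0)),
                                  seed = 61)
  coh <- generate_cohort(panel, "c1", 5000, prevalence = 0.07, seed = 62)
  eta <- drop(coh$dosage %*% panel$true_beta)
  expect_equal(mean(plogis(coh$intercept + eta)), 0.07, tolerance = 1e-6)
})

test_that("summary-statistic fast path has the stated sampling law", {
  panel <- generate_variant_panel(1, maf_range = c(0.5, 0.5),
                                  enrichment_values = 1, seed = 71,
                                  causal_fraction = 0)
  st <- simulate_summary_stats(panel, 10000, 0.5, seed = 72)
  expect_equal(st$se, 1 / sqrt(2 * 10000 * 0.25 * 0.25), tolerance = 1e-12)
  # se scales as 1/sqrt(n): quadrupling n halves it
  st4 <- simulate_summary_stats(panel, 40000, 0.5, seed = 72)
  expect_equal(st4$se, st$se / 2, tolerance = 1e-12)
  # null calibration of Z over many draws
  panel_many <- generate_variant_panel(10000, maf_range = c(0.05, 0.4),
                                       enrichment_values = 1, seed = 73,
                                       causal_fraction = 0)
  stm <- simulate_summary_stats(panel_many, 5000, 0.1, seed = 74)
  expect_lt(abs(mean(stm$beta / stm$se)), 0.05)
})

test_that("summary fast path agrees with the individual-level path", {
  # matched parameters: same panel, n and prevalence; the two Z-score
  # samples should be indistinguishable by a two-sample KS test
  panel <- generate_variant_panel(200, maf_range = c(0.02, 0.2),
                                  enrichment_values = 1, ld_rho = 0,
                                  causal_fraction = 0.25,
                                  effect_sampler = effect_sampler(c(0.1, 0.2)),
                                  seed = 81)
  coh <- generate_cohort(panel, "c1", 20000, prevalence = 0.2, seed = 82)
  ind <- assoc_scan(coh, cfg = filter_config(firth_trigger_p = 1e-300))
  z_ind <- ind$beta / ind$se
  fast <- simulate_summary_stats(panel, 20000, 0.2, seed = 83)
  z_fast <- (fast$beta / fast$se)[match(ind$variant_id, fast$variant_id)]
  expect_gt(ks.test(z_ind, z_fast)$p.value, 0.01)
})

test_that("generators are pure functions of their seed", {
  panel <- make_test_panel(seed = 91)
  c1 <- generate_cohort(panel, "c1", 500, 0.1, seed = 92)
  c2 <- generate_cohort(panel, "c1", 500, 0.1, seed = 92)
  expect_identical(c1, c2)
  s1 <- simulate_summary_stats(panel, 1000, 0.1, seed = 93)
  s2 <- simulate_summary_stats(panel, 1000, 0.1, seed = 93)
  expect_identical(s1, s2)
  # and they do not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_cohort(panel, "c1", 100, 0.1, seed = 94))
  expect_identical(rnorm(1), before)
})

test_that("ICD pairs hit their Jaccard targets", {
  pairs <- generate_icd_pairs(6, 80, c(1, 0, 0.5, 0.7, 0.3, 0.85), seed = 101)
  expect_true(all(abs(pairs$jaccard - pairs$jaccard_target) <= 0.05))
  expect_identical(sort(pairs$codes_cohort1[[1]]), sort(pairs$codes_cohort2[[1]]))
  expect_length(intersect(pairs$codes_cohort1[[2]], pairs$codes_cohort2[[2]]), 0)
  # target 0.5 realized exactly: 2 shared of 4 total
  expect_equal(pairs$jaccard[3], 0.5)
  expect_error(generate_icd_pairs(1, 80, 1.2, seed = 1), "\\[0, 1\\]")
})
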