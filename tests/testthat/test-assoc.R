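# Association testing: inclusion filters, score test, Firth fallback,
# quantitative biomarker scan.

test_that("inclusion filters apply the strict case-count and MAC rules", {
  # exactly 100 cases fails the strict >100 rule
  expect_false(apply_inclusion_filters(100, 50, 25, 25)$include)
  expect_equal(apply_inclusion_filters(100, 50, 25, 25)$reason, "case_count")
  # MAC 3/2 split fails the per-stratum rule even though the total passes
  f <- apply_inclusion_filters(101, 5, 3, 2)
  expect_false(f$include)
  expect_equal(f$reason, "stratum_mac")
  # boundary satisfaction: 101 cases, MAC 5 total, 3/3 strata, INFO 1
  expect_true(apply_inclusion_filters(101, 5, 3, 3, info = 1)$include)
  # INFO at the threshold fails (strict >)
  expect_false(apply_inclusion_filters(101, 10, 5, 5, info = 0.6)$include)
  expect_equal(apply_inclusion_filters(101, 10, 5, 5, info = 0.6)$reason, "info")
})

test_that("filters give the same include set regardless of evaluation order", {
  set.seed(1)
  cases <- sample(50:200, 50, replace = TRUE)
  mac_c <- sample(0:10, 50, replace = TRUE)
  mac_k <- sample(0:10, 50, replace = TRUE)
  info <- runif(50, 0.3, 1)
  include <- mapply(function(nc, a, b, i)
    apply_inclusion_filters(nc, a + b, a, b, i)$include,
    cases, mac_c, mac_k, info)
  # conjunction evaluated as a whole must agree with the short-circuit path
  manual <- cases > 100 & (mac_c + mac_k) >= 5 & pmin(mac_c, mac_k) >= 3 & info > 0.6
  expect_identical(unname(include), unname(manual))
})

test_that("score test is calibrated under the null", {
  set.seed(5)
  n <- 5000
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-2 + 0.3 * covs[, "age"]))
  nf <- cwasmeta:::fit_null_logistic(y, covs)
  pvals <- replicate(1000, {
    d <- rbinom(n, 2, 0.2)
    fit_logistic_score(d, y, covs, null_fit = nf)$p_value
  })
  t1 <- mean(pvals < 0.05)
  expect_gt(t1, 0.035)
  expect_lt(t1, 0.065)
})

test_that("score statistic is zero for dosage balanced across outcomes", {
  y <- rep(c(0, 1), each = 10)
  d <- rep(c(0, 2, 0, 2), each = 5)  # identical dosage profile in each class
  st <- fit_logistic_score(d, y)
  expect_equal(st$beta, 0, tolerance = 1e-12)
  expect_equal(st$p_value, 1, tolerance = 1e-12)
})

test_that("score-based estimate recovers a simulated effect", {
  set.seed(6)
  est <- replicate(200, {
    n <- 20000
    d <- rbinom(n, 2, 0.2)
    y <- rbinom(n, 1, plogis(-2 + 0.3 * d))
    fit_logistic_score(d, y)$beta
  })
  expect_gt(mean(est), 0.27)
  expect_lt(mean(est), 0.33)
})

test_that("summary-stat p-values are consistent with beta/se", {
  set.seed(7)
  n <- 4000
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1.5 + 0.2 * d))
  st <- fit_logistic_score(d, y)
  expect_equal(st$p_value, 2 * pnorm(-abs(st$beta / st$se)), tolerance = 1e-6)
  expect_equal(st$mac_cases + st$mac_controls, st$mac_total)
})

test_that("Firth regression stays finite under complete separation", {
  # all 8 carriers are cases: plain ML diverges, Firth does not
  y <- c(rep(1, 20), rep(0, 80))
  d <- c(rep(1, 8), rep(0, 92))
  st <- fit_firth(d, y)
  expect_true(is.finite(st$beta))
  expect_true(is.finite(st$se))
  expect_true(st$converged)
  # se is defined through the LRT p-value: |beta|/se = z(p) by construction
  z <- qnorm(st$p_value / 2, lower.tail = FALSE)
  expect_equal(abs(st$beta) / st$se, z, tolerance = 1e-9)
})

test_that("Firth agrees with plain logistic on a well-behaved common variant", {
  set.seed(8)
  n <- 20000
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.15 * d))
  st_f <- fit_firth(d, y)
  b_ml <- coef(glm(y ~ d, family = binomial()))[["d"]]
  expect_lt(abs(st_f$beta - b_ml) / abs(b_ml), 0.05)
})

test_that("score and Firth p-values agree in the asymptotic regime", {
  set.seed(9)
  n <- 20000
  for (rep in 1:5) {
    d <- rbinom(n, 2, 0.25)
    y <- rbinom(n, 1, plogis(-1.8 + 0.01 * d))
    st_s <- fit_logistic_score(d, y)
    if (abs(st_s$beta / st_s$se) >= 2) next
    st_f <- fit_firth(d, y)
    expect_lt(abs(st_f$p_value - st_s$p_value) / st_s$p_value, 0.10)
  }
})

test_that("association scan applies the Firth fallback and logs exclusions", {
  panel <- generate_variant_panel(40, maf_range = c(0.005, 0.2),
                                  enrichment_values = 1, ld_rho = 0,
                                  causal_fraction = 0.2,
                                  effect_sampler = effect_sampler(c(0.72, 1.07)),
                                  seed = 10)
  coh <- generate_cohort(panel, "c1", 4000, prevalence = 0.2, seed = 11)
  st <- assoc_scan(coh, panel = panel)
  expect_true(all(st$method %in% c("score", "firth")))
  # every variant with score p < 0.01 must carry the firth method label
  expect_true(all(st$method[st$p_value < 0.01] == "firth"))
  log <- attr(st, "filter_log")
  expect_true(is.data.frame(log))
  expect_equal(nrow(st) + nrow(log), 40)
})

test_that("monomorphic dosage and single-class phenotypes error", {
  expect_error(fit_logistic_score(rep(1, 50), rbinom(50, 1, 0.5)), "no variation")
  expect_error(fit_logistic_score(rbinom(50, 2, 0.3), rep(1, 50)), "both classes")
})

test_that("quantitative scan recovers a biomarker slope", {
  set.seed(12)
  n <- 50000
  d <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "v1"))
  bio <- 0.047 * d[, 1] + rnorm(n)
  res <- scan_quantitative(bio, d)
  expect_gt(res$beta, 0.04)
  expect_lt(res$beta, 0.055)
})

test_that("quantitative scan is calibrated under permutation", {
  set.seed(13)
  n <- 2000
  D <- matrix(rbinom(n * 1000, 2, 0.2), n, 1000)
  flagged <- replicate(100, {
    bio <- rnorm(n)
    sum(scan_quantitative(bio, D)$significant)
  })
  # at alpha 1e-6 essentially nothing should be flagged
  expect_lte(max(flagged), 2)
  # alpha = 1 flags everything
  res_all <- scan_quantitative(rnorm(n), D[, 1:10], alpha = 1)
  expect_true(all(res_all$significant))
  expect_error(scan_quantitative(rep(1, n), D[, 1:2]), "constant")
})
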