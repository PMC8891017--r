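# Significance tiers, clumping, region merging, fold enrichment, pleiotropy.

meta_row <- function(p_meta, directions = "++", p1 = 1e-6, p2 = 1e-4,
                     concordant = NULL) {
  if (is.null(concordant))
    concordant <- !grepl("-", directions) || !grepl("\\+", directions)
  out <- data.frame(variant_id = "v1", beta_meta = 0.1, se_meta = 0.02,
                    z_meta = 5, p_meta = p_meta, directions = directions,
                    n_total = 1000L, concordant = concordant,
                    stringsAsFactors = FALSE)
  out$p_cohort <- I(list(c(c1 = p1, c2 = p2)))
  out
}

test_that("significance tiers follow the three-part rule", {
  # conservative: meta p, concordance, and both cohorts replicating
  t1 <- classify_significance(meta_row(1e-10, "++", 1e-6, 3e-4))
  expect_equal(t1$tier, "conservative")
  # discordant direction caps the tier at genome-wide
  t2 <- classify_significance(meta_row(1e-10, "+-"))
  expect_equal(t2$tier, "genome_wide")
  # between the thresholds: genome-wide only
  t3 <- classify_significance(meta_row(3e-8, "++"))
  expect_equal(t3$tier, "genome_wide")
  expect_equal(classify_significance(meta_row(1e-7, "++"))$tier, "none")
  # a failed per-cohort replication blocks the conservative tier
  t4 <- classify_significance(meta_row(1e-10, "++", 1e-6, 0.2))
  expect_equal(t4$tier, "genome_wide")
  expect_false(t4$replicated_both)
  # missing cohort evidence: tier from meta p alone, flagged degraded
  m <- meta_row(1e-10, "++"); m$p_cohort <- I(list(c(c1 = 1e-6)))
  t5 <- classify_significance(m)
  expect_true(t5$degraded)
  expect_equal(t5$tier, "conservative")
})

test_that("Bonferroni threshold reproduces the reported rounding", {
  b <- bonferroni_threshold(26.8e6, reported = TRUE)
  expect_equal(b$exact, 0.05 / 26.8e6, tolerance = 1e-12)
  expect_equal(b$reported, 2e-9)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(1e6), 5e-8)
})

test_that("greedy clumping follows lead order, window, and r2", {
  meta <- data.frame(
    variant_id = c("v1", "v2", "v3"), chromosome = "1",
    position = c(1000000, 1010000, 1020000),
    p_meta = c(1e-12, 1e-9, 1e-8), stringsAsFactors = FALSE)
  ld <- data.frame(id1 = c("v1", "v1", "v2"), id2 = c("v2", "v3", "v3"),
                   r2 = c(0.5, 0.05, 0.04), stringsAsFactors = FALSE)
  cl <- clump(meta, ld)
  expect_equal(cl$lead_variant[cl$variant_id == "v2"], "v1")
  expect_equal(cl$lead_variant[cl$variant_id == "v3"], "v3")
  expect_equal(length(unique(cl$clump_id)), 2)
  # mutually unlinked variants each form their own clump
  ld0 <- data.frame(id1 = character(0), id2 = character(0), r2 = numeric(0))
  cl0 <- clump(meta, ld0)
  expect_equal(length(unique(cl0$clump_id)), 3)
})

test_that("MHC variants form a single pseudo-clump regardless of LD", {
  meta <- data.frame(
    variant_id = c("m1", "m2", "out"), chromosome = "6",
    position = c(26000000, 33000000, 40000000),
    p_meta = c(1e-9, 1e-20, 1e-10), stringsAsFactors = FALSE)
  ld <- data.frame(id1 = "m1", id2 = "m2", r2 = 0.0)
  cl <- clump(meta, ld)
  expect_equal(cl$clump_id[cl$variant_id == "m1"], "MHC")
  expect_equal(cl$clump_id[cl$variant_id == "m2"], "MHC")
  expect_false(cl$clump_id[cl$variant_id == "out"] == "MHC")
  # the MHC lead is still the most significant member
  expect_equal(unique(cl$lead_variant[cl$is_mhc]), "m2")
})

test_that("greedy clumping equals an exhaustive reference on random instances", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    ids <- sprintf("v%02d", seq_len(n))
    meta <- data.frame(variant_id = ids, chromosome = "2",
                       position = sort(sample.int(3e6, n)),
                       p_meta = 10^(-runif(n, 4, 12)),
                       stringsAsFactors = FALSE)
    r2mat <- matrix(0, n, n, dimnames = list(ids, ids))
    pairs <- which(upper.tri(r2mat), arr.ind = TRUE)
    vals <- ifelse(runif(nrow(pairs)) < 0.4, runif(nrow(pairs)), 0)
    r2mat[pairs] <- vals
    r2mat <- r2mat + t(r2mat); diag(r2mat) <- 1
    cl <- clump(meta, r2mat, window_bp = 500000, r2_threshold = 0.1)
    ref <- reference_clump(meta, r2mat, 500000, 0.1)
    got <- lapply(split(cl$variant_id, cl$clump_id), sort)
    got <- unname(got[order(vapply(got, `[`, character(1), 1))])
    want <- lapply(ref, `[[`, "members")
    want <- unname(want[order(vapply(want, `[`, character(1), 1))])
    expect_identical(got, want)
    # partition property: every variant in exactly one clump
    expect_setequal(cl$variant_id, ids)
    expect_false(anyNA(cl$clump_id))
  }
})

test_that("regions merge overlapping envelopes and keep gene sentinels", {
  clumps <- data.frame(
    clump_id = c("clump001", "clump001", "clump002", "clump003"),
    lead_variant = c("a", "a", "b", "c"),
    variant_id = c("a", "a2", "b", "c"),
    chromosome = "3",
    position = c(1000000, 1005000, 1400000, 2700000),
    p_meta = c(1e-12, 1e-8, 1e-10, 1e-9),
    is_mhc = FALSE,
    gene = c("G1", "G1", "G2", "G3"),
    stringsAsFactors = FALSE)
  reg <- merge_regions(clumps)
  # leads 400 kb apart merge; the lead 1.3 Mb further does not
  expect_equal(nrow(reg), 2)
  r1 <- reg[reg$start == 1000000, ]
  expect_equal(r1$sentinel_variant, "a")
  gs <- r1$gene_sentinels[[1]]
  expect_setequal(gs$gene, c("G1", "G2"))
  expect_equal(gs$variant_id[gs$gene == "G2"], "b")
})

test_that("sentinel ties break lexicographically by variant id", {
  clumps <- data.frame(
    clump_id = "clump001", lead_variant = "vb",
    variant_id = c("vb", "va"), chromosome = "1",
    position = c(100, 200), p_meta = c(1e-9, 1e-9),
    is_mhc = FALSE, stringsAsFactors = FALSE)
  reg <- merge_regions(clumps)
  expect_equal(reg$sentinel_variant, "va")
})

test_that("MHC regions carry the fixed bounds", {
  clumps <- data.frame(
    clump_id = "MHC", lead_variant = "m1",
    variant_id = c("m1", "m2"), chromosome = "6",
    position = c(26000000, 30000000), p_meta = c(1e-12, 1e-9),
    is_mhc = TRUE, stringsAsFactors = FALSE)
  reg <- merge_regions(clumps)
  expect_true(reg$is_mhc)
  expect_equal(reg$start, 25500000)
  expect_equal(reg$end, 34000000)
  expect_equal(reg$region_id, "region_MHC")
})

test_that("fold enrichment reproduces tabulated log2 values", {
  fe1 <- fold_enrichment(0.0152, 392814, 0.0872, 260405)
  expect_equal(round(fe1$log2_fe, 2), 2.52)
  expect_true(fe1$flagged)
  fe2 <- fold_enrichment(0.0024, 392814, 0.0064, 260405)
  expect_equal(round(fe2$log2_fe, 2), 1.42)
  # equal frequencies: log2 fold enrichment of zero
  expect_equal(fold_enrichment(0.01, 1000, 0.01, 1000)$log2_fe, 0)
})

test_that("fold enrichment is antisymmetric under cohort swap", {
  fe_a <- fold_enrichment(0.01, 5000, 0.04, 3000)
  fe_b <- fold_enrichment(0.04, 3000, 0.01, 5000)
  expect_equal(fe_a$log2_fe, -fe_b$log2_fe, tolerance = 1e-12)
  expect_equal(fe_a$fisher_p, fe_b$fisher_p, tolerance = 1e-9)
  # zero frequency handled with infinite sentinel and a valid test
  fe0 <- fold_enrichment(0, 1000, 0.01, 1000)
  expect_identical(fe0$log2_fe, Inf)
  expect_true(is.finite(fe0$fisher_p))
})

test_that("Fisher p equals the hypergeometric tail-sum oracle", {
  set.seed(55)
  for (i in 1:50) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    af1 <- runif(1, 0.005, 0.3); af2 <- runif(1, 0.005, 0.3)
    fe <- fold_enrichment(af1, n1, af2, n2)
    expect_equal(fe$fisher_p, hypergeom_fisher_p(fe$allele_counts),
                 tolerance = 1e-10)
  }
})

test_that("pleiotropy counts unique disease clusters per distinct region", {
  regions <- data.frame(
    region_id = c("r1", "r1", "r1", "r1", "r1", "r2", "r1"),
    disease_cluster = c("a", "b", "c", "d", "e", "a", "a"),
    stringsAsFactors = FALSE)
  pc <- count_pleiotropy(regions)
  expect_equal(pc$n_clusters[pc$region_id == "r1"], 5)
  expect_true(pc$pleiotropic[pc$region_id == "r1"])
  expect_equal(pc$n_clusters[pc$region_id == "r2"], 1)
  expect_false(pc$pleiotropic[pc$region_id == "r2"])
})
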