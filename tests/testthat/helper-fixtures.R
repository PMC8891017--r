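# Shared fixtures and independent reference implementations used as
# oracles across test files.

# Small common-variant panel handy for individual-level tests.
make_test_panel <- function(n_variants = 20, maf_range = c(0.05, 0.4),
                            enrichment_values = 1, ld_block_size = 5,
                            ld_rho = 0.5, causal_fraction = 0, seed = 11) {
  generate_variant_panel(n_variants, maf_range = maf_range,
                         enrichment_values = enrichment_values,
                         ld_block_size = ld_block_size, ld_rho = ld_rho,
                         causal_fraction = causal_fraction, seed = seed)
}

# A one-row summary-stat record with free fields, for harmonization and
# meta tests.
make_stat <- function(variant_id = "v1", cohort_id = "c1", a0 = "C", a1 = "T",
                      af = 0.2, beta = 0.1, se = 0.05, p = NULL, n = 1000) {
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(variant_id = variant_id, cohort_id = cohort_id,
             allele_ref = a0, allele_alt = a1, af_alt = af,
             beta = beta, se = se, p_value = p, n = n, n_cases = n %/% 10,
             mac_total = round(2 * n * af), mac_cases = round(2 * (n %/% 10) * af),
             mac_controls = round(2 * n * af) - round(2 * (n %/% 10) * af),
             method = "score", info_score = 1, converged = TRUE,
             stringsAsFactors = FALSE)
}

# Exhaustive reference implementation of greedy clumping, written
# independently of the package version: no MHC handling, explicit loops.
reference_clump <- function(meta, r2mat, window_bp, r2_threshold) {
  remaining <- meta$variant_id
  clumps <- list()
  while (length(remaining) > 0) {
    sub <- meta[meta$variant_id %in% remaining, ]
    sub <- sub[order(sub$p_meta, sub$variant_id), ]
    lead <- sub$variant_id[1]
    lead_row <- meta[meta$variant_id == lead, ]
    members <- lead
    for (v in setdiff(remaining, lead)) {
      vrow <- meta[meta$variant_id == v, ]
      if (vrow$chromosome == lead_row$chromosome &&
          abs(vrow$position - lead_row$position) <= window_bp &&
          r2mat[lead, v] > r2_threshold) {
        members <- c(members, v)
      }
    }
    clumps[[length(clumps) + 1]] <- list(lead = lead, members = sort(members))
    remaining <- setdiff(remaining, members)
  }
  clumps
}

# Two-sided Fisher p by brute-force hypergeometric tail summation over all
# tables with the observed margins (probability-at-most-observed rule).
hypergeom_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Build a two-cluster MR estimate set: 10 variants at causal ratio -0.5
# and 10 at +0.5. Exposure effects span an order of magnitude (as
# instrument strengths do in real GWAS panels) and outcome estimates are
# precise, as from a large outcome GWAS.
make_two_cluster_estimates <- function(seed = 42, se_y = 0.01) {
  set.seed(seed)
  truth <- rep(c(-0.5, 0.5), each = 10)
  bx <- exp(runif(20, log(0.1), log(1.0))) * sample(c(-1, 1), 20, TRUE)
  do.call(rbind, lapply(seq_along(truth), function(i) {
    ratio_estimate(beta_x = bx[i], se_x = 0.02,
                   beta_y = rnorm(1, truth[i] * bx[i], se_y),
                   se_y = se_y, variant_id = sprintf("v%02d", i))
  }))
}

# A disease-loci panel as in a clustered-MR sensitivity analysis: most
# loci have no effect on the secondary outcome (null mechanism), two
# small groups carry opposite-sign causal ratios. This is the natural
# input for permutation-null calibration: permuting the outcome column
# must destroy the variant-outcome matching.
make_mr_locus_panel <- function(seed = 42, n_null = 20, n_per = 7,
                                se_y = 0.01) {
  set.seed(seed)
  truth <- c(rep(0, n_null), rep(-0.5, n_per), rep(0.5, n_per))
  n <- length(truth)
  bx <- exp(runif(n, log(0.1), log(1.0))) * sample(c(-1, 1), n, TRUE)
  do.call(rbind, lapply(seq_len(n), function(i)
    ratio_estimate(beta_x = bx[i], se_x = 0.02,
                   beta_y = rnorm(1, truth[i] * bx[i], se_y),
                   se_y = se_y, variant_id = sprintf("v%02d", i))))
}
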