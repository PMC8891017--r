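# Synthetic two-cohort study generators: variant panels with cohort-specific
# allele enrichment, HWE genotypes with block-structured LD, binary disease
# status from a logistic liability with an exactly calibrated prevalence,
# a summary-statistic fast path, and paired ICD-10 code sets.

#' Positive log odds-ratio effect pool
#'
#' Default pool of positive per-allele log odds ratios used when drawing
#' causal effect sizes for synthetic variants. The values span the range
#' reported for coding disease associations from modest common-variant
#' effects to large rare-variant effects.
#'
#' @format Numeric vector of positive log odds ratios.
#' @export
cwas_effect_pool <- c(0.14, 0.19, 0.21, 0.24, 0.38, 0.72, 1.07, 1.38, 1.52, 2.09)

#' Construct an effect-size sampler
#'
#' @param pool Multiset of positive log odds ratios to draw from.
#' @param mode `"uniform-from-pool"` draws uniformly with replacement from
#'   `pool`; `"fixed"` always returns the first pool entry.
#' @return An object of class `effect_sampler`.
#' @export
effect_sampler <- function(pool = cwas_effect_pool,
                           mode = c("uniform-from-pool", "fixed")) {
  mode <- match.arg(mode)
  if (!is.numeric(pool) || length(pool) == 0L || any(!is.finite(pool)) || any(pool <= 0))
    stop("effect pool entries must all be positive finite numbers", call. = FALSE)
  structure(list(pool = as.numeric(pool), mode = mode), class = "effect_sampler")
}

#' Draw effect sizes from a sampler
#'
#' @param sampler An [effect_sampler()].
#' @param n Number of effects to draw.
#' @return Numeric vector of length `n`, all positive.
#' @export
draw_effects <- function(sampler, n) {
  stopifnot(inherits(sampler, "effect_sampler"), n >= 0)
  if (n == 0L) return(numeric(0))
  switch(sampler$mode,
    "uniform-from-pool" = sample(sampler$pool, n, replace = TRUE),
    "fixed" = rep(sampler$pool[[1L]], n))
}

#' Generate a synthetic variant panel
#'
#' Builds a biallelic variant panel for a two-cohort study. Cohort 1 is the
#' reference cohort; cohort 2 carries a per-variant allele enrichment so that
#' `maf_cohort2 = enrichment * maf_cohort1`. Variants are laid out with
#' strictly increasing positions on one chromosome and partitioned into
#' consecutive LD blocks.
#'
#' @param n_variants Number of variants (>= 1).
#' @param maf_range Length-2 numeric `(low, high)` with
#'   `0 < low <= high <= 0.5`; cohort-1 MAFs are drawn log-uniformly.
#' @param enrichment_values Positive reals; each variant's enrichment is
#'   drawn uniformly from this set. Every value must satisfy
#'   `enrichment * high < 1`.
#' @param ld_block_size Number of consecutive variants per LD block.
#' @param ld_rho Latent-Gaussian within-block correlation in `[0, 1)`.
#' @param causal_fraction Fraction of variants given a nonzero `true_beta`.
#' @param effect_sampler An [effect_sampler()] for the causal effects.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param chromosome Chromosome label for the panel.
#' @param info_score Imputation INFO score recorded per variant (default 1,
#'   sequencing-like).
#' @return A `data.frame` of class `variant_panel` with columns
#'   `variant_id`, `chromosome`, `position`, `allele_ref`, `allele_alt`,
#'   `gene`, `maf_cohort1`, `maf_cohort2`, `enrichment`, `ld_block_id`,
#'   `true_beta`, `info_score`; `ld_rho` is carried as an attribute.
#' @export
generate_variant_panel <- function(n_variants,
                                   maf_range = c(1e-4, 0.01),
                                   enrichment_values = c(1, 2, 5, 10, 20, 50),
                                   ld_block_size = 10L,
                                   ld_rho = 0.5,
                                   causal_fraction = 0.1,
                                   effect_sampler = cwasmeta::effect_sampler(),
                                   seed = 1L,
                                   chromosome = "1",
                                   info_score = 1.0) {
  if (!is_scalar_number(n_variants) || n_variants < 1)
    stop("`n_variants` must be >= 1", call. = FALSE)
  n_variants <- as.integer(n_variants)
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0,
            maf_range[1] <= maf_range[2], maf_range[2] <= 0.5)
  if (any(enrichment_values <= 0))
    stop("enrichment values must be positive", call. = FALSE)
  if (any(enrichment_values * maf_range[2] >= 1))
    stop("enrichment x maf >= 1: impossible cohort-2 allele frequency", call. = FALSE)
  stopifnot(ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            causal_fraction >= 0, causal_fraction <= 1)
  stopifnot(inherits(effect_sampler, "effect_sampler"))

  with_seed(seed, {
    maf1 <- exp(stats::runif(n_variants, log(maf_range[1]), log(maf_range[2])))
    enrich <- sample(as.numeric(enrichment_values), n_variants, replace = TRUE)
    maf2 <- enrich * maf1
    pos <- cumsum(sample(1000:10000, n_variants, replace = TRUE))
    block <- as.integer((seq_len(n_variants) - 1L) %/% ld_block_size + 1L)
    bases <- c("A", "C", "G", "T")
    complement <- c(A = "T", C = "G", G = "C", T = "A")
    a0 <- sample(bases, n_variants, replace = TRUE)
    # avoid strand-ambiguous (A/T, G/C) pairs so harmonization keeps
    # every synthetic variant
    a1 <- vapply(a0, function(b) sample(setdiff(bases, c(b, complement[[b]])), 1L),
                 character(1))
    n_causal <- round(causal_fraction * n_variants)
    beta <- numeric(n_variants)
    if (n_causal > 0) {
      idx <- sample.int(n_variants, n_causal)
      beta[idx] <- draw_effects(effect_sampler, n_causal)
    }
    panel <- data.frame(
      variant_id = sprintf("var%05d", seq_len(n_variants)),
      chromosome = chromosome,
      position = pos,
      allele_ref = unname(a0),
      allele_alt = unname(a1),
      gene = sprintf("GENE%03d", block),
      maf_cohort1 = maf1,
      maf_cohort2 = maf2,
      enrichment = enrich,
      ld_block_id = block,
      true_beta = beta,
      info_score = rep(info_score, n_variants),
      stringsAsFactors = FALSE
    )
    attr(panel, "ld_rho") <- ld_rho
    attr(panel, "ld_block_size") <- as.integer(ld_block_size)
    class(panel) <- c("variant_panel", "data.frame")
    panel
  })
}

#' Covariate recipe for association models
#'
#' Simulates the standard covariate set: age, age squared, sex, their
#' interactions, and simulated genetic principal components. A sex-specific
#' recipe drops the sex-related terms.
#'
#' @param n Number of individuals.
#' @param n_pcs Number of simulated principal components (default 10).
#' @param sex_specific Drop sex and sex-interaction covariates (for
#'   sex-specific disease endpoints analysed within one sex).
#' @return Numeric matrix with named columns.
#' @export
covariate_recipe <- function(n, n_pcs = 10L, sex_specific = FALSE) {
  age <- stats::runif(n, 40, 70)
  age_c <- (age - 55) / 10
  pcs <- matrix(stats::rnorm(n * n_pcs), n, n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  if (sex_specific) {
    cbind(age = age_c, age2 = age_c^2, pcs)
  } else {
    sex <- stats::rbinom(n, 1L, 0.5)
    cbind(age = age_c, age2 = age_c^2, sex = sex,
          age_sex = age_c * sex, age2_sex = age_c^2 * sex, pcs)
  }
}

# Simulate haplotypes for one LD block through a latent Gaussian copula with
# equicorrelation rho, thresholded at the allele frequency. Two independent
# haplotypes per individual give HWE genotype frequencies marginally.
simulate_block_dosages <- function(n, mafs, rho) {
  m <- length(mafs)
  thr <- stats::qnorm(mafs)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    shared <- stats::rnorm(n)
    z <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
    dos <- dos + (z < rep(thr, each = n))
  }
  dos
}

# Solve the logistic intercept so that the mean case probability over the
# realized genotype distribution equals the target prevalence.
solve_prevalence_intercept <- function(eta, prevalence, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  stats::uniroot(f, c(-80, 80), tol = tol * 1e-3)$root
}

#' Generate an individual-level synthetic cohort
#'
#' Draws HWE genotypes per LD block via a latent Gaussian copula at the
#' panel's within-block correlation, then binary disease status from a
#' logistic model whose intercept is solved numerically so that the
#' population (in-sample expected) prevalence matches the target to 1e-6.
#'
#' @param panel A [generate_variant_panel()] result.
#' @param cohort_id Cohort label stored in the result.
#' @param n_individuals Number of individuals (>= 1).
#' @param prevalence Target disease prevalence in (0, 1).
#' @param seed Integer seed.
#' @param cohort Which panel MAF column to use: 1 (reference) or 2 (enriched).
#' @param sex_specific Use the sex-specific covariate recipe.
#' @return A list of class `cohort_dataset` with elements `cohort_id`,
#'   `n_individuals`, `dosage` (individuals x variants integer matrix),
#'   `phenotype` (0/1), `prevalence`, `covariates`, `variant_id`, `intercept`.
#' @export
generate_cohort <- function(panel, cohort_id, n_individuals, prevalence,
                            seed = 1L, cohort = 1L, sex_specific = FALSE) {
  stopifnot(inherits(panel, "variant_panel"))
  if (!is_scalar_number(n_individuals) || n_individuals < 1)
    stop("`n_individuals` must be >= 1", call. = FALSE)
  stop_if_not_fraction(prevalence, "prevalence")
  stopifnot(cohort %in% c(1L, 2L))
  n <- as.integer(n_individuals)
  mafs <- if (cohort == 1L) panel$maf_cohort1 else panel$maf_cohort2
  if (any(mafs <= 0 | mafs >= 1))
    stop("panel allele frequencies for this cohort must lie in (0, 1)", call. = FALSE)
  rho <- attr(panel, "ld_rho") %||% 0

  with_seed(seed, {
    dos <- matrix(0L, n, nrow(panel))
    for (b in unique(panel$ld_block_id)) {
      j <- which(panel$ld_block_id == b)
      dos[, j] <- simulate_block_dosages(n, mafs[j], rho)
    }
    colnames(dos) <- panel$variant_id
    causal <- which(panel$true_beta != 0)
    eta <- if (length(causal)) drop(dos[, causal, drop = FALSE] %*% panel$true_beta[causal]) else rep(0, n)
    alpha <- solve_prevalence_intercept(eta, prevalence)
    y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
    covs <- covariate_recipe(n, sex_specific = sex_specific)
    structure(list(cohort_id = cohort_id, n_individuals = n, dosage = dos,
                   phenotype = y, prevalence = prevalence, covariates = covs,
                   variant_id = panel$variant_id, intercept = alpha),
              class = "cohort_dataset")
  })
}

#' Simulate summary statistics directly (fast path)
#'
#' Draws per-variant effect estimates from the asymptotic sampling
#' distribution of the logistic score estimator:
#' `beta_hat ~ Normal(true_beta, 1/v)` with
#' `v = 2 n p (1-p) phi (1-phi)`, `se = 1/sqrt(v)` and a Wald p-value. This
#' fast path must agree in distribution with the individual-level path and
#' exists for large power grids.
#'
#' @param panel A [generate_variant_panel()] result.
#' @param n Cohort sample size.
#' @param prevalence Disease prevalence phi in (0, 1).
#' @param seed Integer seed.
#' @param cohort Which panel MAF column to use (1 or 2).
#' @param cohort_id Cohort label for the output rows.
#' @return A `data.frame` of summary statistics (one row per variant) with
#'   the standard columns (`variant_id`, `beta`, `se`, `p_value`, counts,
#'   `method = "score"`).
#' @export
simulate_summary_stats <- function(panel, n, prevalence, seed = 1L,
                                   cohort = 1L, cohort_id = paste0("cohort", cohort)) {
  stopifnot(inherits(panel, "variant_panel"))
  if (!is_scalar_number(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  stop_if_not_fraction(prevalence, "prevalence")
  p <- if (cohort == 1L) panel$maf_cohort1 else panel$maf_cohort2
  v <- 2 * n * p * (1 - p) * prevalence * (1 - prevalence)
  if (any(v <= 0)) stop("non-positive score information v; check MAF and prevalence", call. = FALSE)
  se <- 1 / sqrt(v)
  with_seed(seed, {
    beta_hat <- stats::rnorm(nrow(panel), panel$true_beta, se)
    z <- beta_hat / se
    n_cases <- round(n * prevalence)
    mac_total <- round(2 * n * p)
    mac_cases <- round(2 * n_cases * p)
    summary_stat(
      variant_id = panel$variant_id, cohort_id = cohort_id,
      allele_ref = panel$allele_ref, allele_alt = panel$allele_alt,
      af_alt = p, beta = beta_hat, se = se,
      p_value = 2 * stats::pnorm(-abs(z)),
      n = n, n_cases = n_cases,
      mac_total = mac_total, mac_cases = mac_cases,
      mac_controls = mac_total - mac_cases,
      method = "score", info_score = panel$info_score)
  })
}

# Canonical summary-statistic record constructor (shared column layout).
summary_stat <- function(variant_id, cohort_id, allele_ref, allele_alt, af_alt,
                         beta, se, p_value, n, n_cases, mac_total, mac_cases,
                         mac_controls, method, info_score = 1, converged = TRUE) {
  data.frame(variant_id = variant_id, cohort_id = cohort_id,
             allele_ref = allele_ref, allele_alt = allele_alt,
             af_alt = af_alt, beta = beta, se = se, p_value = p_value,
             n = as.integer(n), n_cases = as.integer(n_cases),
             mac_total = as.integer(mac_total), mac_cases = as.integer(mac_cases),
             mac_controls = as.integer(mac_controls), method = method,
             info_score = info_score, converged = converged,
             stringsAsFactors = FALSE)
}

#' Generate paired ICD-10 code sets with target Jaccard overlap
#'
#' For each phenotype, constructs one code set per cohort such that the
#' realized Jaccard index is within 0.05 of the requested target (exactly
#' when an integer intersection/union pair achieves it).
#'
#' @param n_phenotypes Number of phenotypes.
#' @param code_universe_size Size of the ICD-10 code universe to draw from.
#' @param jaccard_targets Vector of targets in `[0, 1]`, recycled across
#'   phenotypes.
#' @param seed Integer seed.
#' @param max_set_size Largest union size considered per pair.
#' @return A `data.frame` of class `icd_pairs` with columns `phenotype_id`,
#'   `name`, `jaccard_target`, `jaccard`, and list columns
#'   `codes_cohort1`, `codes_cohort2`.
#' @export
generate_icd_pairs <- function(n_phenotypes, code_universe_size,
                               jaccard_targets, seed = 1L, max_set_size = 12L) {
  stopifnot(n_phenotypes >= 1, code_universe_size >= 2)
  if (any(jaccard_targets < 0 | jaccard_targets > 1))
    stop("jaccard targets must lie in [0, 1]", call. = FALSE)
  targets <- rep_len(jaccard_targets, n_phenotypes)
  universe <- sprintf("%s%02d.%d",
                      rep(LETTERS, length.out = code_universe_size),
                      (seq_len(code_universe_size) - 1L) %/% 10 %% 100,
                      (seq_len(code_universe_size) - 1L) %% 10)
  universe <- make.unique(universe)

  # Best integer (intersection i, union u) pair for a target Jaccard.
  best_pair <- function(t, u_max) {
    best <- c(err = Inf, i = NA, u = NA)
    for (u in 2:u_max) {
      i <- round(t * u)
      if (t > 0 && i == 0) i <- 1L
      if (t < 1 && i == u) i <- u - 1L
      if (i < u && i >= 1 && u - i > max(0, 2 - i) * 0) {
        # both sets non-empty: need i + extras per side >= 1, always true if i>=1
      }
      if (i < 0 || i > u) next
      err <- abs(i / u - t)
      if (err < best["err"]) best <- c(err = err, i = i, u = u)
    }
    best
  }

  with_seed(seed, {
    rows <- vector("list", n_phenotypes)
    for (k in seq_len(n_phenotypes)) {
      t <- targets[k]
      if (t == 1) {
        u <- min(4L, code_universe_size); i <- u
      } else if (t == 0) {
        u <- min(6L, code_universe_size); i <- 0L
        if (u < 2) stop("code universe too small for disjoint sets", call. = FALSE)
      } else {
        bp <- best_pair(t, min(max_set_size, code_universe_size))
        if (!is.finite(bp["err"]) || bp["err"] > 0.05)
          stop(sprintf("jaccard target %.3f unreachable within 0.05 for universe size %d",
                       t, code_universe_size), call. = FALSE)
        i <- as.integer(bp["i"]); u <- as.integer(bp["u"])
      }
      codes <- sample(universe, u)
      shared <- if (i > 0) codes[seq_len(i)] else character(0)
      rest <- if (u > i) codes[(i + 1L):u] else character(0)
      if (t == 0) {
        half <- ceiling(length(rest) / 2)
        set1 <- rest[seq_len(half)]; set2 <- rest[-seq_len(half)]
      } else {
        n1 <- ceiling(length(rest) / 2)
        set1 <- c(shared, rest[seq_len(n1)])
        set2 <- c(shared, if (length(rest) > n1) rest[(n1 + 1L):length(rest)] else character(0))
      }
      realized <- jaccard_similarity(set1, set2)
      rows[[k]] <- data.frame(phenotype_id = sprintf("PHENO%03d", k),
                              name = sprintf("synthetic phenotype %03d", k),
                              jaccard_target = t, jaccard = realized,
                              stringsAsFactors = FALSE)
      rows[[k]]$codes_cohort1 <- I(list(set1))
      rows[[k]]$codes_cohort2 <- I(list(set2))
    }
    out <- do.call(rbind, rows)
    class(out) <- c("icd_pairs", "data.frame")
    out
  })
}
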