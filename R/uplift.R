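# Power model for cohort-specific allele enrichment: the theoretical
# inverse-variance-weighted meta-analysis Z-score uplift, its simulation
# validation over a MAF x enrichment grid, and the median absolute relative
# error (MARE) between the two.

#' Default two-cohort configuration for uplift calculations
#'
#' Reference cohort of 392,814 (sequencing-scale biobank) and enriched
#' cohort of 260,405 (founder-population biobank), disease prevalence 0.05
#' in both. The `scale` factor shrinks both sample sizes for desk runs.
#'
#' @param n_ref,n_enriched Cohort sample sizes.
#' @param prevalence_ref,prevalence_enriched Disease prevalences.
#' @param scale Multiplier applied to both sample sizes.
#' @return A list with the four cohort parameters.
#' @export
uplift_cohorts <- function(n_ref = 392814, n_enriched = 260405,
                           prevalence_ref = 0.05, prevalence_enriched = 0.05,
                           scale = 1) {
  stopifnot(scale > 0)
  list(n_ref = n_ref * scale, n_enriched = n_enriched * scale,
       prevalence_ref = prevalence_ref, prevalence_enriched = prevalence_enriched)
}

# Score-test information for a biallelic additive variant.
score_information <- function(n, p, phi) 2 * n * p * (1 - p) * phi * (1 - phi)

#' Expected association Z-score (first-order theory)
#'
#' Under the small-effect score-test approximation, the expected Z is
#' `beta * sqrt(v)` with `v = 2 n p (1-p) phi (1-phi)`.
#'
#' @param beta Per-allele log odds ratio.
#' @param maf Allele frequency p in (0, 1).
#' @param n Sample size.
#' @param prevalence Disease prevalence phi in (0, 1).
#' @return Expected Z-score.
#' @export
expected_z <- function(beta, maf, n, prevalence) {
  if (!is_scalar_number(maf) || maf <= 0 || maf >= 1)
    stop("`maf` must lie strictly in (0, 1)", call. = FALSE)
  stop_if_not_fraction(prevalence, "prevalence")
  beta * sqrt(score_information(n, maf, prevalence))
}

#' Theoretical IVW uplift from cohort-specific allele enrichment
#'
#' The uplift is the ratio of the inverse-variance-weighted meta-analysis
#' Z-score to the reference study's Z-score. Under the first-order score
#' model it is `U = sqrt(1 + v2/v1)` with
#' `v_i = 2 N_i p_i (1-p_i) phi_i (1-phi_i)` and `p2 = e * p1`; it does not
#' depend on the effect size.
#'
#' @param maf_ref Reference-cohort allele frequency p1.
#' @param enrichment Allele enrichment e in the second cohort (`p2 = e*p1`,
#'   must satisfy `e*p1 < 1`).
#' @param cohorts An [uplift_cohorts()] configuration.
#' @return Theoretical uplift (>= 1 whenever both cohorts contribute).
#' @export
theoretical_uplift <- function(maf_ref, enrichment, cohorts = uplift_cohorts()) {
  stopifnot(maf_ref > 0, enrichment > 0)
  p2 <- enrichment * maf_ref
  if (p2 >= 1) stop("enrichment x maf >= 1: impossible allele frequency", call. = FALSE)
  if (cohorts$n_enriched == 0) return(1)
  v1 <- score_information(cohorts$n_ref, maf_ref, cohorts$prevalence_ref)
  v2 <- score_information(cohorts$n_enriched, p2, cohorts$prevalence_enriched)
  sqrt(1 + v2 / v1)
}

#' Simulate the IVW uplift for one MAF x enrichment cell
#'
#' Per replicate, an effect size is drawn from the sampler, both cohorts'
#' summary statistics are simulated, the fixed-effect IVW combination is
#' formed, and the ratio `Z_meta / Z_ref` recorded. The cell estimate is
#' the median ratio (configurable to the mean). Replicates with a
#' near-zero reference Z (|Z| < 0.1) are resampled, capped at ten times the
#' requested replicate count, because the ratio estimator is heavy-tailed.
#'
#' @inheritParams theoretical_uplift
#' @param effect_sampler An [effect_sampler()].
#' @param n_reps Number of replicates (default 1000).
#' @param engine `"summary"` draws from the asymptotic sampling
#'   distribution; `"individual"` simulates HWE genotypes and case status
#'   and runs the logistic score test (use with scaled-down cohorts).
#' @param seed Integer seed.
#' @param aggregate `"median"` (default) or `"mean"` over replicates.
#' @return A list of class `uplift_cell` with `uplift_theory`,
#'   `uplift_sim`, the cell parameters, `n_reps` and `seed`.
#' @export
simulate_uplift_cell <- function(maf_ref, enrichment,
                                 cohorts = uplift_cohorts(),
                                 effect_sampler = cwasmeta::effect_sampler(),
                                 n_reps = 1000L,
                                 engine = c("summary", "individual"),
                                 seed = 1L,
                                 aggregate = c("median", "mean")) {
  engine <- match.arg(engine)
  aggregate <- match.arg(aggregate)
  stopifnot(n_reps >= 1)
  u_theory <- theoretical_uplift(maf_ref, enrichment, cohorts)
  p1 <- maf_ref
  p2 <- enrichment * maf_ref
  ratios <- numeric(n_reps)
  with_seed(seed, {
    got <- 0L
    draws <- 0L
    max_draws <- 10L * n_reps
    while (got < n_reps && draws < max_draws) {
      draws <- draws + 1L
      b <- draw_effects(effect_sampler, 1L)
      zs <- simulate_two_cohort_stats(b, p1, p2, cohorts, engine)
      if (abs(zs$z_ref) < 0.1) next
      w1 <- 1 / zs$se_ref^2
      w2 <- 1 / zs$se_enr^2
      beta_meta <- (w1 * zs$beta_ref + w2 * zs$beta_enr) / (w1 + w2)
      z_meta <- beta_meta * sqrt(w1 + w2)
      got <- got + 1L
      ratios[got] <- z_meta / zs$z_ref
    }
    if (got < n_reps)
      stop(sprintf(paste0("uplift cell unstable: only %d/%d usable replicates after %d draws ",
                          "(maf_ref=%g, enrichment=%g)"), got, n_reps, draws, maf_ref, enrichment),
           call. = FALSE)
    u_sim <- if (aggregate == "median") stats::median(ratios) else mean(ratios)
    structure(list(maf_ref = maf_ref, enrichment = enrichment,
                   cohorts = cohorts, uplift_theory = u_theory,
                   uplift_sim = u_sim, n_reps = as.integer(n_reps),
                   seed = as.integer(seed), engine = engine),
              class = "uplift_cell")
  })
}

# One replicate of both cohorts' association statistics for a single
# variant with effect `b`, via the summary-level sampling distribution or
# an individual-level HWE/logistic simulation.
simulate_two_cohort_stats <- function(b, p1, p2, cohorts, engine) {
  if (engine == "summary") {
    v1 <- score_information(cohorts$n_ref, p1, cohorts$prevalence_ref)
    v2 <- score_information(cohorts$n_enriched, p2, cohorts$prevalence_enriched)
    se1 <- 1 / sqrt(v1); se2 <- 1 / sqrt(v2)
    b1 <- stats::rnorm(1, b, se1); b2 <- stats::rnorm(1, b, se2)
    list(beta_ref = b1, se_ref = se1, z_ref = b1 / se1,
         beta_enr = b2, se_enr = se2, z_enr = b2 / se2)
  } else {
    s1 <- simulate_one_variant_study(b, p1, round(cohorts$n_ref), cohorts$prevalence_ref)
    s2 <- simulate_one_variant_study(b, p2, round(cohorts$n_enriched), cohorts$prevalence_enriched)
    list(beta_ref = s1$beta, se_ref = s1$se, z_ref = s1$beta / s1$se,
         beta_enr = s2$beta, se_enr = s2$se, z_enr = s2$beta / s2$se)
  }
}

simulate_one_variant_study <- function(b, p, n, phi) {
  repeat {
    d <- stats::rbinom(n, 2L, p)
    if (stats::var(d) > 0) break
  }
  alpha <- solve_prevalence_intercept(b * d, phi)
  y <- stats::rbinom(n, 1L, stats::plogis(alpha + b * d))
  if (length(unique(y)) < 2L) return(list(beta = 0, se = Inf))
  nf <- fit_null_logistic(y, NULL)
  sc <- score_components(nf, d)
  list(beta = sc[["U"]] / sc[["V"]], se = 1 / sqrt(sc[["V"]]))
}

#' Theoretical and simulated uplift over a MAF x enrichment grid
#'
#' Fills every grid cell with the theoretical uplift and a simulated
#' estimate, and summarizes agreement by the median absolute relative
#' error (MARE, in percent) over cells.
#'
#' @param maf_grid Reference-cohort MAF values (default five log-spaced
#'   points from 0.01% to 1%).
#' @param enrichment_grid Enrichment values (default 1 to 50).
#' @param cohorts An [uplift_cohorts()] configuration.
#' @param n_reps Replicates per cell.
#' @param seed Integer seed (each cell uses a derived child seed).
#' @param engine,aggregate Passed to [simulate_uplift_cell()].
#' @param effect_sampler An [effect_sampler()].
#' @return A long-format `data.frame` of class `uplift_grid` with columns
#'   `maf_ref`, `enrichment`, `uplift_theory`, `uplift_sim`, `n_reps`;
#'   attribute `mare_percent` holds the grid MARE.
#' @export
uplift_surface <- function(maf_grid = 10^seq(log10(1e-4), log10(1e-2), length.out = 5),
                           enrichment_grid = c(1, 2, 5, 10, 20, 50),
                           cohorts = uplift_cohorts(),
                           n_reps = 1000L, seed = 1L,
                           engine = "summary", aggregate = "median",
                           effect_sampler = cwasmeta::effect_sampler()) {
  stopifnot(length(maf_grid) >= 1, length(enrichment_grid) >= 1)
  grid <- expand.grid(maf_ref = maf_grid, enrichment = enrichment_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cells[[k]] <- simulate_uplift_cell(
      grid$maf_ref[k], grid$enrichment[k], cohorts = cohorts,
      effect_sampler = effect_sampler, n_reps = n_reps, engine = engine,
      seed = derive_seed(seed, paste0("cell", k)), aggregate = aggregate)
  }
  out <- data.frame(
    maf_ref = grid$maf_ref, enrichment = grid$enrichment,
    uplift_theory = vapply(cells, `[[`, numeric(1), "uplift_theory"),
    uplift_sim = vapply(cells, `[[`, numeric(1), "uplift_sim"),
    n_reps = n_reps)
  rel_err <- abs(out$uplift_sim - out$uplift_theory) / out$uplift_theory
  attr(out, "mare_percent") <- stats::median(rel_err) * 100
  class(out) <- c("uplift_grid", "data.frame")
  out
}

#' Median absolute relative error of an uplift grid
#'
#' @param grid An [uplift_surface()] result.
#' @return MARE in percent.
#' @export
mare_percent <- function(grid) {
  stopifnot(inherits(grid, "uplift_grid"))
  attr(grid, "mare_percent")
}

#' Plot an uplift surface
#'
#' Filled-contour rendering of the theoretical or simulated uplift over
#' the MAF x enrichment grid (MAF on a log axis).
#'
#' @param x An [uplift_surface()] result.
#' @param which `"theory"` or `"sim"`.
#' @param ... Passed to [graphics::filled.contour()].
#' @export
plot.uplift_grid <- function(x, which = c("theory", "sim"), ...) {
  which <- match.arg(which)
  mafs <- sort(unique(x$maf_ref))
  es <- sort(unique(x$enrichment))
  col <- if (which == "theory") "uplift_theory" else "uplift_sim"
  z <- matrix(NA_real_, length(mafs), length(es))
  for (i in seq_along(mafs)) for (j in seq_along(es))
    z[i, j] <- x[[col]][x$maf_ref == mafs[i] & x$enrichment == es[j]][1]
  graphics::filled.contour(log10(mafs), es, z,
                           xlab = "log10 reference MAF", ylab = "allele enrichment",
                           main = sprintf("IVW uplift (%s)", which), ...)
  invisible(x)
}
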