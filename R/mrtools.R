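# Two-sample Mendelian randomization ratio estimation and clustered MR:
# an EM mixture over per-variant ratio estimates with a null component, a
# flat junk component, singleton-friendly substantive components, and
# inclusion-probability-thresholded assignments.

#' Mendelian randomization ratio estimate for one variant
#'
#' The causal-effect ratio estimate is `beta_y / beta_x`, with leading-order
#' standard error `se(beta_y) / |beta_x|` (the exposure-side uncertainty is
#' carried for diagnostics but does not enter the leading-order formula).
#'
#' @param beta_x,se_x Variant-exposure association and its SE.
#' @param beta_y,se_y Variant-outcome association and its SE.
#' @param variant_id Label.
#' @return One-row `data.frame` with `ratio` and `ratio_se`.
#' @export
ratio_estimate <- function(beta_x, se_x, beta_y, se_y, variant_id = "v1") {
  if (beta_x == 0) stop("weak instrument: beta_x = 0", call. = FALSE)
  stopifnot(se_y > 0)
  data.frame(variant_id = variant_id, beta_x = beta_x, se_x = se_x,
             beta_y = beta_y, se_y = se_y,
             ratio = beta_y / beta_x, ratio_se = se_y / abs(beta_x),
             stringsAsFactors = FALSE)
}

# Expected complete-data log-likelihood helpers -------------------------------

# Component densities. A substantive cluster is a set of variants sharing
# one causal ratio, so its density uses the per-variant known variances
# only: x_i ~ Normal(mu_k, s_i^2). The null is Normal(0, s_i^2); junk is
# flat over the observed ratio range. Keeping the cluster variance at the
# observation level (no free spread parameter) is what prevents a diffuse
# pseudo-cluster from soaking up scattered null ratios.
mixture_density_matrix <- function(x, s2, means, junk_height,
                                   include_null, include_junk) {
  k <- length(means)
  dens <- matrix(0, length(x), k + include_null + include_junk)
  for (j in seq_len(k))
    dens[, j] <- stats::dnorm(x, means[j], sqrt(s2))
  col <- k
  if (include_null) {
    col <- col + 1L
    dens[, col] <- stats::dnorm(x, 0, sqrt(s2))
  }
  if (include_junk) {
    col <- col + 1L
    dens[, col] <- junk_height
  }
  dens
}

fit_mixture_em <- function(x, s2, k, junk_height, include_null, include_junk,
                           max_iter = 500L, tol = 1e-8, seed = 1L) {
  n <- length(x)
  n_comp <- k + include_null + include_junk
  if (n_comp == 0L) stop("mixture needs at least one component", call. = FALSE)
  # k-means initialization on the ratios, 10 restarts (k = 0 fits the
  # null/junk-only model, the reference for "no substantive mechanism").
  means <- if (k == 0L) numeric(0) else with_seed(seed, {
    if (k == 1L) mean(x)
    else if (length(unique(x)) <= k) {
      ux <- unique(x)
      c(ux, rep(mean(x), max(0, k - length(ux))))[seq_len(k)]
    } else stats::kmeans(x, centers = k, nstart = 10L)$centers[, 1L]
  })
  wts <- rep(1 / n_comp, n_comp)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    dens <- mixture_density_matrix(x, s2, means, junk_height,
                                   include_null, include_junk)
    num <- sweep(dens, 2L, wts, `*`)
    rowsum_ <- rowSums(num)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    resp <- num / rowsum_
    ll <- sum(log(rowsum_))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-9)
      warning("EM log-likelihood decreased beyond tolerance", call. = FALSE)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    wts <- colMeans(resp)
    wts[wts < 1e-12] <- 1e-12
    wts <- wts / sum(wts)
    # Exact M-step: each cluster mean is the responsibility-weighted
    # inverse-variance mean of the ratios.
    for (j in seq_len(k)) {
      w <- resp[, j] / s2
      means[j] <- sum(w * x) / sum(w)
    }
  }
  dens <- mixture_density_matrix(x, s2, means, junk_height,
                                 include_null, include_junk)
  num <- sweep(dens, 2L, wts, `*`)
  rowsum_ <- rowSums(num)
  rowsum_[rowsum_ == 0] <- .Machine$double.xmin
  resp <- num / rowsum_
  ll <- sum(log(rowsum_))
  list(means = means, vars = rep(0, k), weights = wts, responsibilities = resp,
       log_likelihood = ll, ll_trace = c(ll_trace, ll), converged = converged,
       k = k, include_null = include_null, include_junk = include_junk)
}

#' Clustered Mendelian randomization by EM mixture
#'
#' Fits a Gaussian mixture to per-variant ratio estimates with known
#' per-variant variances (`ratio_se^2`; a cluster is a set of variants
#' sharing one causal ratio, so clusters carry no free spread parameter),
#' alongside a null component fixed at zero and a flat "junk" component
#' spanning the observed ratio range.
#' The number of substantive components is chosen by BIC over `0..max_k`
#' (zero substantive clusters — null and junk only — is a valid outcome,
#' and is what permuted or signal-free data should select).
#' Variants are assigned to the component with maximum responsibility only
#' when that inclusion probability exceeds 0.7; singleton clusters are
#' allowed by default, accommodating rare variants with large but
#' genuine ratio estimates.
#'
#' @param estimates `data.frame` from [ratio_estimate()] rows (needs
#'   `variant_id`, `ratio`, `ratio_se`).
#' @param max_k Maximum number of substantive clusters (default 3).
#' @param allow_singletons Allow one-variant substantive clusters
#'   (default TRUE). When FALSE, components owning fewer than two assigned
#'   variants are pruned and the model refitted.
#' @param include_null,include_junk Include the null / junk components.
#' @param inclusion_threshold Responsibility required for assignment
#'   (default 0.7).
#' @param seed Integer seed for the k-means initialization.
#' @param max_iter EM iteration cap (default 500).
#' @return A list of class `mr_clust_model`: `k_substantive`,
#'   `cluster_means`, `cluster_variances`, `cluster_weights`,
#'   `responsibilities`, `assignments` (`data.frame` with `variant_id`,
#'   `component`, `inclusion_prob`, `assigned`), `log_likelihood`,
#'   `ll_trace`, `bic`.
#' @export
mr_clust_em <- function(estimates, max_k = 3L, allow_singletons = TRUE,
                        include_null = TRUE, include_junk = TRUE,
                        inclusion_threshold = 0.7, seed = 1L, max_iter = 500L) {
  stopifnot(all(c("variant_id", "ratio", "ratio_se") %in% names(estimates)))
  x <- estimates$ratio
  s <- estimates$ratio_se
  if (length(x) < 2L) stop("need at least two variant estimates", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(s)))
    stop("ratio estimates must be finite", call. = FALSE)
  s2 <- pmax(s^2, 1e-10)
  junk_range <- c(min(x) - 3 * max(s), max(x) + 3 * max(s))
  junk_height <- 1 / diff(junk_range)

  # BIC over k = 0..max_k; k = 0 (null + junk only) lets permuted or
  # signal-free data select "no substantive mechanism".
  k_grid <- if (include_null || include_junk) 0:max_k else 1:max_k
  fits <- vector("list", length(k_grid))
  bics <- rep(NA_real_, length(k_grid))
  for (j in seq_along(k_grid)) {
    k <- k_grid[j]
    fit <- fit_mixture_em(x, s2, k, junk_height, include_null, include_junk,
                          max_iter = max_iter, seed = derive_seed(seed, k + 1L))
    n_par <- k + (k + include_null + include_junk - 1L)
    bics[j] <- -2 * fit$log_likelihood + n_par * log(length(x))
    fits[[j]] <- fit
  }
  best <- which.min(bics)
  fit <- fits[[best]]
  bics <- stats::setNames(bics, paste0("k", k_grid))

  build_model <- function(fit) {
    comp_names <- c(sprintf("cluster%d", seq_len(fit$k)),
                    if (fit$include_null) "null",
                    if (fit$include_junk) "junk")
    colnames(fit$responsibilities) <- comp_names
    best <- max.col(fit$responsibilities, ties.method = "first")
    prob <- fit$responsibilities[cbind(seq_along(x), best)]
    assignments <- data.frame(
      variant_id = estimates$variant_id,
      component = comp_names[best],
      inclusion_prob = prob,
      assigned = prob > inclusion_threshold,
      stringsAsFactors = FALSE)
    structure(list(estimates = estimates,
                   k_substantive = fit$k,
                   cluster_means = fit$means,
                   cluster_variances = fit$vars,
                   cluster_weights = fit$weights,
                   responsibilities = fit$responsibilities,
                   assignments = assignments,
                   log_likelihood = fit$log_likelihood,
                   ll_trace = fit$ll_trace,
                   bic = unname(bics[paste0("k", fit$k)]),
                   bic_trace = bics,
                   converged = fit$converged,
                   include_null = fit$include_null,
                   include_junk = fit$include_junk),
              class = "mr_clust_model")
  }
  model <- build_model(fit)
  if (!allow_singletons && model$k_substantive > 1L) {
    counts <- table(factor(model$assignments$component[model$assignments$assigned],
                           levels = sprintf("cluster%d", seq_len(model$k_substantive))))
    keep <- sum(counts >= 2L)
    if (keep < model$k_substantive && keep >= 1L) {
      fit <- fit_mixture_em(x, s2, keep, junk_height, include_null, include_junk,
                            max_iter = max_iter, seed = derive_seed(seed, keep + 100L))
      model <- build_model(fit)
    }
  }
  if (!model$converged)
    warning("EM did not converge within the iteration cap; returning best-so-far fit",
            call. = FALSE)
  model
}

#' Permutation null for clustered MR
#'
#' Permutes the outcome associations (`beta_y`, `se_y` pairs) across
#' variants, recomputes the ratio estimates, and refits the cluster model.
#' Used as the empirical null for substantive-cluster discovery.
#'
#' @param estimates As in [mr_clust_em()], with `beta_x`, `beta_y`, `se_y`.
#' @param seed Integer seed for the permutation.
#' @param ... Passed to [mr_clust_em()].
#' @return An `mr_clust_model` fitted to the permuted estimates; the
#'   permutation used is attached as attribute `permutation`.
#' @export
permute_outcome_null <- function(estimates, seed = 1L, ...) {
  stopifnot(nrow(estimates) >= 2L,
            all(c("beta_x", "beta_y", "se_y") %in% names(estimates)))
  perm <- with_seed(seed, sample.int(nrow(estimates)))
  est <- estimates
  est$beta_y <- estimates$beta_y[perm]
  est$se_y <- estimates$se_y[perm]
  est$ratio <- est$beta_y / est$beta_x
  est$ratio_se <- est$se_y / abs(est$beta_x)
  model <- mr_clust_em(est, seed = seed, ...)
  attr(model, "permutation") <- perm
  model
}

#' Count substantive clusters supported by assigned variants
#'
#' A substantive cluster counts as "discovered" when (a) at least
#' `min_size` variants are assigned to it at the inclusion threshold, and
#' (b) its mean is distinguishable from the null mechanism: the cluster
#' mean exceeds `z_null` of its inverse-variance standard errors. The
#' defaults mirror the reporting convention of published clustered-MR
#' analyses, where small chance groupings are not reported as mechanisms.
#'
#' @param model An `mr_clust_model`.
#' @param min_size Minimum assigned variants (default 4).
#' @param z_null Required |mean| / se(mean) distance from zero (default 3).
#' @return Integer count.
#' @export
n_substantive_clusters <- function(model, min_size = 4L, z_null = 3) {
  a <- model$assignments
  sub <- a$assigned & grepl("^cluster", a$component)
  if (!any(sub)) return(0L)
  count <- 0L
  for (comp in unique(a$component[sub])) {
    members <- which(a$component == comp & a$assigned)
    if (length(members) < min_size) next
    k <- as.integer(sub("cluster", "", comp))
    s2 <- pmax(model$estimates$ratio_se[members]^2, 1e-10)
    se_mean <- 1 / sqrt(sum(1 / s2))
    if (abs(model$cluster_means[k]) > z_null * se_mean) count <- count + 1L
  }
  count
}
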