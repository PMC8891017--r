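# Per-cohort association testing: logistic score test with Firth fallback,
# inclusion filters on case counts / minor allele counts / INFO, and a
# quantitative-trait scan for biomarkers.

#' Inclusion filter configuration
#'
#' @param min_cases Phenotypes must have strictly more cases than this
#'   (default 100).
#' @param min_mac_total Minimum minor allele count over all samples
#'   (default 5, inclusive).
#' @param min_mac_stratum Minimum minor allele count in cases and in
#'   controls (default 3, inclusive).
#' @param min_info Minimum imputation INFO score (default 0.6, strict).
#' @param firth_trigger_p Score-test p-value below which the Firth fallback
#'   is invoked (default 0.01).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_cases = 100L, min_mac_total = 5L,
                          min_mac_stratum = 3L, min_info = 0.6,
                          firth_trigger_p = 0.01) {
  stopifnot(min_cases >= 0, min_mac_total >= 0, min_mac_stratum >= 0,
            min_info >= 0, firth_trigger_p > 0)
  structure(list(min_cases = min_cases, min_mac_total = min_mac_total,
                 min_mac_stratum = min_mac_stratum, min_info = min_info,
                 firth_trigger_p = firth_trigger_p),
            class = "filter_config")
}

#' Apply variant/phenotype inclusion filters
#'
#' A variant-phenotype pair is tested only if the phenotype has more than
#' `min_cases` cases (strict), the variant's total minor allele count is at
#' least `min_mac_total`, its minor allele count is at least
#' `min_mac_stratum` in both cases and controls, and its INFO score exceeds
#' `min_info`. The reason code names the first failing rule, in that order.
#'
#' @param n_cases Phenotype case count.
#' @param mac_total,mac_cases,mac_controls Minor allele counts.
#' @param info INFO score of the variant (default 1).
#' @param cfg A [filter_config()].
#' @return A list with `include` (logical) and `reason` (`"pass"`,
#'   `"case_count"`, `"total_mac"`, `"stratum_mac"`, or `"info"`).
#' @export
apply_inclusion_filters <- function(n_cases, mac_total, mac_cases,
                                    mac_controls, info = 1,
                                    cfg = filter_config()) {
  stopifnot(n_cases >= 0, mac_total >= 0, mac_cases >= 0, mac_controls >= 0)
  if (!(n_cases > cfg$min_cases)) return(list(include = FALSE, reason = "case_count"))
  if (!(mac_total >= cfg$min_mac_total)) return(list(include = FALSE, reason = "total_mac"))
  if (!(min(mac_cases, mac_controls) >= cfg$min_mac_stratum))
    return(list(include = FALSE, reason = "stratum_mac"))
  if (!(info > cfg$min_info)) return(list(include = FALSE, reason = "info"))
  list(include = TRUE, reason = "pass")
}

# Fit the null logistic model phenotype ~ covariates and cache the pieces
# needed for per-variant score tests.
fit_null_logistic <- function(phenotype, covariates = NULL) {
  y <- phenotype
  if (length(unique(y)) < 2L) stop("phenotype must contain both classes", call. = FALSE)
  X0 <- if (is.null(covariates)) matrix(1, length(y), 1L)
        else cbind(1, as.matrix(covariates))
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) stop("covariate matrix is rank deficient", call. = FALSE)
  fit <- stats::glm.fit(X0, y, family = stats::binomial())
  if (!fit$converged) stop("null logistic model failed to converge", call. = FALSE)
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  XtWX_inv <- chol2inv(chol(crossprod(X0, X0 * w)))
  list(y = y, X0 = X0, mu = mu, w = w, XtWX_inv = XtWX_inv)
}

# Efficient score and its variance for one dosage vector given a null fit.
score_components <- function(null_fit, dosage) {
  d <- dosage
  U <- sum(d * (null_fit$y - null_fit$mu))
  xw <- crossprod(null_fit$X0, d * null_fit$w)
  V <- sum(null_fit$w * d^2) - drop(t(xw) %*% null_fit$XtWX_inv %*% xw)
  c(U = U, V = V)
}

#' Logistic score test for one variant
#'
#' Tests the dosage term in a covariate-adjusted logistic model using the
#' efficient score statistic from the null model (fitted without the
#' dosage). The reported effect size is the one-step estimate `U/V` with
#' `se = 1/sqrt(V)`, so `beta/se` reproduces the score Z exactly and the
#' two-sided p-value comes from chi-square(1).
#'
#' @param dosage Numeric dosage vector (0/1/2 or imputed fractions).
#' @param phenotype Binary 0/1 vector with both classes present.
#' @param covariates Optional numeric covariate matrix (full rank).
#' @param variant_id,cohort_id,allele_ref,allele_alt Labels for the record.
#' @param null_fit Optional precomputed result of the internal null fit,
#'   reused when scanning many variants against one phenotype.
#' @return One-row summary-statistic `data.frame` with `method = "score"`.
#' @export
fit_logistic_score <- function(dosage, phenotype, covariates = NULL,
                               variant_id = "v1", cohort_id = "cohort1",
                               allele_ref = "A", allele_alt = "C",
                               null_fit = NULL) {
  if (stats::var(dosage) == 0) stop("no variation in dosage", call. = FALSE)
  if (is.null(null_fit)) null_fit <- fit_null_logistic(phenotype, covariates)
  sc <- score_components(null_fit, dosage)
  if (sc[["V"]] <= 0) stop("non-positive score variance", call. = FALSE)
  beta <- sc[["U"]] / sc[["V"]]
  se <- 1 / sqrt(sc[["V"]])
  chi <- sc[["U"]]^2 / sc[["V"]]
  p <- stats::pchisq(chi, df = 1L, lower.tail = FALSE)
  y <- null_fit$y
  ac <- sum(dosage)
  af <- ac / (2 * length(dosage))
  mac <- round(min(ac, 2 * length(dosage) - ac))
  mac_cases <- round(sum(dosage[y == 1]))
  if (af > 0.5) mac_cases <- round(sum(2 - dosage[y == 1]))
  mac_controls <- mac - mac_cases
  summary_stat(variant_id = variant_id, cohort_id = cohort_id,
               allele_ref = allele_ref, allele_alt = allele_alt,
               af_alt = af, beta = beta, se = se, p_value = p,
               n = length(y), n_cases = sum(y == 1), mac_total = mac,
               mac_cases = mac_cases, mac_controls = max(mac_controls, 0),
               method = "score")
}

# Penalized (Jeffreys-prior) logistic log-likelihood; the penalty is
# always the full design's information determinant so that constrained
# (profile) fits are comparable with the unconstrained fit in a penalized
# likelihood-ratio test.
firth_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  ll <- sum(y * eta - log1p(exp(eta)))
  ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
}

# Firth-penalized logistic fit by modified-score Newton-Raphson.
# Coefficients listed in `fixed` are constrained to zero while the Jeffreys
# penalty (and the hat diagonal in the modified score) is still that of the
# full design: the profile fit used by the penalized LRT.
firth_fit <- function(X, y, fixed = integer(0), max_iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), fixed)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    XtWX_inv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(XtWX_inv)) break
    # Hat-matrix diagonal of the weighted full design.
    h <- rowSums((X %*% XtWX_inv) * X) * w
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- rep(0, p)
    step[free] <- solve(XtWX[free, free, drop = FALSE], U[free])
    # Step-halving keeps the penalized likelihood finite and increasing.
    ll_old <- firth_loglik(X, y, beta)
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      if (firth_loglik(X, y, beta_new) >= ll_old - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta_new
    if (sqrt(sum(U[free]^2)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  XtWX <- crossprod(X, X * (mu * (1 - mu)))
  list(beta = beta, loglik = firth_loglik(X, y, beta),
       vcov = tryCatch(chol2inv(chol(XtWX)), error = function(e) matrix(NA, p, p)),
       converged = converged)
}

#' Firth penalized logistic regression for one variant
#'
#' Maximizes the Jeffreys-penalized logistic likelihood (finite estimates
#' under complete separation), tests the dosage term by penalized
#' likelihood ratio, and recomputes the standard error from the effect size
#' and the likelihood-ratio p-value: `se = |beta| / z(p_LRT)`, the
#' convention used when combining Firth results by inverse-variance
#' weighting.
#'
#' @inheritParams fit_logistic_score
#' @return One-row summary-statistic `data.frame` with `method = "firth"`;
#'   `converged` is `FALSE` if the iteration cap was reached.
#' @export
fit_firth <- function(dosage, phenotype, covariates = NULL,
                      variant_id = "v1", cohort_id = "cohort1",
                      allele_ref = "A", allele_alt = "C") {
  if (stats::var(dosage) == 0) stop("no variation in dosage", call. = FALSE)
  y <- phenotype
  if (length(unique(y)) < 2L) stop("phenotype must contain both classes", call. = FALSE)
  X0 <- if (is.null(covariates)) matrix(1, length(y), 1L)
        else cbind(1, as.matrix(covariates))
  X1 <- cbind(X0, dosage = dosage)
  full <- firth_fit(X1, y)
  null <- firth_fit(X1, y, fixed = ncol(X1))
  beta <- full$beta[[ncol(X1)]]
  lrt <- 2 * (full$loglik - null$loglik)
  lrt <- max(lrt, 0)
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  se <- if (is.finite(z) && z > 0) abs(beta) / z else sqrt(full$vcov[ncol(X1), ncol(X1)])
  ac <- sum(dosage)
  af <- ac / (2 * length(dosage))
  mac <- round(min(ac, 2 * length(dosage) - ac))
  mac_cases <- round(sum(if (af > 0.5) 2 - dosage[y == 1] else dosage[y == 1]))
  summary_stat(variant_id = variant_id, cohort_id = cohort_id,
               allele_ref = allele_ref, allele_alt = allele_alt,
               af_alt = af, beta = beta, se = se, p_value = p,
               n = length(y), n_cases = sum(y == 1), mac_total = mac,
               mac_cases = mac_cases, mac_controls = max(mac - mac_cases, 0),
               method = "firth", converged = full$converged && null$converged)
}

#' Association scan over a cohort
#'
#' Runs the inclusion filters and the score test for every panel variant in
#' a cohort, switching to the Firth fallback whenever the score p-value
#' falls below `cfg$firth_trigger_p`. Filtered and non-convergent variants
#' are reported in the attached `filter_log` attribute rather than dropped
#' silently.
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg A [filter_config()].
#' @param panel Optional panel supplying allele labels and INFO scores.
#' @return Summary-statistic `data.frame`, one row per variant that passed
#'   the filters; attribute `filter_log` is a data.frame of
#'   (variant_id, reason) for exclusions.
#' @export
assoc_scan <- function(cohort, cfg = filter_config(), panel = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  y <- cohort$phenotype
  nf <- fit_null_logistic(y, cohort$covariates)
  n_cases <- sum(y == 1)
  m <- ncol(cohort$dosage)
  rows <- vector("list", m)
  log_rows <- vector("list", m)
  info <- if (!is.null(panel)) panel$info_score else rep(1, m)
  a0 <- if (!is.null(panel)) panel$allele_ref else rep("A", m)
  a1 <- if (!is.null(panel)) panel$allele_alt else rep("C", m)
  for (j in seq_len(m)) {
    d <- cohort$dosage[, j]
    ac <- sum(d)
    mac <- min(ac, 2 * length(d) - ac)
    mac_cases <- sum(if (ac / (2 * length(d)) > 0.5) 2 - d[y == 1] else d[y == 1])
    flt <- apply_inclusion_filters(n_cases, mac, mac_cases, mac - mac_cases,
                                   info = info[j], cfg = cfg)
    vid <- cohort$variant_id[j]
    if (!flt$include) {
      log_rows[[j]] <- data.frame(variant_id = vid, reason = flt$reason,
                                  stringsAsFactors = FALSE)
      next
    }
    st <- fit_logistic_score(d, y, variant_id = vid,
                             cohort_id = cohort$cohort_id,
                             allele_ref = a0[j], allele_alt = a1[j],
                             null_fit = nf)
    if (st$p_value < cfg$firth_trigger_p) {
      st <- fit_firth(d, y, cohort$covariates, variant_id = vid,
                      cohort_id = cohort$cohort_id,
                      allele_ref = a0[j], allele_alt = a1[j])
      if (!st$converged) {
        log_rows[[j]] <- data.frame(variant_id = vid, reason = "non_convergence",
                                    stringsAsFactors = FALSE)
        next
      }
    }
    st$info_score <- info[j]
    rows[[j]] <- st
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- summary_stat(character(0), character(0), character(0),
                                        character(0), numeric(0), numeric(0),
                                        numeric(0), numeric(0), integer(0),
                                        integer(0), integer(0), integer(0),
                                        integer(0), character(0))
  attr(out, "filter_log") <-
    do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))]) %||%
    data.frame(variant_id = character(0), reason = character(0))
  out
}

#' Quantitative biomarker scan across sentinel variants
#'
#' Ordinary least squares of a biomarker on each dosage column with
#' covariates partialled out (Frisch-Waugh residualization), flagging
#' associations at the multiple-testing-adjusted threshold.
#'
#' @param biomarker Numeric response vector (finite; optionally
#'   inverse-normal transformed via `inverse_normal = TRUE`).
#' @param dosages Numeric matrix, individuals x variants.
#' @param covariates Optional covariate matrix.
#' @param alpha Significance threshold (default 1e-6).
#' @param inverse_normal Apply a rank-based inverse normal transform first.
#' @return `data.frame` with `variant_id`, `beta`, `se`, `p_value`,
#'   `significant`, `method = "linear"`.
#' @export
scan_quantitative <- function(biomarker, dosages, covariates = NULL,
                              alpha = 1e-6, inverse_normal = FALSE) {
  y <- biomarker
  if (any(!is.finite(y))) stop("biomarker must be finite", call. = FALSE)
  if (stats::var(y) == 0) stop("biomarker is constant", call. = FALSE)
  if (inverse_normal)
    y <- stats::qnorm((rank(y) - 0.5) / length(y))
  D <- as.matrix(dosages)
  n <- length(y)
  X0 <- if (is.null(covariates)) matrix(1, n, 1L) else cbind(1, as.matrix(covariates))
  q <- qr(X0)
  ry <- qr.resid(q, y)
  rD <- qr.resid(q, D)
  sxx <- colSums(rD^2)
  if (any(sxx == 0)) stop("monomorphic dosage column after residualization", call. = FALSE)
  beta <- colSums(rD * ry) / sxx
  df <- n - ncol(X0) - 1L
  rss_j <- sum(ry^2) - beta^2 * sxx
  se <- sqrt(rss_j / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  data.frame(variant_id = colnames(D) %||% sprintf("var%05d", seq_len(ncol(D))),
             beta = beta, se = se, p_value = p,
             significant = p < alpha, method = "linear",
             stringsAsFactors = FALSE, row.names = NULL)
}
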