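# Allele harmonization across cohorts and fixed-effect inverse-variance
# meta-analysis, with genomic-control diagnostics.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  vapply(strsplit(a, ""), function(ch) {
    paste(rev(unname(DNA_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

is_strand_ambiguous <- function(a0, a1) {
  (a0 %in% names(DNA_COMPLEMENT)) & (a1 %in% names(DNA_COMPLEMENT)) &
    unname(DNA_COMPLEMENT[a0] == a1)
}

#' Harmonize alleles between two cohorts' records for one variant
#'
#' Aligns cohort B's record to cohort A's allele orientation. Records with
#' identical alleles pass through; swapped reference/alternate alleles flip
#' B's effect sign and allele frequency; unambiguous strand-complement
#' matches are relabelled (with a swap flip when needed). Strand-ambiguous
#' (A/T, G/C) variants and irreconcilable allele sets are dropped with a
#' reason code.
#'
#' @param stat_a,stat_b One-row summary-statistic data.frames for the same
#'   variant position.
#' @return A list with `status` (`"ok"`, `"flipped"`, `"strand"`,
#'   `"strand_flipped"`, or `"dropped"`), `reason` (for drops), and the
#'   aligned `stat_a`, `stat_b` (NULL when dropped).
#' @export
harmonize_alleles <- function(stat_a, stat_b) {
  a0 <- stat_a$allele_ref; a1 <- stat_a$allele_alt
  b0 <- stat_b$allele_ref; b1 <- stat_b$allele_alt
  if (is_strand_ambiguous(a0, a1) || is_strand_ambiguous(b0, b1))
    return(list(status = "dropped", reason = "strand_ambiguous",
                stat_a = NULL, stat_b = NULL))
  flip_b <- function(b) {
    tmp <- b$allele_ref; b$allele_ref <- b$allele_alt; b$allele_alt <- tmp
    b$beta <- -b$beta
    b$af_alt <- 1 - b$af_alt
    b
  }
  if (identical(c(a0, a1), c(b0, b1)))
    return(list(status = "ok", reason = NA_character_, stat_a = stat_a, stat_b = stat_b))
  if (identical(c(a0, a1), c(b1, b0)))
    return(list(status = "flipped", reason = NA_character_,
                stat_a = stat_a, stat_b = flip_b(stat_b)))
  cb0 <- complement_allele(b0); cb1 <- complement_allele(b1)
  if (identical(c(a0, a1), c(cb0, cb1))) {
    stat_b$allele_ref <- a0; stat_b$allele_alt <- a1
    return(list(status = "strand", reason = NA_character_,
                stat_a = stat_a, stat_b = stat_b))
  }
  if (identical(c(a0, a1), c(cb1, cb0))) {
    stat_b$allele_ref <- b1; stat_b$allele_alt <- b0
    out <- flip_b(stat_b)
    out$allele_ref <- a0; out$allele_alt <- a1
    return(list(status = "strand_flipped", reason = NA_character_,
                stat_a = stat_a, stat_b = out))
  }
  list(status = "dropped", reason = "allele_mismatch", stat_a = NULL, stat_b = NULL)
}

#' Fixed-effect inverse-variance meta-analysis of one variant
#'
#' Combines aligned per-cohort estimates with weights `1/se^2`:
#' `se_meta = (sum se_i^-2)^-1/2`, `beta_meta = se_meta^2 sum beta_i/se_i^2`,
#' `z_meta = beta_meta/se_meta`, two-sided normal p-value. Cochran's Q is
#' computed as a heterogeneity diagnostic but never used for filtering.
#'
#' @param stats A summary-statistic `data.frame` with one row per cohort
#'   (already allele-aligned), or a list of one-row data.frames.
#' @return One-row `data.frame` (class `meta_record`) with `beta_meta`,
#'   `se_meta`, `z_meta`, `p_meta`, `directions`, per-cohort p-values in
#'   the `p_cohort` list column, `n_total`, `concordant`, `q_het`, `p_het`.
#' @export
ivw_meta <- function(stats) {
  if (is.list(stats) && !is.data.frame(stats)) stats <- do.call(rbind, stats)
  stopifnot(nrow(stats) >= 1L)
  if (any(stats$se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / stats$se^2
  se_meta <- 1 / sqrt(sum(w))
  beta_meta <- sum(w * stats$beta) / sum(w)
  z <- beta_meta / se_meta
  p <- 2 * stats::pnorm(-abs(z))
  q <- sum(w * (stats$beta - beta_meta)^2)
  p_het <- if (nrow(stats) > 1L) stats::pchisq(q, df = nrow(stats) - 1L, lower.tail = FALSE) else NA_real_
  out <- data.frame(
    variant_id = stats$variant_id[[1L]],
    beta_meta = beta_meta, se_meta = se_meta, z_meta = z, p_meta = p,
    directions = paste(ifelse(stats$beta >= 0, "+", "-"), collapse = ""),
    n_total = sum(stats$n),
    concordant = all(stats$beta >= 0) || all(stats$beta <= 0),
    q_het = q, p_het = p_het,
    stringsAsFactors = FALSE)
  out$p_cohort <- I(list(stats::setNames(stats$p_value, stats$cohort_id)))
  class(out) <- c("meta_record", "data.frame")
  out
}

#' Meta-analyse two cohorts' summary-statistic tables
#'
#' Matches variants by id across the two tables, harmonizes alleles
#' (dropping strand-ambiguous and irreconcilable records), and runs the
#' fixed-effect inverse-variance combination per variant. Variants present
#' in only one cohort are passed through as single-cohort records.
#'
#' @param stats_a,stats_b Per-cohort summary-statistic data.frames.
#' @param require_both Drop variants absent from either cohort instead of
#'   passing them through (default FALSE).
#' @return `data.frame` of meta records; attribute `harmonization_log`
#'   records dropped variants and reasons.
#' @export
meta_analyse <- function(stats_a, stats_b, require_both = FALSE) {
  ids <- union(stats_a$variant_id, stats_b$variant_id)
  rows <- vector("list", length(ids))
  log_rows <- list()
  ia <- match(ids, stats_a$variant_id)
  ib <- match(ids, stats_b$variant_id)
  for (k in seq_along(ids)) {
    ra <- if (!is.na(ia[k])) stats_a[ia[k], , drop = FALSE] else NULL
    rb <- if (!is.na(ib[k])) stats_b[ib[k], , drop = FALSE] else NULL
    if (!is.null(ra) && !is.null(rb)) {
      h <- harmonize_alleles(ra, rb)
      if (h$status == "dropped") {
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(variant_id = ids[k], reason = h$reason, stringsAsFactors = FALSE)
        next
      }
      rows[[k]] <- ivw_meta(rbind(h$stat_a, h$stat_b))
    } else if (!require_both) {
      rows[[k]] <- ivw_meta(if (is.null(ra)) rb else ra)
    } else {
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(variant_id = ids[k], reason = "single_cohort", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "harmonization_log") <-
    do.call(rbind, log_rows) %||% data.frame(variant_id = character(0),
                                             reason = character(0))
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median of the chi-square(1) quantiles of the observed
#' p-values divided by the null median 0.45494 (i.e. `qchisq(0.5, 1)`).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return A list of class `scan_summary` with `lambda_gc` and `n_tests`.
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chi <- stats::qchisq(p_values, df = 1L, lower.tail = FALSE)
  structure(list(lambda_gc = stats::median(chi) / stats::qchisq(0.5, df = 1L),
                 n_tests = length(p_values)),
            class = "scan_summary")
}
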