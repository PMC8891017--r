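# Significance tiering, LD clumping, region merging, sentinel selection,
# pleiotropy counting and allele-frequency fold-enrichment testing.

MHC_CHROM <- "6"
MHC_START <- 25500000L
MHC_END <- 34000000L

in_mhc <- function(chromosome, position) {
  gsub("^chr", "", as.character(chromosome)) == MHC_CHROM &
    position >= MHC_START & position <= MHC_END
}

#' Classify the significance tier of a meta-analysis record
#'
#' `conservative` requires meta p below the Bonferroni threshold (default
#' 2e-9), concordant effect direction across cohorts, and p < 0.05 in every
#' cohort; `genome_wide` requires meta p below 5e-8. When per-cohort
#' evidence is missing the tier is computed from the meta p alone and the
#' record is flagged degraded.
#'
#' @param meta A one-row meta record from [ivw_meta()].
#' @param alpha_gw Genome-wide threshold (default 5e-8).
#' @param alpha_conservative Conservative threshold (default 2e-9).
#' @param alpha_cohort Per-cohort replication threshold (default 0.05).
#' @return A list with `tier` (`"none"`, `"genome_wide"`,
#'   `"conservative"`), `concordant`, `replicated_both`, `degraded`.
#' @export
classify_significance <- function(meta, alpha_gw = 5e-8,
                                  alpha_conservative = 2e-9,
                                  alpha_cohort = 0.05) {
  p_cohort <- if (!is.null(meta$p_cohort)) meta$p_cohort[[1L]] else NULL
  degraded <- is.null(p_cohort) || length(p_cohort) < 2L || anyNA(p_cohort)
  concordant <- isTRUE(meta$concordant)
  replicated <- !degraded && all(p_cohort < alpha_cohort)
  tier <- "none"
  if (meta$p_meta < alpha_gw) tier <- "genome_wide"
  if (degraded) {
    if (meta$p_meta < alpha_conservative) tier <- "conservative"
  } else if (meta$p_meta < alpha_conservative && concordant && replicated) {
    tier <- "conservative"
  }
  list(tier = tier, concordant = concordant,
       replicated_both = replicated, degraded = degraded)
}

#' Bonferroni threshold for a number of tests
#'
#' @param n_tests Effective number of independent tests (> 0).
#' @param reported Also return the one-significant-figure rounding used for
#'   reporting.
#' @return `0.05 / n_tests`; with `reported = TRUE`, a list with `exact`
#'   and `reported`.
#' @export
bonferroni_threshold <- function(n_tests, reported = FALSE) {
  stopifnot(n_tests > 0)
  x <- 0.05 / n_tests
  if (reported) list(exact = x, reported = signif(x, 1)) else x
}

#' Build an LD lookup from a pair table or a matrix
#'
#' @param ld Either a data.frame with columns `id1`, `id2`, `r2`, or a
#'   symmetric matrix with variant ids as dimnames.
#' @return A function `(id_a, id_b) -> r2` returning 1 on the diagonal and
#'   0 (with a log attribute) for absent pairs.
#' @export
ld_lookup <- function(ld) {
  if (is.matrix(ld)) {
    function(a, b) {
      if (a == b) return(1)
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else 0
    }
  } else {
    stopifnot(all(c("id1", "id2", "r2") %in% names(ld)))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    env <- new.env(parent = emptyenv(), size = max(1L, nrow(ld)))
    if (nrow(ld)) {
      ks <- key(ld$id1, ld$id2)
      for (i in seq_len(nrow(ld))) assign(ks[i], ld$r2[i], envir = env)
    }
    function(a, b) {
      if (a == b) return(1)
      get0(key(a, b), envir = env, ifnotfound = 0)
    }
  }
}

#' Greedy LD clumping around lead variants
#'
#' Variants inside the MHC (chr6:25.5-34.0 Mb) are first assigned to a
#' single MHC pseudo-clump regardless of LD. The remaining variants are
#' clumped greedily: the lowest-p unassigned variant becomes a lead (ties
#' broken lexicographically by variant id) and all unassigned variants on
#' the same chromosome within the window and with r2 above the threshold
#' join its clump.
#'
#' @param meta `data.frame` with `variant_id`, `chromosome`, `position`,
#'   `p_meta` (and optionally `gene`).
#' @param ld An [ld_lookup()] function, pair table, or matrix. Missing
#'   in-window pairs count as r2 = 0.
#' @param window_bp Half-window around leads (default 500000).
#' @param r2_threshold r2 above which (strict) a variant joins a clump
#'   (default 0.1).
#' @return `data.frame` with one row per variant: `clump_id`,
#'   `lead_variant`, `variant_id`, `chromosome`, `position`, `p_meta`,
#'   `is_mhc` (plus `gene` when supplied).
#' @export
clump <- function(meta, ld, window_bp = 500000L, r2_threshold = 0.1) {
  stopifnot(all(c("variant_id", "chromosome", "position", "p_meta") %in% names(meta)))
  r2 <- if (is.function(ld)) ld else ld_lookup(ld)
  meta <- as.data.frame(meta)
  n <- nrow(meta)
  assigned <- rep(NA_character_, n)
  lead_of <- rep(NA_character_, n)
  mhc <- in_mhc(meta$chromosome, meta$position)
  if (any(mhc)) {
    assigned[mhc] <- "MHC"
    sent <- order(meta$p_meta, meta$variant_id)
    sent <- sent[mhc[sent]][1L]
    lead_of[mhc] <- meta$variant_id[sent]
  }
  ord <- order(meta$p_meta, meta$variant_id)
  clump_n <- 0L
  for (i in ord) {
    if (!is.na(assigned[i])) next
    clump_n <- clump_n + 1L
    cid <- sprintf("clump%03d", clump_n)
    lead <- meta$variant_id[i]
    members <- which(is.na(assigned) &
                       meta$chromosome == meta$chromosome[i] &
                       abs(meta$position - meta$position[i]) <= window_bp)
    members <- members[vapply(meta$variant_id[members],
                              function(v) v == lead || r2(lead, v) > r2_threshold,
                              logical(1))]
    assigned[members] <- cid
    lead_of[members] <- lead
  }
  out <- data.frame(clump_id = assigned, lead_variant = lead_of,
                    variant_id = meta$variant_id,
                    chromosome = meta$chromosome, position = meta$position,
                    p_meta = meta$p_meta, is_mhc = mhc,
                    stringsAsFactors = FALSE)
  if (!is.null(meta$gene)) out$gene <- meta$gene
  if (!is.null(meta$disease_cluster)) out$disease_cluster <- meta$disease_cluster
  out
}

#' Merge clumps into distinct association regions
#'
#' Clumps whose spans, padded by the window on both sides, overlap on the
#' same chromosome are unioned into one region (regions from different
#' disease clusters that overlap are merged into one distinct region).
#' Within each region the most significant variant per annotated gene is
#' kept as that gene's sentinel, and the overall minimum-p variant (ties
#' broken lexicographically) is the region sentinel. The MHC is always a
#' single region with fixed bounds.
#'
#' @param clumps A [clump()] result (optionally with `gene` and
#'   `disease_cluster` columns).
#' @param window_bp Padding used for the overlap test (default 500000).
#' @return `data.frame` of class `region_table`: `region_id`,
#'   `chromosome`, `start`, `end`, `sentinel_variant`, `sentinel_gene`,
#'   `n_variants`, `is_mhc`, list columns `member_variants`,
#'   `disease_clusters`, and attribute `gene_sentinels`.
#' @export
merge_regions <- function(clumps, window_bp = 500000L) {
  stopifnot(all(c("clump_id", "variant_id", "chromosome", "position", "p_meta") %in% names(clumps)))
  cl <- split(clumps, clumps$clump_id)
  spans <- do.call(rbind, lapply(cl, function(d) {
    data.frame(clump_id = d$clump_id[[1L]], chromosome = d$chromosome[[1L]],
               start = min(d$position), end = max(d$position),
               is_mhc = any(d$is_mhc), stringsAsFactors = FALSE)
  }))
  # Union of padded spans per chromosome; the MHC clump keeps fixed bounds.
  spans$rid <- NA_integer_
  rid <- 0L
  for (chr in unique(spans$chromosome)) {
    idx <- which(spans$chromosome == chr & !spans$is_mhc)
    idx <- idx[order(spans$start[idx])]
    last_end <- -Inf
    for (i in idx) {
      if (spans$start[i] - window_bp > last_end) {
        rid <- rid + 1L
        spans$rid[i] <- rid
      } else {
        spans$rid[i] <- rid
      }
      last_end <- max(last_end, spans$end[i] + window_bp)
    }
  }
  if (any(spans$is_mhc)) {
    rid <- rid + 1L
    spans$rid[spans$is_mhc] <- rid
  }
  regions <- vector("list", length(unique(spans$rid)))
  k <- 0L
  for (r in unique(spans$rid)) {
    k <- k + 1L
    members <- clumps[clumps$clump_id %in% spans$clump_id[spans$rid == r], , drop = FALSE]
    members <- members[order(members$p_meta, members$variant_id), , drop = FALSE]
    is_mhc <- any(members$is_mhc)
    start <- if (is_mhc) MHC_START else min(members$position)
    end <- if (is_mhc) MHC_END else max(members$position)
    sentinel <- members$variant_id[[1L]]
    sentinel_gene <- if (!is.null(members$gene)) members$gene[[1L]] else NA_character_
    gene_sent <- NULL
    if (!is.null(members$gene)) {
      gene_sent <- do.call(rbind, lapply(split(members, members$gene), function(d) {
        d <- d[order(d$p_meta, d$variant_id), , drop = FALSE]
        data.frame(gene = d$gene[[1L]], variant_id = d$variant_id[[1L]],
                   p_meta = d$p_meta[[1L]], stringsAsFactors = FALSE)
      }))
    }
    reg <- data.frame(
      chromosome = members$chromosome[[1L]], start = start, end = end,
      sentinel_variant = sentinel, sentinel_gene = sentinel_gene,
      n_variants = nrow(members), is_mhc = is_mhc, stringsAsFactors = FALSE)
    reg$member_variants <- I(list(members$variant_id))
    reg$disease_clusters <- I(list(
      if (!is.null(members$disease_cluster)) sort(unique(members$disease_cluster)) else character(0)))
    reg$gene_sentinels <- I(list(gene_sent))
    regions[[k]] <- reg
  }
  out <- do.call(rbind, regions)
  # Deterministic region ids: chromosome, then start, then sentinel.
  out <- out[order(out$chromosome, out$start, out$sentinel_variant), , drop = FALSE]
  out$region_id <- ifelse(out$is_mhc, "region_MHC",
                          sprintf("region_%s_%d_%s", out$chromosome, out$start,
                                  out$sentinel_variant))
  rownames(out) <- NULL
  out <- out[, c("region_id", setdiff(names(out), "region_id"))]
  class(out) <- c("region_table", "data.frame")
  out
}

#' Allele-frequency fold enrichment between cohorts
#'
#' `log2_fe = log2(af_enriched / af_ref)` together with a two-sided
#' Fisher's exact test on the 2x2 allele-count table (alternate vs
#' reference alleles by cohort). Allele counts are reconstructed as
#' `round(2 n af)` unless exact counts are supplied. Enrichment is flagged
#' at unadjusted p < 5e-5.
#'
#' @param af_ref,af_enr Alternate-allele frequencies in the reference and
#'   enriched cohorts.
#' @param n_ref,n_enr Cohort sample sizes (individuals).
#' @param counts Optional exact alternate-allele counts
#'   `c(ref = ..., enr = ...)`.
#' @param alpha Flagging threshold (default 5e-5).
#' @return A list of class `fold_enrichment` with `log2_fe`, `fisher_p`,
#'   `odds_ratio`, `allele_counts` (2x2), `flagged`.
#' @export
fold_enrichment <- function(af_ref, n_ref, af_enr, n_enr, counts = NULL,
                            alpha = 5e-5) {
  stopifnot(af_ref >= 0, af_ref < 1, af_enr >= 0, af_enr < 1,
            n_ref >= 1, n_enr >= 1)
  a_ref <- if (!is.null(counts)) counts[["ref"]] else round(2 * n_ref * af_ref)
  a_enr <- if (!is.null(counts)) counts[["enr"]] else round(2 * n_enr * af_enr)
  tab <- matrix(c(a_enr, 2 * n_enr - a_enr,
                  a_ref, 2 * n_ref - a_ref), nrow = 2, byrow = TRUE,
                dimnames = list(c("enriched", "reference"), c("alt", "ref")))
  ft <- stats::fisher.test(tab)
  log2_fe <- if (af_ref == 0 && af_enr == 0) NaN
             else if (af_ref == 0) Inf
             else if (af_enr == 0) -Inf
             else log2(af_enr / af_ref)
  structure(list(log2_fe = log2_fe, fisher_p = ft$p.value,
                 odds_ratio = unname(ft$estimate), allele_counts = tab,
                 flagged = ft$p.value < alpha),
            class = "fold_enrichment")
}

#' Count disease-cluster pleiotropy per locus
#'
#' For each distinct region, the number of unique associated disease
#' clusters; the MHC is counted as a single locus. Loci associated with
#' five or more clusters are flagged pleiotropic.
#'
#' @param regions A `data.frame` with `region_id` and `disease_cluster`
#'   columns (one row per region-cluster association), or a
#'   [merge_regions()] result whose `disease_clusters` list column is used.
#' @param pleiotropy_min Cluster count at which a locus is flagged
#'   (default 5).
#' @return `data.frame` with `region_id`, `n_clusters`, `pleiotropic`.
#' @export
count_pleiotropy <- function(regions, pleiotropy_min = 5L) {
  if (!is.null(regions$disease_clusters)) {
    df <- data.frame(region_id = regions$region_id,
                     n_clusters = vapply(regions$disease_clusters,
                                         function(x) length(unique(x)), integer(1)))
  } else {
    stopifnot(all(c("region_id", "disease_cluster") %in% names(regions)))
    agg <- stats::aggregate(disease_cluster ~ region_id, data = regions,
                            FUN = function(x) length(unique(x)))
    df <- data.frame(region_id = agg$region_id, n_clusters = agg$disease_cluster)
  }
  df <- df[!duplicated(df$region_id), , drop = FALSE]
  df$pleiotropic <- df$n_clusters >= pleiotropy_min
  rownames(df) <- NULL
  df
}
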