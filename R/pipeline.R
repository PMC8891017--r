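# End-to-end orchestration of the synthetic two-cohort study:
# simulate -> per-cohort association -> meta-analysis -> significance
# tiers -> clump/merge -> reports, with a JSON manifest and full
# determinism under fixed seeds.

#' Pipeline configuration
#'
#' Validates and assembles the full configuration for [run_pipeline()].
#' Unknown keys are rejected. All decision thresholds carry their standard
#' defaults: genome-wide 5e-8, conservative 2e-9, per-cohort replication
#' 0.05, Jaccard retention 0.7, cluster cut height 0.8, biomarker scan
#' 1e-6, fold-enrichment flag 5e-5.
#'
#' @param n_variants,maf_range,enrichment_values,ld_block_size,ld_rho,causal_fraction
#'   Panel parameters (see [generate_variant_panel()]).
#' @param n_cohort1,n_cohort2 Cohort sample sizes.
#' @param prevalence Disease prevalence (both cohorts).
#' @param seed Master seed; stage seeds are derived from it.
#' @param filter A [filter_config()].
#' @param thresholds Named list of decision thresholds (partial overrides
#'   allowed).
#' @param ... Unknown keys trigger an error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_variants = 2000L,
                            maf_range = c(1e-4, 0.01),
                            enrichment_values = c(1, 2, 5, 10, 20, 50),
                            ld_block_size = 10L,
                            ld_rho = 0.5,
                            causal_fraction = 0.05,
                            n_cohort1 = 20000L,
                            n_cohort2 = 13000L,
                            prevalence = 0.1,
                            seed = 1L,
                            filter = filter_config(),
                            thresholds = list(),
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(names(extra), collapse = ", ")), call. = FALSE)
  default_thresholds <- list(alpha_gw = 5e-8, alpha_conservative = 2e-9,
                             alpha_cohort = 0.05, jaccard = 0.7,
                             cut_height = 0.8, alpha_biomarker = 1e-6,
                             alpha_fold = 5e-5, clump_r2 = 0.1,
                             clump_window_bp = 500000L)
  unknown <- setdiff(names(thresholds), names(default_thresholds))
  if (length(unknown))
    stop(sprintf("unknown threshold key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  default_thresholds[names(thresholds)] <- thresholds
  structure(list(n_variants = n_variants, maf_range = maf_range,
                 enrichment_values = enrichment_values,
                 ld_block_size = ld_block_size, ld_rho = ld_rho,
                 causal_fraction = causal_fraction,
                 n_cohort1 = n_cohort1, n_cohort2 = n_cohort2,
                 prevalence = prevalence, seed = as.integer(seed),
                 filter = filter, thresholds = default_thresholds),
            class = "pipeline_config")
}

# Dosage r-squared between in-window variant pairs within LD blocks.
compute_block_ld <- function(dosage, panel) {
  rows <- list()
  for (b in unique(panel$ld_block_id)) {
    j <- which(panel$ld_block_id == b)
    if (length(j) < 2L) next
    cm <- suppressWarnings(stats::cor(dosage[, j, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      id1 = panel$variant_id[j][idx[, 1L]],
      id2 = panel$variant_id[j][idx[, 2L]],
      r2 = cm[idx]^2, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||% data.frame(id1 = character(0), id2 = character(0),
                                       r2 = numeric(0))
}

#' Run the end-to-end synthetic study
#'
#' Executes simulate -> association (per cohort) -> meta-analysis ->
#' significance classification -> clump/merge, writing each stage's TSV to
#' `out_dir` together with a JSON manifest recording seeds, thresholds,
#' row counts and every filter counter. Reruns with the same configuration
#' are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly, with the main stage outputs attached
#'   as attributes (`panel`, `stats1`, `stats2`, `meta`, `tiers`,
#'   `clumps`, `regions`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("cwas_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds

  panel <- generate_variant_panel(
    n_variants = config$n_variants, maf_range = config$maf_range,
    enrichment_values = config$enrichment_values,
    ld_block_size = config$ld_block_size, ld_rho = config$ld_rho,
    causal_fraction = config$causal_fraction,
    seed = derive_seed(config$seed, "panel"))
  write_panel(panel, file.path(out_dir, "panel.tsv"))

  cohort1 <- generate_cohort(panel, "cohort1", config$n_cohort1,
                             config$prevalence,
                             seed = derive_seed(config$seed, "cohort1"), cohort = 1L)
  cohort2 <- generate_cohort(panel, "cohort2", config$n_cohort2,
                             config$prevalence,
                             seed = derive_seed(config$seed, "cohort2"), cohort = 2L)

  stats1 <- assoc_scan(cohort1, cfg = config$filter, panel = panel)
  stats2 <- assoc_scan(cohort2, cfg = config$filter, panel = panel)
  write_summary_stats(stats1, file.path(out_dir, "assoc_cohort1.tsv"), panel = panel)
  write_summary_stats(stats2, file.path(out_dir, "assoc_cohort2.tsv"), panel = panel)

  meta <- meta_analyse(stats1, stats2)
  write_meta_records(meta, file.path(out_dir, "meta.tsv"))

  tiers <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    cl <- classify_significance(meta[i, ], alpha_gw = th$alpha_gw,
                                alpha_conservative = th$alpha_conservative,
                                alpha_cohort = th$alpha_cohort)
    data.frame(variant_id = meta$variant_id[i], tier = cl$tier,
               concordant = cl$concordant, replicated_both = cl$replicated_both,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(data.table::as.data.table(tiers),
                     file.path(out_dir, "tiers.tsv"), sep = "\t", quote = FALSE)

  ld <- compute_block_ld(cohort1$dosage, panel)
  write_ld(ld, file.path(out_dir, "ld.tsv"))

  sig <- meta[meta$p_meta < th$alpha_gw, , drop = FALSE]
  regions <- NULL
  clumps <- NULL
  if (nrow(sig)) {
    sig$chromosome <- panel$chromosome[match(sig$variant_id, panel$variant_id)]
    sig$position <- panel$position[match(sig$variant_id, panel$variant_id)]
    sig$gene <- panel$gene[match(sig$variant_id, panel$variant_id)]
    clumps <- clump(sig, ld, window_bp = th$clump_window_bp,
                    r2_threshold = th$clump_r2)
    data.table::fwrite(data.table::as.data.table(clumps),
                       file.path(out_dir, "clumps.tsv"), sep = "\t", quote = FALSE)
    regions <- merge_regions(clumps, window_bp = th$clump_window_bp)
    reg_flat <- regions[, c("region_id", "chromosome", "start", "end",
                            "sentinel_variant", "sentinel_gene", "n_variants",
                            "is_mhc")]
    data.table::fwrite(data.table::as.data.table(reg_flat),
                       file.path(out_dir, "regions.tsv"), sep = "\t", quote = FALSE)
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
  }

  inflation <- genomic_inflation(meta$p_meta)

  filter_counts <- function(st) {
    log <- attr(st, "filter_log")
    counts <- table(factor(log$reason, levels = c("case_count", "total_mac",
                                                  "stratum_mac", "info",
                                                  "non_convergence")))
    as.list(counts)
  }
  manifest <- list(
    seed = config$seed,
    thresholds = th,
    stages = list(
      panel = list(rows = nrow(panel)),
      assoc_cohort1 = c(list(rows = nrow(stats1)), filtered = filter_counts(stats1)),
      assoc_cohort2 = c(list(rows = nrow(stats2)), filtered = filter_counts(stats2)),
      meta = list(rows = nrow(meta),
                  dropped = nrow(attr(meta, "harmonization_log"))),
      tiers = list(rows = nrow(tiers),
                   genome_wide = sum(tiers$tier != "none"),
                   conservative = sum(tiers$tier == "conservative")),
      regions = list(rows = if (is.null(regions)) 0L else nrow(regions))),
    lambda_gc = inflation$lambda_gc)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(manifest, "panel") <- panel
  attr(manifest, "stats1") <- stats1
  attr(manifest, "stats2") <- stats2
  attr(manifest, "meta") <- meta
  attr(manifest, "tiers") <- tiers
  attr(manifest, "clumps") <- clumps
  attr(manifest, "regions") <- regions
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}
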