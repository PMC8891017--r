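# Validating readers and writers for the pipeline's delimited text formats.
# All coordinates in TSVs are 1-based inclusive; only the BED export is
# 0-based half-open (stated in its header).

SUMMARY_STAT_COLUMNS <- c("VARIANT_ID", "CHR", "POS", "A0", "A1", "AF", "INFO",
                          "BETA", "SE", "PVAL", "N", "N_CASES", "MAC_CASES",
                          "MAC_CONTROLS", "METHOD")

PANEL_COLUMNS <- c("VARIANT_ID", "CHR", "POS", "A0", "A1", "GENE", "MAF1",
                   "MAF2", "ENRICH", "BLOCK", "BETA_TRUE", "INFO")

check_header <- function(found, expected, path) {
  if (!identical(found, expected)) {
    missing <- setdiff(expected, found)
    extra <- setdiff(found, expected)
    stop(sprintf("header mismatch in %s: missing [%s], unexpected [%s]",
                 path, paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

valid_allele <- function(a) grepl("^[ACGT]+$|^-$", a)

#' Write a METAL-compatible summary-statistic TSV
#'
#' @param stats Summary-statistic `data.frame` (package column layout) with
#'   `chromosome`/`position` columns or a `panel` supplying them.
#' @param path Output path.
#' @param panel Optional panel for coordinates.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path, panel = NULL) {
  chr <- stats$chromosome %||% (if (!is.null(panel)) panel$chromosome[match(stats$variant_id, panel$variant_id)] else rep(NA, nrow(stats)))
  pos <- stats$position %||% (if (!is.null(panel)) panel$position[match(stats$variant_id, panel$variant_id)] else rep(NA, nrow(stats)))
  out <- data.table::data.table(
    VARIANT_ID = stats$variant_id, CHR = chr, POS = pos,
    A0 = stats$allele_ref, A1 = stats$allele_alt, AF = stats$af_alt,
    INFO = stats$info_score, BETA = stats$beta, SE = stats$se,
    PVAL = stats$p_value, N = stats$n, N_CASES = stats$n_cases,
    MAC_CASES = stats$mac_cases, MAC_CONTROLS = stats$mac_controls,
    METHOD = stats$method)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a METAL-compatible summary-statistic TSV
#'
#' Validates the header, allele strings, and numeric ranges; malformed
#' rows are reported with their line numbers.
#'
#' @param path Input TSV.
#' @param cohort_id Cohort label to attach.
#' @return Summary-statistic `data.frame` in the package layout, with
#'   `chromosome` and `position` columns.
#' @export
read_summary_stats <- function(path, cohort_id = "cohort1") {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = c("VARIANT_ID", "CHR", "A0", "A1", "METHOD")))
  check_header(names(dt), SUMMARY_STAT_COLUMNS, path)
  line <- seq_len(nrow(dt)) + 1L  # header is line 1
  bad_allele <- !valid_allele(dt$A0) | !valid_allele(dt$A1)
  if (any(bad_allele))
    stop(sprintf("invalid allele string at line(s) %s of %s",
                 paste(line[bad_allele], collapse = ", "), path), call. = FALSE)
  bad_af <- !is.finite(dt$AF) | dt$AF < 0 | dt$AF > 1
  if (any(bad_af))
    stop(sprintf("AF outside [0, 1] at line(s) %s of %s",
                 paste(line[bad_af], collapse = ", "), path), call. = FALSE)
  bad_se <- !is.finite(dt$SE) | dt$SE <= 0
  if (any(bad_se))
    stop(sprintf("non-positive SE at line(s) %s of %s",
                 paste(line[bad_se], collapse = ", "), path), call. = FALSE)
  bad_p <- !is.finite(dt$PVAL) | dt$PVAL <= 0 | dt$PVAL > 1
  if (any(bad_p))
    stop(sprintf("PVAL outside (0, 1] at line(s) %s of %s",
                 paste(line[bad_p], collapse = ", "), path), call. = FALSE)
  out <- summary_stat(variant_id = dt$VARIANT_ID, cohort_id = cohort_id,
                      allele_ref = dt$A0, allele_alt = dt$A1, af_alt = dt$AF,
                      beta = dt$BETA, se = dt$SE, p_value = dt$PVAL,
                      n = dt$N, n_cases = dt$N_CASES,
                      mac_total = dt$MAC_CASES + dt$MAC_CONTROLS,
                      mac_cases = dt$MAC_CASES, mac_controls = dt$MAC_CONTROLS,
                      method = dt$METHOD, info_score = dt$INFO)
  out$chromosome <- dt$CHR
  out$position <- dt$POS
  out
}

#' Write a variant panel TSV
#' @param panel A [generate_variant_panel()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- data.table::data.table(
    VARIANT_ID = panel$variant_id, CHR = panel$chromosome, POS = panel$position,
    A0 = panel$allele_ref, A1 = panel$allele_alt, GENE = panel$gene,
    MAF1 = panel$maf_cohort1, MAF2 = panel$maf_cohort2,
    ENRICH = panel$enrichment, BLOCK = panel$ld_block_id,
    BETA_TRUE = panel$true_beta, INFO = panel$info_score)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a variant panel TSV
#' @param path Input TSV.
#' @param ld_rho Latent LD correlation to attach (not stored in the file).
#' @return A `variant_panel` data.frame.
#' @export
read_panel <- function(path, ld_rho = 0) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("VARIANT_ID", "CHR", "A0", "A1", "GENE")))
  check_header(names(dt), PANEL_COLUMNS, path)
  line <- seq_len(nrow(dt)) + 1L
  bad_maf <- !is.finite(dt$MAF1) | dt$MAF1 <= 0 | dt$MAF1 > 0.5 |
    !is.finite(dt$MAF2) | dt$MAF2 <= 0 | dt$MAF2 >= 1
  if (any(bad_maf))
    stop(sprintf("MAF out of range at line(s) %s of %s",
                 paste(line[bad_maf], collapse = ", "), path), call. = FALSE)
  panel <- data.frame(
    variant_id = dt$VARIANT_ID, chromosome = dt$CHR, position = dt$POS,
    allele_ref = dt$A0, allele_alt = dt$A1, gene = dt$GENE,
    maf_cohort1 = dt$MAF1, maf_cohort2 = dt$MAF2, enrichment = dt$ENRICH,
    ld_block_id = dt$BLOCK, true_beta = dt$BETA_TRUE, info_score = dt$INFO,
    stringsAsFactors = FALSE)
  attr(panel, "ld_rho") <- ld_rho
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Write pairwise LD as three-column delimited text
#' @param ld `data.frame` with `id1`, `id2`, `r2`.
#' @param path Output path.
#' @export
write_ld <- function(ld, path) {
  stopifnot(all(c("id1", "id2", "r2") %in% names(ld)))
  data.table::fwrite(data.table::as.data.table(ld[, c("id1", "id2", "r2")]),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read pairwise LD from three-column delimited text
#' @param path Input path.
#' @return `data.frame` with `id1`, `id2`, `r2`.
#' @export
read_ld <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("id1", "id2")))
  check_header(names(dt), c("id1", "id2", "r2"), path)
  bad <- !is.finite(dt$r2) | dt$r2 < 0 | dt$r2 > 1
  if (any(bad))
    stop(sprintf("r2 outside [0, 1] at line(s) %s of %s",
                 paste(which(bad) + 1L, collapse = ", "), path), call. = FALSE)
  as.data.frame(dt)
}

#' Write meta-analysis records as TSV
#' @param meta [meta_analyse()] output.
#' @param path Output path.
#' @export
write_meta_records <- function(meta, path) {
  pc <- do.call(rbind, lapply(meta$p_cohort, function(p) {
    if (length(p) == 2L) p else c(p, NA_real_)[1:2]
  }))
  out <- data.table::data.table(
    VARIANT_ID = meta$variant_id, BETA_META = meta$beta_meta,
    SE_META = meta$se_meta, Z_META = meta$z_meta, P_META = meta$p_meta,
    DIRECTIONS = meta$directions, P_COHORT1 = pc[, 1L], P_COHORT2 = pc[, 2L],
    N_TOTAL = meta$n_total, CONCORDANT = meta$concordant,
    Q_HET = meta$q_het, P_HET = meta$p_het)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Export regions as BED (0-based half-open)
#'
#' The only 0-based half-open output of the package; the coordinate
#' convention is stated in the file's header comment.
#'
#' @param regions [merge_regions()] output.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open coordinates (internal tables are 1-based inclusive)", con)
  for (i in seq_len(nrow(regions))) {
    writeLines(sprintf("%s\t%d\t%d\t%s", regions$chromosome[i],
                       regions$start[i] - 1L, regions$end[i],
                       regions$region_id[i]), con)
  }
  invisible(path)
}

#' Write ICD phenotype definitions as CSV
#' @param pairs [generate_icd_pairs()] output.
#' @param path Output path.
#' @export
write_icd_pairs <- function(pairs, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    data.frame(phenotype_id = rep(pairs$phenotype_id[i], 2L),
               cohort = c("cohort1", "cohort2"),
               name = rep(pairs$name[i], 2L),
               codes = c(paste(pairs$codes_cohort1[[i]], collapse = ";"),
                         paste(pairs$codes_cohort2[[i]], collapse = ";")),
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(data.table::as.data.table(rows), path, sep = ",", quote = TRUE)
  invisible(path)
}

#' Read ICD phenotype definitions from CSV
#' @param path Input path (columns phenotype_id, cohort, name, codes).
#' @return An `icd_pairs`-style data.frame with list columns.
#' @export
read_icd_pairs <- function(path) {
  dt <- data.table::fread(path, sep = ",", colClasses = "character")
  check_header(names(dt), c("phenotype_id", "cohort", "name", "codes"), path)
  ids <- unique(dt$phenotype_id)
  rows <- lapply(ids, function(id) {
    d <- dt[dt$phenotype_id == id, ]
    c1 <- strsplit(d$codes[d$cohort == "cohort1"], ";")[[1]] %||% character(0)
    c2 <- strsplit(d$codes[d$cohort == "cohort2"], ";")[[1]] %||% character(0)
    out <- data.frame(phenotype_id = id, name = d$name[[1L]],
                      jaccard_target = NA_real_,
                      jaccard = jaccard_similarity(c1, c2),
                      stringsAsFactors = FALSE)
    out$codes_cohort1 <- I(list(c1))
    out$codes_cohort2 <- I(list(c2))
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("icd_pairs", "data.frame")
  out
}

#' Read an MR input table
#' @param path Four/five-column TSV: variant_id, beta_x, se_x, beta_y, se_y.
#' @return `data.frame` of ratio estimates (via [ratio_estimate()]).
#' @export
read_mr_input <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = "variant_id"))
  check_header(names(dt), c("variant_id", "beta_x", "se_x", "beta_y", "se_y"), path)
  bad <- dt$beta_x == 0
  if (any(bad))
    stop(sprintf("beta_x = 0 (weak instrument) at line(s) %s of %s",
                 paste(which(bad) + 1L, collapse = ", "), path), call. = FALSE)
  do.call(rbind, lapply(seq_len(nrow(dt)), function(i)
    ratio_estimate(dt$beta_x[i], dt$se_x[i], dt$beta_y[i], dt$se_y[i],
                   variant_id = dt$variant_id[i])))
}
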