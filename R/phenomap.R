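# Phenotype harmonization between cohorts (Jaccard filter on ICD-10 code
# sets) and disease clustering (cosine similarity, Ward linkage, fixed cut
# height).

#' Jaccard similarity of two code sets
#'
#' `|intersection| / |union|`; defined as 1 when both sets are empty (a
#' warning is emitted for that degenerate case).
#'
#' @param set_a,set_b Character vectors (treated as sets).
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both code sets empty; Jaccard defined as 1", call. = FALSE)
    return(1)
  }
  length(intersect(a, b)) / u
}

#' Default phenotype exclusion patterns
#'
#' Case-insensitive regular expressions matched against phenotype names;
#' spontaneous deliveries and abortions are excluded from harmonization.
#' @export
phenotype_exclusion_patterns <- c("spontaneous deliver", "abortion")

#' Harmonize phenotype definitions across cohorts
#'
#' A phenotype is retained when the Jaccard index between its two cohorts'
#' ICD-10 code sets is strictly greater than the threshold and its name
#' matches none of the exclusion patterns.
#'
#' @param defs A `data.frame` with `phenotype_id`, `name` and list columns
#'   `codes_cohort1`, `codes_cohort2` (e.g. from [generate_icd_pairs()]).
#' @param threshold Strict retention threshold (default 0.7).
#' @param exclusion_patterns Case-insensitive regexes on `name`.
#' @return `defs` with added columns `jaccard`, `excluded_by_rule`,
#'   `retained`.
#' @export
harmonize_phenotypes <- function(defs, threshold = 0.7,
                                 exclusion_patterns = phenotype_exclusion_patterns) {
  stopifnot(all(c("phenotype_id", "codes_cohort1", "codes_cohort2") %in% names(defs)))
  jac <- mapply(jaccard_similarity, defs$codes_cohort1, defs$codes_cohort2)
  nm <- defs$name %||% defs$phenotype_id
  excl <- rep(FALSE, nrow(defs))
  for (pat in exclusion_patterns)
    excl <- excl | grepl(pat, nm, ignore.case = TRUE)
  defs$jaccard <- as.numeric(jac)
  defs$excluded_by_rule <- excl
  defs$retained <- jac > threshold & !excl
  defs
}

# Row-wise cosine similarity.
cosine_similarity <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  s <- tcrossprod(x / nrm)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' Cluster disease phenotypes
#'
#' Computes cosine similarity between phenotype feature rows (binary
#' ICD-10 incidence by default, optionally case-count weighted), runs Ward
#' agglomeration (`ward.D2`) on the distance `1 - similarity`, and cuts the
#' tree at a fixed height. Identical feature rows are deduplicated before
#' agglomeration and share a cluster, so duplicated phenotype definitions
#' cannot change the clustering of the rest.
#'
#' @param feature_matrix Numeric matrix, phenotypes x features, with
#'   phenotype ids as rownames; no all-zero rows.
#' @param cut_height Tree cut height on the `1 - cosine` scale
#'   (default 0.8).
#' @return A list of class `cluster_tree` with `similarity`, `hclust`,
#'   `cut_height`, `assignments` (named integer vector).
#' @export
cluster_diseases <- function(feature_matrix, cut_height = 0.8) {
  x <- as.matrix(feature_matrix)
  if (nrow(x) < 2L) stop("need at least two phenotypes to cluster", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- sprintf("PHENO%03d", seq_len(nrow(x)))
  zero <- rowSums(abs(x)) == 0
  if (any(zero))
    stop(sprintf("all-zero feature row for phenotype(s): %s",
                 paste(rownames(x)[zero], collapse = ", ")), call. = FALSE)
  key <- apply(x, 1L, paste, collapse = "\r")
  uniq <- !duplicated(key)
  xu <- x[uniq, , drop = FALSE]
  sim <- cosine_similarity(x)
  if (nrow(xu) == 1L) {
    memb <- rep(1L, nrow(x))
    names(memb) <- rownames(x)
    return(structure(list(similarity = sim, hclust = NULL,
                          cut_height = cut_height, assignments = memb),
                     class = "cluster_tree"))
  }
  d <- stats::as.dist(1 - cosine_similarity(xu))
  hc <- stats::hclust(d, method = "ward.D2")
  cl_u <- stats::cutree(hc, h = cut_height)
  memb <- cl_u[match(key, key[uniq])]
  names(memb) <- rownames(x)
  structure(list(similarity = sim, hclust = hc, cut_height = cut_height,
                 assignments = memb),
            class = "cluster_tree")
}

#' Binary incidence matrix from harmonized phenotype definitions
#'
#' Builds the phenotype x ICD-code indicator matrix over the union code
#' universe of both cohorts, the default feature space for
#' [cluster_diseases()].
#'
#' @param defs Output of [harmonize_phenotypes()] (retained rows are used
#'   unless `retained_only = FALSE`).
#' @param retained_only Restrict to retained phenotypes.
#' @return Binary matrix with phenotype ids as rownames.
#' @export
phenotype_feature_matrix <- function(defs, retained_only = TRUE) {
  if (retained_only && !is.null(defs$retained)) defs <- defs[defs$retained, , drop = FALSE]
  codes <- mapply(function(a, b) unique(c(a, b)),
                  defs$codes_cohort1, defs$codes_cohort2, SIMPLIFY = FALSE)
  universe <- sort(unique(unlist(codes)))
  x <- matrix(0L, nrow(defs), length(universe),
              dimnames = list(defs$phenotype_id, universe))
  for (i in seq_along(codes)) x[i, match(codes[[i]], universe)] <- 1L
  x
}
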