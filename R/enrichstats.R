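# Exact-test enrichment utilities: Fisher's exact test on 2x2 tables built
# from a gene set against a background, in background-inclusive or
# background-exclusive form, and a motif-set wrapper over id sets.

#' Fisher's exact enrichment test
#'
#' Builds the 2x2 table for `a` hits among `set_size` set members against
#' `hits_bg` hits among `bg_size` background members and runs the two-sided
#' exact test. In `background-inclusive` mode (the default) the background
#' margins are used as given, i.e. the table is
#' `(a, set_size - a, hits_bg, bg_size - hits_bg)`; `background-exclusive`
#' first subtracts the set from the background. The odds ratio is the
#' conditional maximum-likelihood estimate.
#'
#' @param a Hits inside the set.
#' @param set_size Size of the set.
#' @param hits_bg Hits in the background.
#' @param bg_size Size of the background.
#' @param table_mode `"background-inclusive"` or `"background-exclusive"`.
#' @return A list of class `enrichment_table` with `odds_ratio`,
#'   `p_two_sided`, `table` (2x2), `table_mode`.
#' @export
fisher_enrichment <- function(a, set_size, hits_bg, bg_size,
                              table_mode = c("background-inclusive",
                                             "background-exclusive")) {
  table_mode <- match.arg(table_mode)
  stopifnot(a >= 0, set_size >= a, hits_bg >= 0, bg_size >= hits_bg)
  if (table_mode == "background-inclusive") {
    tab <- matrix(c(a, set_size - a, hits_bg, bg_size - hits_bg),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("set", "background"), c("hit", "miss")))
  } else {
    if (bg_size - set_size < 0 || hits_bg - a < 0)
      stop("background-exclusive mode requires the set to be contained in the background",
           call. = FALSE)
    tab <- matrix(c(a, set_size - a, hits_bg - a, (bg_size - set_size) - (hits_bg - a)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("set", "background"), c("hit", "miss")))
    if (any(tab < 0)) stop("inconsistent counts for background-exclusive table",
                           call. = FALSE)
  }
  ft <- stats::fisher.test(tab)
  structure(list(odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value,
                 table = tab, table_mode = table_mode),
            class = "enrichment_table")
}

#' Motif-set enrichment over id sets
#'
#' Tests whether `target_set` is enriched for ids carrying a motif,
#' delegating to [fisher_enrichment()] in background-exclusive mode over
#' the supplied universe. No remote retrieval is performed; all id sets
#' are caller-supplied.
#'
#' @param motif_hits Ids carrying the motif.
#' @param target_set Ids in the target set (must be a subset of
#'   `universe`).
#' @param universe All ids under consideration.
#' @return An `enrichment_table`.
#' @export
motif_enrichment <- function(motif_hits, target_set, universe) {
  motif_hits <- unique(motif_hits)
  target_set <- unique(target_set)
  universe <- unique(universe)
  if (!all(target_set %in% universe))
    stop("target set must be a subset of the universe", call. = FALSE)
  motif_hits <- intersect(motif_hits, universe)
  a <- length(intersect(motif_hits, target_set))
  fisher_enrichment(a, length(target_set), length(motif_hits), length(universe),
                    table_mode = "background-exclusive")
}
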