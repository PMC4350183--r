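#' Filter homology hits by significance
#'
#' Retains hits with e-value strictly below `max_evalue`. The percent-identity
#' rule is deliberately applied only to the top hit during best-hit selection
#' (see [best_hits()]), not as a global filter; set `strict = TRUE` to also
#' drop every hit at or below `min_identity` up front.
#'
#' @param hits Tibble from [read_hit_table()].
#' @param max_evalue Significance threshold (hits with `evalue < max_evalue`
#'   are kept). Default `1e-10`.
#' @param min_identity Percent-identity threshold used only when
#'   `strict = TRUE`. Default 30.
#' @param strict Apply the identity threshold to all hits, not just top hits.
#' @return The filtered hit tibble.
#' @export
filter_hits <- function(hits, max_evalue = 1e-10, min_identity = 30,
                        strict = FALSE) {
  stopifnot(max_evalue > 0, min_identity > 0)
  out <- dplyr::filter(hits, .data$evalue < max_evalue)
  if (strict) out <- dplyr::filter(out, .data$pct_identity > min_identity)
  out
}

#' Best hit per query
#'
#' Orders each query's hits by bitscore (descending), breaking ties by
#' e-value (ascending), percent identity (descending) and finally subject id
#' (lexicographic), and keeps the top hit — but only when that top hit's
#' identity exceeds `min_identity` percent. The tie-break cascade is a
#' reproducibility choice: bitscore alone can tie, and downstream pairing
#' must not depend on input row order.
#'
#' @param hits Filtered hit tibble (any number of queries).
#' @param min_identity Identity (percent) the top hit must exceed. Default 30.
#' @return One row per query whose top hit passes the identity rule.
#' @export
best_hits <- function(hits, min_identity = 30) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore), .data$evalue,
                   dplyr::desc(.data$pct_identity), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::filter(.data$pct_identity > min_identity)
}

#' Reciprocal best hits (rBBH) between two genomes
#'
#' A pair (a, b) is an ortholog call iff b is a's best hit in the A-to-B
#' search and a is b's best hit in the B-to-A search, after e-value filtering
#' and the top-hit identity rule. The result is one-to-one and symmetric by
#' construction.
#'
#' @param hits_ab,hits_ba Hit tibbles for the two search directions
#'   (queries of `hits_ab` are genome-A genes).
#' @param max_evalue,min_identity,strict Passed to [filter_hits()] and
#'   [best_hits()].
#' @return A tibble of pairs: `gene_a`, `gene_b`, plus best-hit provenance in
#'   both directions (`evalue_ab`, `bitscore_ab`, `identity_ab` and the `_ba`
#'   counterparts).
#' @export
#' @examples
#' ab <- tibble::tibble(query_id = "a1", subject_id = "b1",
#'                      pct_identity = 80, evalue = 1e-50, bitscore = 200)
#' ba <- tibble::tibble(query_id = "b1", subject_id = "a1",
#'                      pct_identity = 80, evalue = 1e-50, bitscore = 200)
#' reciprocal_best_hits(ab, ba)
reciprocal_best_hits <- function(hits_ab, hits_ba, max_evalue = 1e-10,
                                 min_identity = 30, strict = FALSE) {
  top_ab <- best_hits(filter_hits(hits_ab, max_evalue, min_identity, strict),
                      min_identity)
  top_ba <- best_hits(filter_hits(hits_ba, max_evalue, min_identity, strict),
                      min_identity)
  empty <- tibble::tibble(
    gene_a = character(), gene_b = character(),
    evalue_ab = double(), bitscore_ab = double(), identity_ab = double(),
    evalue_ba = double(), bitscore_ba = double(), identity_ba = double()
  )
  if (nrow(top_ab) == 0 || nrow(top_ba) == 0) return(empty)
  dplyr::inner_join(
    dplyr::select(top_ab, gene_a = "query_id", gene_b = "subject_id",
                  evalue_ab = "evalue", bitscore_ab = "bitscore",
                  identity_ab = "pct_identity"),
    dplyr::select(top_ba, gene_b = "query_id", gene_a = "subject_id",
                  evalue_ba = "evalue", bitscore_ba = "bitscore",
                  identity_ba = "pct_identity"),
    by = c("gene_a", "gene_b")
  ) |>
    dplyr::arrange(.data$gene_a)
}

#' Restrict an ortholog map to placed genes
#'
#' Keeps pairs in which both genes sit on sequences large enough to infer
#' synteny (the catalogs' `placed` flag), and reports how many pairs were
#' dropped.
#'
#' @param pairs Ortholog pairs from [reciprocal_best_hits()].
#' @param catalog_a,catalog_b Gene catalogs of the two genomes.
#' @param quiet Suppress the dropped-pair message.
#' @return The filtered pair tibble.
#' @export
restrict_to_placed <- function(pairs, catalog_a, catalog_b, quiet = FALSE) {
  placed_a <- catalog_a$genes$gene_id[catalog_a$genes$placed]
  placed_b <- catalog_b$genes$gene_id[catalog_b$genes$placed]
  out <- dplyr::filter(pairs, .data$gene_a %in% placed_a,
                       .data$gene_b %in% placed_b)
  if (!quiet && nrow(out) < nrow(pairs)) {
    message(nrow(pairs) - nrow(out), " of ", nrow(pairs),
            " ortholog pairs dropped (unplaced gene)")
  }
  out
}
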