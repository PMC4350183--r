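#' Build a gene catalog
#'
#' A gene catalog bundles the gene coordinate table of one genome with its
#' chromosome (or scaffold) lengths. All coordinates are stored 0-based
#' half-open; conversion from 1-based formats happens only in the readers.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (`"+"`, `"-"` or `"*"`), `is_mtn` (logical flag
#'   for mitonuclear genes, i.e. nuclear genes whose product localises to the
#'   mitochondrion) and `placed` (logical: on a sequence large enough to infer
#'   synteny).
#' @param chrom_lengths A data frame with columns `chrom` and `length` (bp),
#'   covering every chromosome that appears in `genes`.
#' @param genome_label Short label for the genome (used in messages and
#'   reports).
#' @param placed_pattern Optional regular expression; chromosomes matching it
#'   are considered placed. The default treats every sequence in
#'   `chrom_lengths` as placed. Which scaffolds count as "large enough" is
#'   assembly-specific metadata, so it is a configuration input rather than a
#'   rule in code.
#'
#' @return An object of class `gene_catalog`: a list with elements
#'   `genome_label`, `genes` (tibble) and `chrom_lengths` (tibble).
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2"), chrom = "chr1",
#'   start = c(0L, 200L), end = c(100L, 300L)
#' )
#' lens <- tibble::tibble(chrom = "chr1", length = 1000L)
#' gene_catalog(genes, lens, "toy")
gene_catalog <- function(genes, chrom_lengths, genome_label = "genome",
                         placed_pattern = NULL) {
  genes <- tibble::as_tibble(genes)
  chrom_lengths <- tibble::as_tibble(chrom_lengths)
  required <- c("gene_id", "chrom", "start", "end")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("chrom", "length") %in% names(chrom_lengths))) {
    stop("chrom_lengths needs columns 'chrom' and 'length'", call. = FALSE)
  }
  if (!"strand" %in% names(genes)) genes$strand <- "*"
  if (!"is_mtn" %in% names(genes)) genes$is_mtn <- FALSE
  genes$strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")

  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- genes$start >= genes$end
  if (any(bad)) {
    stop("start >= end for gene(s): ",
         paste(utils::head(genes$gene_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(genes$chrom, chrom_lengths$chrom)
  if (length(orphan) > 0) {
    stop("gene(s) on chromosome(s) absent from the lengths table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  max_end <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(max_end = max(.data$end), .groups = "drop")
  chk <- dplyr::inner_join(max_end, chrom_lengths, by = "chrom")
  short <- chk$chrom[chk$length < chk$max_end]
  if (length(short) > 0) {
    stop("chromosome length smaller than max gene end on: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  if (is.null(placed_pattern)) {
    if (!"placed" %in% names(genes)) genes$placed <- TRUE
  } else {
    genes$placed <- grepl(placed_pattern, genes$chrom)
  }
  genes <- dplyr::select(
    genes, "gene_id", "chrom", "start", "end", "strand", "is_mtn", "placed"
  )
  structure(
    list(genome_label = genome_label, genes = genes,
         chrom_lengths = chrom_lengths[, c("chrom", "length")]),
    class = "gene_catalog"
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog> ", x$genome_label, ": ",
      nrow(x$genes), " genes on ", nrow(x$chrom_lengths), " sequences; ",
      sum(x$genes$is_mtn), " mt-N; ",
      sum(!x$genes$placed), " unplaced\n", sep = "")
  invisible(x)
}

#' Flag mitonuclear genes in a catalog
#'
#' @param catalog A [gene_catalog()].
#' @param mtn_ids Character vector of gene ids to flag as mitonuclear
#'   (typically from [read_go_annotations()]).
#' @return The catalog with `is_mtn` set to membership in `mtn_ids`.
#' @export
set_mtn_flags <- function(catalog, mtn_ids) {
  stopifnot(inherits(catalog, "gene_catalog"))
  catalog$genes$is_mtn <- catalog$genes$gene_id %in% mtn_ids
  catalog
}

#' Midpoints of genes (internal helper)
#' @noRd
gene_midpoints <- function(genes) {
  (genes$start + genes$end) / 2
}

#' Per-chromosome gene-order ranks, 0-based, by start position
#' @noRd
gene_ranks <- function(genes) {
  genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(rank = rank(.data$start, ties.method = "first") - 1L) |>
    dplyr::ungroup()
}
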