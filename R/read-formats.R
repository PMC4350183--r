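#' Read a chromosome-lengths table
#'
#' Two-column TSV (`chrom`, `length` in bp), no header.
#'
#' @param path File path or connection.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_lengths <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "ci", progress = FALSE)
  if (any(is.na(tab$length))) {
    stop("non-integer length in chromosome lengths table", call. = FALSE)
  }
  tab
}

#' Read a gene coordinate table (BED6 or GFF3) into a gene catalog
#'
#' BED input is 0-based half-open and is stored as-is; GFF3 is 1-based closed
#' and converted (`start - 1`) on the way in, so internal coordinates are
#' uniformly 0-based half-open.
#'
#' @param path Path to the BED or GFF3 file.
#' @param format `"bed"` or `"gff3"`.
#' @param chrom_lengths A tibble from [read_chrom_lengths()] or a path to the
#'   lengths TSV.
#' @param genome_label Label for the genome.
#' @param mtn_ids Optional gene ids to flag as mitonuclear.
#' @param placed_pattern Optional regex defining which sequences are placed;
#'   see [gene_catalog()].
#' @return A [gene_catalog()].
#' @export
read_gene_table <- function(path, format = c("bed", "gff3"), chrom_lengths,
                            genome_label = "genome", mtn_ids = character(),
                            placed_pattern = NULL) {
  format <- match.arg(format)
  if (is.character(chrom_lengths) && length(chrom_lengths) == 1) {
    chrom_lengths <- read_chrom_lengths(chrom_lengths)
  }
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  genes <- if (format == "bed") {
    parse_bed_lines(lines[keep], idx)
  } else {
    parse_gff3_lines(lines[keep], idx)
  }
  cat <- gene_catalog(genes, chrom_lengths, genome_label,
                      placed_pattern = placed_pattern)
  if (length(mtn_ids) > 0) cat <- set_mtn_flags(cat, mtn_ids)
  cat
}

parse_bed_lines <- function(lines, line_no) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 4)) {
    stop("malformed BED line ", line_no[which(n < 4)[1]],
         ": fewer than 4 fields", call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed BED line ", line_no[which(bad)[1]],
         ": non-numeric coordinate", call. = FALSE)
  }
  tibble::tibble(
    gene_id = vapply(fields, `[`, "", 4),
    chrom = vapply(fields, `[`, "", 1),
    start = start, end = end,
    strand = vapply(fields, function(f) if (length(f) >= 6) f[6] else "*", "")
  )
}

parse_gff3_lines <- function(lines, line_no) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 9)) {
    stop("malformed GFF3 line ", line_no[which(n < 9)[1]],
         ": fewer than 9 fields", call. = FALSE)
  }
  type <- vapply(fields, `[`, "", 3)
  keep <- type == "gene" | !any(type == "gene")
  fields <- fields[keep]
  line_no <- line_no[keep]
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("malformed GFF3 line ", line_no[which(bad)[1]],
         ": non-numeric coordinate", call. = FALSE)
  }
  attrs <- vapply(fields, `[`, "", 9)
  id <- stringr::str_match(attrs, "(?:^|;)\\s*(?:ID|gene_id)=([^;]+)")[, 2]
  if (any(is.na(id))) {
    stop("GFF3 line ", line_no[which(is.na(id))[1]],
         ": no ID= or gene_id= attribute", call. = FALSE)
  }
  tibble::tibble(
    gene_id = id,
    chrom = vapply(fields, `[`, "", 1),
    start = start - 1L,   # 1-based closed -> 0-based half-open
    end = end,
    strand = vapply(fields, `[`, "", 7)
  )
}

#' Write a gene catalog as BED6
#'
#' Inverse of [read_gene_table()] with `format = "bed"`; round-trips
#' coordinates and ids exactly.
#'
#' @param catalog A [gene_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(catalog, path) {
  g <- catalog$genes
  readr::write_tsv(
    tibble::tibble(chrom = g$chrom, start = g$start, end = g$end,
                   name = g$gene_id, score = 0L,
                   strand = ifelse(g$strand == "*", ".", g$strand)),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a BLAST tabular homology hit table (outfmt 6)
#'
#' Expects the standard 12 columns (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bitscore). Only query, subject, identity, e-value and
#' bitscore are retained; row order is preserved.
#'
#' @param path File path or connection.
#' @return A tibble with columns `query_id`, `subject_id`, `pct_identity`,
#'   `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          pct_identity = double(), evalue = double(),
                          bitscore = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 12)) {
    stop("hit table line ", which(n != 12)[1], ": expected 12 columns, got ",
         n[which(n != 12)[1]], call. = FALSE)
  }
  pick <- function(i) vapply(fields, `[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(pick(i)))
    if (any(is.na(v))) {
      stop("hit table line ", which(is.na(v))[1], ": non-numeric ", what,
           call. = FALSE)
    }
    v
  }
  tibble::tibble(
    query_id = pick(1), subject_id = pick(2),
    pct_identity = num(3, "identity"),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore")
  )
}

#' Read a gene-to-GO annotation table and extract a term's gene set
#'
#' Two-column TSV (`gene_id`, GO term), one term per row. Used to flag
#' mitonuclear genes via the mitochondrion cellular-component term
#' GO:0005739.
#'
#' @param path File path or connection.
#' @param mito_term GO term whose gene set is returned.
#' @return Character vector of unique gene ids carrying `mito_term`.
#' @export
read_go_annotations <- function(path, mito_term = "GO:0005739") {
  tab <- readr::read_tsv(path, col_names = c("gene_id", "go_term"),
                         col_types = "cc", progress = FALSE)
  unique(tab$gene_id[tab$go_term == mito_term])
}

#' Read an MCScanX collinearity file
#'
#' Parses the `.collinearity` text dialect: `## Alignment n: score=...
#' e_value=... N=... chrA&chrB plus|minus` headers followed by anchor-pair
#' rows. These blocks can stand in for the package's internal chaining when
#' users already have MCScanX output.
#'
#' @param path File path or connection.
#' @return A tibble with one row per alignment: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation` (`"same"`/`"inverted"`), `n_anchors`, and an
#'   `anchors` list-column of tibbles (`gene_a`, `gene_b`).
#' @export
read_collinearity <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- grepl("^## Alignment", lines)
  empty_blocks <- tibble::tibble(
    block_id = integer(), chrom_a = character(), chrom_b = character(),
    orientation = character(), n_anchors = integer(), anchors = list()
  )
  if (!any(hdr)) return(empty_blocks)
  starts <- which(hdr)
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2_dfr(starts, ends, function(s, e) {
    h <- lines[s]
    m <- stringr::str_match(h, "Alignment\\s+(\\d+):.*\\s(\\S+)&(\\S+)\\s+(plus|minus)")
    if (is.na(m[1, 1])) {
      stop("unparseable alignment header at line ", s, call. = FALSE)
    }
    body <- lines[seq(s + 1L, e)]
    body <- body[!grepl("^#", body) & nzchar(trimws(body))]
    parts <- strsplit(body, "\t", fixed = TRUE)
    # rows look like " 0-  0:\tgeneA\tgeneB\t  evalue"
    gene_a <- vapply(parts, `[`, "", 2)
    gene_b <- vapply(parts, `[`, "", 3)
    tibble::tibble(
      block_id = as.integer(m[1, 2]),
      chrom_a = m[1, 3], chrom_b = m[1, 4],
      orientation = ifelse(m[1, 5] == "minus", "inverted", "same"),
      n_anchors = length(gene_a),
      anchors = list(tibble::tibble(gene_a = gene_a, gene_b = gene_b))
    )
  })
}

#' Validate imported collinearity blocks against gene catalogs
#'
#' Drops anchors whose gene ids are absent from either catalog (with a
#' warning giving the count) and attaches ranks and bp spans so the blocks
#' are interchangeable with [chain_anchors()] output.
#'
#' @param blocks Output of [read_collinearity()].
#' @param catalog_a,catalog_b Gene catalogs of the two genomes.
#' @return Blocks in the [chain_anchors()] output format.
#' @export
validate_collinearity <- function(blocks, catalog_a, catalog_b) {
  ranked_a <- gene_ranks(catalog_a$genes)
  ranked_b <- gene_ranks(catalog_b$genes)
  dropped <- 0L
  out <- purrr::pmap_dfr(blocks, function(block_id, chrom_a, chrom_b,
                                          orientation, n_anchors, anchors) {
    a <- anchors |>
      dplyr::inner_join(
        dplyr::select(ranked_a, gene_a = "gene_id", start_a = "start",
                      end_a = "end", rank_a = "rank"),
        by = "gene_a") |>
      dplyr::inner_join(
        dplyr::select(ranked_b, gene_b = "gene_id", start_b = "start",
                      end_b = "end", rank_b = "rank"),
        by = "gene_b")
    dropped <<- dropped + (nrow(anchors) - nrow(a))
    if (nrow(a) == 0) return(NULL)
    tibble::tibble(
      block_id = block_id, chrom_a = chrom_a, chrom_b = chrom_b,
      orientation = orientation, n_anchors = nrow(a),
      start_a = min(a$start_a), end_a = max(a$end_a),
      start_b = min(a$start_b), end_b = max(a$end_b),
      anchors = list(a)
    )
  })
  if (dropped > 0) {
    warning(dropped, " anchor(s) dropped: gene id absent from catalogs",
            call. = FALSE)
  }
  out
}
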