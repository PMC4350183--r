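#' Turn ortholog pairs into synteny anchors
#'
#' Each ortholog pair becomes an anchor carrying the two genes' chromosomes,
#' coordinates, and 0-based gene-order ranks (position in the start-sorted
#' per-chromosome gene list). Ranks, not bp, drive chaining, matching how
#' collinearity detectors treat gene order.
#'
#' @param pairs Ortholog pairs (columns `gene_a`, `gene_b`), already
#'   restricted to placed genes.
#' @param catalog_a,catalog_b Gene catalogs.
#' @return A tibble with one row per anchor: `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `start_a`, `end_a`, `start_b`, `end_b`, `rank_a`, `rank_b`.
#' @export
anchors_from_orthologs <- function(pairs, catalog_a, catalog_b) {
  ranked_a <- gene_ranks(catalog_a$genes)
  ranked_b <- gene_ranks(catalog_b$genes)
  miss_a <- setdiff(pairs$gene_a, ranked_a$gene_id)
  miss_b <- setdiff(pairs$gene_b, ranked_b$gene_id)
  if (length(miss_a) + length(miss_b) > 0) {
    stop("gene(s) missing coordinates: ",
         paste(utils::head(c(miss_a, miss_b), 5), collapse = ", "),
         call. = FALSE)
  }
  unplaced <- c(
    intersect(pairs$gene_a, ranked_a$gene_id[!ranked_a$placed]),
    intersect(pairs$gene_b, ranked_b$gene_id[!ranked_b$placed])
  )
  if (length(unplaced) > 0) {
    stop("unplaced gene(s) reached anchoring: ",
         paste(utils::head(unplaced, 5), collapse = ", "), call. = FALSE)
  }
  pairs |>
    dplyr::select("gene_a", "gene_b") |>
    dplyr::inner_join(
      dplyr::select(ranked_a, gene_a = "gene_id", chrom_a = "chrom",
                    start_a = "start", end_a = "end", rank_a = "rank"),
      by = "gene_a") |>
    dplyr::inner_join(
      dplyr::select(ranked_b, gene_b = "gene_id", chrom_b = "chrom",
                    start_b = "start", end_b = "end", rank_b = "rank"),
      by = "gene_b") |>
    dplyr::arrange(.data$chrom_a, .data$rank_a)
}

# Longest gap-bounded strictly monotone chain among the given anchors.
# `dir` is +1 (rank_b increasing) or -1 (decreasing). Quadratic DP with
# backtracking; on ties the leftmost (smallest rank_a) predecessor wins so
# results are order-independent.
longest_chain <- function(ra, rb, dir, max_gap) {
  n <- length(ra)
  ord <- order(ra, rb * dir)
  ra <- ra[ord]; rb <- rb[ord]
  len <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)[-1]) {
    j <- seq_len(i - 1L)
    ok <- ra[j] < ra[i] & (ra[i] - ra[j]) <= max_gap &
      (rb[i] - rb[j]) * dir > 0 & abs(rb[i] - rb[j]) <= max_gap
    if (any(ok)) {
      cand <- j[ok]
      best <- max(len[cand])
      pick <- cand[len[cand] == best][1]
      len[i] <- best + 1L
      prev[i] <- pick
    }
  }
  best_len <- max(len)
  ends <- which(len == best_len)
  # prefer the chain starting leftmost on genome A
  chain_of <- function(e) {
    path <- integer(best_len)
    k <- best_len
    while (e != 0L) { path[k] <- e; k <- k - 1L; e <- prev[e] }
    path
  }
  chains <- lapply(ends, chain_of)
  starts <- vapply(chains, function(p) ra[p[1]], numeric(1))
  path <- chains[[which.min(starts)]]
  ord[path]
}

#' Chain synteny anchors into collinear blocks
#'
#' Within each chromosome pair, finds maximal runs of anchors strictly
#' monotone in both genomes' gene-order ranks — increasing/increasing
#' (`same` orientation) or increasing/decreasing (`inverted`) — with
#' consecutive anchors at most `max_gap_genes` apart in both rank
#' coordinates. Runs with at least `min_block_anchors` anchors become blocks.
#' Blocks are extracted greedily by descending anchor count (ties: leftmost
#' genome-A interval, then chromosome pair), and each anchor belongs to at
#' most one block. The defaults mirror the usual collinearity-detector
#' settings (at least 5 collinear genes, gaps of at most 25 genes).
#'
#' @param anchors Tibble from [anchors_from_orthologs()].
#' @param min_block_anchors Minimum anchors per block. Default 5.
#' @param max_gap_genes Maximum rank gap between consecutive anchors.
#'   Default 25.
#' @return A tibble of blocks: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, `start_a`, `end_a`, `start_b`, `end_b`, and
#'   an `anchors` list-column.
#' @export
chain_anchors <- function(anchors, min_block_anchors = 5, max_gap_genes = 25) {
  empty <- tibble::tibble(
    block_id = integer(), chrom_a = character(), chrom_b = character(),
    orientation = character(), n_anchors = integer(),
    start_a = double(), end_a = double(),
    start_b = double(), end_b = double(), anchors = list()
  )
  if (nrow(anchors) == 0) return(empty)
  groups <- anchors |>
    dplyr::group_by(.data$chrom_a, .data$chrom_b) |>
    dplyr::group_split()
  blocks <- purrr::map_dfr(groups, function(g) {
    out <- list()
    avail <- rep(TRUE, nrow(g))
    repeat {
      idx <- which(avail)
      if (length(idx) < min_block_anchors) break
      ra <- g$rank_a[idx]; rb <- g$rank_b[idx]
      fwd <- longest_chain(ra, rb, +1L, max_gap_genes)
      rev <- longest_chain(ra, rb, -1L, max_gap_genes)
      use_fwd <- length(fwd) >= length(rev)
      path <- idx[if (use_fwd) fwd else rev]
      if (length(path) < min_block_anchors) break
      members <- g[path, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom_a = g$chrom_a[1], chrom_b = g$chrom_b[1],
        orientation = if (use_fwd) "same" else "inverted",
        n_anchors = length(path),
        start_a = min(members$start_a), end_a = max(members$end_a),
        start_b = min(members$start_b), end_b = max(members$end_b),
        anchors = list(members)
      )
      avail[path] <- FALSE
    }
    dplyr::bind_rows(out)
  })
  if (nrow(blocks) == 0) return(empty)
  blocks |>
    dplyr::arrange(dplyr::desc(.data$n_anchors), .data$start_a,
                   .data$chrom_a, .data$chrom_b) |>
    dplyr::mutate(block_id = dplyr::row_number(), .before = 1)
}

interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Merge nearby synteny blocks into larger syntenic regions
#'
#' Blocks on the same chromosome pair are sorted along genome A and merged
#' transitively whenever consecutive blocks are closer than `merge_distance`
#' on *both* genomes (gap between the genome-A intervals and gap between the
#' genome-B hulls both below the threshold). The two-genome gate prevents a
#' chimeric region from joining blocks that are adjacent on one genome but
#' far apart on the other. Region intervals are the hulls of their member
#' blocks. The 10 Mb default reflects the scale over which chromosome
#' rearrangement fragments a conserved region into separate alignments.
#'
#' @param blocks Block tibble from [chain_anchors()] or
#'   [validate_collinearity()].
#' @param merge_distance Maximum gap (bp, exclusive) for merging.
#'   Default 1e7.
#' @return A tibble of merged regions: `region_id`, `chrom_a`, `chrom_b`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `n_blocks`, `n_anchors`, and a
#'   `block_ids` list-column.
#' @export
merge_blocks <- function(blocks, merge_distance = 1e7) {
  empty <- tibble::tibble(
    region_id = integer(), chrom_a = character(), chrom_b = character(),
    start_a = double(), end_a = double(), start_b = double(),
    end_b = double(), n_blocks = integer(), n_anchors = integer(),
    block_ids = list()
  )
  if (nrow(blocks) == 0) return(empty)
  regions <- blocks |>
    dplyr::group_by(.data$chrom_a, .data$chrom_b) |>
    dplyr::group_split() |>
    purrr::map_dfr(function(g) {
      g <- dplyr::arrange(g, .data$start_a)
      cur <- g[1, ]
      ids <- list(cur$block_id)
      out <- list()
      flush <- function(cur, ids) {
        tibble::tibble(
          chrom_a = cur$chrom_a, chrom_b = cur$chrom_b,
          start_a = cur$start_a, end_a = cur$end_a,
          start_b = cur$start_b, end_b = cur$end_b,
          n_blocks = length(ids[[1]]), n_anchors = cur$n_anchors,
          block_ids = ids
        )
      }
      for (i in seq_len(nrow(g))[-1]) {
        nxt <- g[i, ]
        gap_a <- interval_gap(cur$start_a, cur$end_a, nxt$start_a, nxt$end_a)
        gap_b <- interval_gap(cur$start_b, cur$end_b, nxt$start_b, nxt$end_b)
        if (gap_a < merge_distance && gap_b < merge_distance) {
          cur$start_a <- min(cur$start_a, nxt$start_a)
          cur$end_a <- max(cur$end_a, nxt$end_a)
          cur$start_b <- min(cur$start_b, nxt$start_b)
          cur$end_b <- max(cur$end_b, nxt$end_b)
          cur$n_anchors <- cur$n_anchors + nxt$n_anchors
          ids[[1]] <- c(ids[[1]], nxt$block_id)
        } else {
          out[[length(out) + 1L]] <- flush(cur, ids)
          cur <- nxt
          ids <- list(nxt$block_id)
        }
      }
      out[[length(out) + 1L]] <- flush(cur, ids)
      dplyr::bind_rows(out)
    })
  regions |>
    dplyr::arrange(.data$chrom_a, .data$start_a, .data$chrom_b) |>
    dplyr::mutate(region_id = dplyr::row_number(), .before = 1)
}

#' Regions syntenic to a focal chromosome
#'
#' Extracts the merged regions lying on a focal genome-A chromosome (for a
#' human-centred analysis, the X) together with their genome-B intervals —
#' the focal-syntenic map, a proxy for the ancestral chromosome(s) the focal
#' chromosome derives from. The fraction of the focal chromosome covered by
#' the union of the regions' genome-A intervals is attached as the
#' `"coverage"` attribute and returned by [synteny_coverage()].
#'
#' @param regions Merged regions from [merge_blocks()].
#' @param focal_chrom_a Name of the focal chromosome in genome A.
#' @param catalog_a Genome-A catalog (for the chromosome length).
#' @return The focal regions tibble, with attribute `coverage`.
#' @export
focal_syntenic_regions <- function(regions, focal_chrom_a, catalog_a) {
  len <- catalog_a$chrom_lengths$length[
    catalog_a$chrom_lengths$chrom == focal_chrom_a]
  if (length(len) != 1) {
    stop("focal chromosome '", focal_chrom_a, "' absent from catalog",
         call. = FALSE)
  }
  focal <- dplyr::filter(regions, .data$chrom_a == focal_chrom_a)
  cov <- if (nrow(focal) == 0) 0 else {
    iv <- dplyr::arrange(focal, .data$start_a)
    covered <- 0
    lo <- iv$start_a[1]; hi <- iv$end_a[1]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start_a[i] > hi) {
        covered <- covered + (hi - lo)
        lo <- iv$start_a[i]; hi <- iv$end_a[i]
      } else {
        hi <- max(hi, iv$end_a[i])
      }
    }
    covered <- covered + (hi - lo)
    min(1, covered / len)
  }
  attr(focal, "coverage") <- cov
  focal
}

#' Coverage fraction recorded on a focal-regions tibble
#' @param focal Output of [focal_syntenic_regions()].
#' @return Fraction of the focal chromosome covered, in `[0, 1]`.
#' @export
synteny_coverage <- function(focal) {
  cov <- attr(focal, "coverage", exact = TRUE)
  if (is.null(cov)) stop("no coverage attribute; use focal_syntenic_regions()",
                         call. = FALSE)
  cov
}
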