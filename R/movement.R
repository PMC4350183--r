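#' Classify ortholog pairs as retained or moved
#'
#' A pair is *retained* when it is an anchor of a synteny block, or when both
#' genes' midpoints fall inside the corresponding intervals of one merged
#' region. Every other pair is a candidate interchromosomal *movement*,
#' categorised by where it came from in genome B and where it sits in genome
#' A relative to the focal chromosome: source inside a focal-syntenic region
#' of genome B is X-origin, destination on the focal genome-A chromosome is
#' X-destination, giving the categories `X->A`, `A->X` and `A->A`.
#'
#' Moved pairs whose genome-B gene sits on a sequence that only *partly*
#' overlaps a focal-syntenic region (a contig straddling the region boundary)
#' are flagged `ambiguous`: their origin call depends on where the boundary
#' is drawn, so downstream tallies are reported both with (strict) and
#' without (lenient) them.
#'
#' @param pairs Ortholog pairs restricted to placed genes; normally already
#'   subset to the gene class of interest (e.g. mitonuclear pairs).
#' @param regions Merged regions from [merge_blocks()].
#' @param catalog_a,catalog_b Gene catalogs.
#' @param focal_chrom_a Focal chromosome name in genome A.
#' @param blocks Optional block tibble; anchors of any block are retained
#'   regardless of region intervals.
#' @return Per-pair tibble with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `status` (`"retained"`/`"moved"`), `category` (`"X->A"`,
#'   `"A->X"`, `"A->A"`, or `NA` for retained pairs) and `ambiguous`.
#' @export
classify_movements <- function(pairs, regions, catalog_a, catalog_b,
                               focal_chrom_a, blocks = NULL) {
  ga <- catalog_a$genes
  gb <- catalog_b$genes
  df <- pairs |>
    dplyr::select("gene_a", "gene_b") |>
    dplyr::inner_join(
      dplyr::transmute(ga, gene_a = .data$gene_id, chrom_a = .data$chrom,
                       mid_a = (.data$start + .data$end) / 2),
      by = "gene_a") |>
    dplyr::inner_join(
      dplyr::transmute(gb, gene_b = .data$gene_id, chrom_b = .data$chrom,
                       mid_b = (.data$start + .data$end) / 2),
      by = "gene_b")

  in_region <- function(chrom_a, mid_a, chrom_b, mid_b) {
    if (nrow(regions) == 0) return(rep(FALSE, length(mid_a)))
    vapply(seq_along(mid_a), function(i) {
      any(regions$chrom_a == chrom_a[i] & regions$chrom_b == chrom_b[i] &
            regions$start_a <= mid_a[i] & mid_a[i] < regions$end_a &
            regions$start_b <= mid_b[i] & mid_b[i] < regions$end_b)
    }, logical(1))
  }
  retained <- in_region(df$chrom_a, df$mid_a, df$chrom_b, df$mid_b)
  if (!is.null(blocks) && nrow(blocks) > 0) {
    anchor_pairs <- purrr::map_dfr(blocks$anchors, ~ .x[, c("gene_a", "gene_b")])
    key <- paste(df$gene_a, df$gene_b)
    retained <- retained | key %in% paste(anchor_pairs$gene_a,
                                          anchor_pairs$gene_b)
  }

  focal <- dplyr::filter(regions, .data$chrom_a == focal_chrom_a)
  src_x <- rep(FALSE, nrow(df))
  partial <- character(0)
  if (nrow(focal) > 0) {
    src_x <- vapply(seq_len(nrow(df)), function(i) {
      any(focal$chrom_b == df$chrom_b[i] &
            focal$start_b <= df$mid_b[i] & df$mid_b[i] < focal$end_b)
    }, logical(1))
    # genome-B sequences only partly inside a focal region
    blens <- catalog_b$chrom_lengths
    focal_hull <- focal |>
      dplyr::group_by(.data$chrom_b) |>
      dplyr::summarise(cov = sum(.data$end_b - .data$start_b),
                       .groups = "drop") |>
      dplyr::inner_join(blens, by = c(chrom_b = "chrom"))
    partial <- focal_hull$chrom_b[focal_hull$cov < 0.9 * focal_hull$length]
  }
  dest_x <- df$chrom_a == focal_chrom_a
  category <- dplyr::case_when(
    retained ~ NA_character_,
    src_x & !dest_x ~ "X->A",
    !src_x & dest_x ~ "A->X",
    TRUE ~ "A->A"
  )
  tibble::tibble(
    gene_a = df$gene_a, gene_b = df$gene_b,
    chrom_a = df$chrom_a, chrom_b = df$chrom_b,
    status = ifelse(retained, "retained", "moved"),
    category = category,
    ambiguous = !retained & !src_x & df$chrom_b %in% partial
  )
}

#' Expected movement counts under the size-based null
#'
#' Under the null, a movement's source chromosome is drawn in proportion to
#' gene content and its destination in proportion to assembly length:
#' `P(source = X)` is the fraction of classified genome-B ortholog genes
#' lying in focal-syntenic regions, and `P(target = X)` is the fraction of
#' genome-A assembly bp on the focal chromosome. The total observed movement
#' count is redistributed over the source/destination categories; the
#' (rarely populated) X-to-X cell is reported separately and its mass
#' rescaled proportionally into the three tabulated categories so expected
#' counts sum to the observed total.
#'
#' @param p_source_x Probability the source is focal-syntenic.
#' @param p_target_x Probability the target is the focal chromosome.
#' @param total Total observed movements.
#' @return A list with `expected` (named numeric: `X->A`, `A->X`, `A->A`),
#'   `x_to_x` (the excluded cell before rescaling) and the two probabilities.
#' @export
expected_movements <- function(p_source_x, p_target_x, total) {
  stopifnot(p_source_x >= 0, p_source_x <= 1,
            p_target_x >= 0, p_target_x <= 1, total >= 0)
  raw <- c(
    "X->A" = p_source_x * (1 - p_target_x),
    "A->X" = (1 - p_source_x) * p_target_x,
    "A->A" = (1 - p_source_x) * (1 - p_target_x)
  )
  xx <- p_source_x * p_target_x
  scale <- if (sum(raw) > 0) total / sum(raw) else 0
  list(expected = raw * scale, x_to_x = total * xx,
       p_source_x = p_source_x, p_target_x = p_target_x)
}

#' Exact Freeman-Halton test for a 2x3 observed-vs-expected table
#'
#' Enumerates every 2x3 contingency table with the margins of
#' `rbind(observed, expected)` and sums the hypergeometric probabilities of
#' all tables at most as probable as the observed one (within relative
#' tolerance `1e-7`), giving a two-sided exact p-value. Expected counts must
#' be rounded to integers by the caller first — an exact test is only defined
#' on integer tables.
#'
#' @param observed,expected Integer vectors of length 3 (movement counts per
#'   category).
#' @return The exact two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x3(c(0, 4, 132), c(2, 4, 130))
fisher_exact_2x3 <- function(observed, expected) {
  if (length(observed) != 3 || length(expected) != 3) {
    stop("observed and expected must each have 3 categories", call. = FALSE)
  }
  if (any(observed != round(observed)) || any(expected != round(expected))) {
    stop("counts must be integers; round the expected counts first",
         call. = FALSE)
  }
  obs <- as.integer(observed); exp_ <- as.integer(expected)
  if (any(obs < 0) || any(exp_ < 0)) stop("counts must be non-negative",
                                          call. = FALSE)
  r1 <- sum(obs); r2 <- sum(exp_)
  cols <- obs + exp_
  n <- r1 + r2
  if (r1 == 0 || r2 == 0) return(1)
  # log-probability of a table with first row (a, b, c), margins fixed
  ltab <- function(a, b, c) {
    lchoose(cols[1], a) + lchoose(cols[2], b) + lchoose(cols[3], c) -
      lchoose(n, r1)
  }
  lp_obs <- ltab(obs[1], obs[2], obs[3])
  p <- 0
  for (a in 0:min(r1, cols[1])) {
    b <- 0:min(r1 - a, cols[2])
    cc <- r1 - a - b
    ok <- cc >= 0 & cc <= cols[3]
    if (!any(ok)) next
    lp <- ltab(a, b[ok], cc[ok])
    p <- p + sum(exp(lp[lp <= lp_obs + 1e-7]))
  }
  min(1, p)
}

#' Test observed gene movements against the size-based null
#'
#' Runs the full movement analysis for one gene class: classifies each
#' ortholog pair as retained or moved ([classify_movements()]), computes the
#' expected distribution of movements over `X->A` / `A->X` / `A->A` under
#' the size-based null ([expected_movements()]), and compares observed with
#' expected (rounded to integers) by the exact Freeman-Halton test. A
#' lenient tally excluding boundary-ambiguous movements is computed
#' alongside the strict one.
#'
#' @param pairs Ortholog pairs for the gene class of interest (e.g.
#'   mitonuclear pairs), restricted to placed genes.
#' @param regions Merged regions from [merge_blocks()].
#' @param catalog_a,catalog_b Gene catalogs.
#' @param focal_chrom_a Focal chromosome in genome A.
#' @param blocks Optional blocks for anchor-based retention.
#' @param source_pairs Pairs used to estimate `P(source = X)` — by default
#'   the classified `pairs` themselves; pass the full ortholog map to weight
#'   sources by all classified orthologs instead.
#' @return An object of class `synmito_movement` with elements `counts`
#'   (tibble: category, observed, expected, expected_raw), `n_retained`,
#'   `p_value`, `counts_lenient`, `p_value_lenient`, `x_to_x_expected`,
#'   `p_source_x`, `p_target_x` and the per-pair `classification`.
#' @export
movement_test <- function(pairs, regions, catalog_a, catalog_b,
                          focal_chrom_a, blocks = NULL, source_pairs = NULL) {
  cls <- classify_movements(pairs, regions, catalog_a, catalog_b,
                            focal_chrom_a, blocks = blocks)
  if (is.null(source_pairs)) source_pairs <- pairs
  focal <- dplyr::filter(regions, .data$chrom_a == focal_chrom_a)
  gb <- catalog_b$genes
  src <- dplyr::inner_join(
    dplyr::select(source_pairs, "gene_b"),
    dplyr::transmute(gb, gene_b = .data$gene_id, chrom_b = .data$chrom,
                     mid_b = (.data$start + .data$end) / 2),
    by = "gene_b")
  in_focal_b <- if (nrow(focal) == 0) rep(FALSE, nrow(src)) else {
    vapply(seq_len(nrow(src)), function(i) {
      any(focal$chrom_b == src$chrom_b[i] &
            focal$start_b <= src$mid_b[i] & src$mid_b[i] < focal$end_b)
    }, logical(1))
  }
  p_src <- if (nrow(src) == 0) 0 else mean(in_focal_b)
  lens <- catalog_a$chrom_lengths
  p_tgt <- sum(lens$length[lens$chrom == focal_chrom_a]) / sum(lens$length)

  tally <- function(d) {
    moved <- d[d$status == "moved", ]
    obs <- vapply(c("X->A", "A->X", "A->A"),
                  function(k) sum(moved$category == k), integer(1))
    total <- sum(obs)
    ex <- expected_movements(p_src, p_tgt, total)
    exp_int <- round(ex$expected)
    p <- if (total == 0) 1 else fisher_exact_2x3(obs, exp_int)
    list(counts = tibble::tibble(
      category = names(obs), observed = unname(obs),
      expected = unname(exp_int), expected_raw = unname(ex$expected)),
      p = p, x_to_x = ex$x_to_x)
  }
  strict <- tally(cls)
  lenient <- tally(dplyr::filter(cls, !.data$ambiguous))
  structure(
    list(counts = strict$counts, n_retained = sum(cls$status == "retained"),
         p_value = strict$p, counts_lenient = lenient$counts,
         p_value_lenient = lenient$p, x_to_x_expected = strict$x_to_x,
         p_source_x = p_src, p_target_x = p_tgt, classification = cls),
    class = "synmito_movement"
  )
}

#' @export
print.synmito_movement <- function(x, ...) {
  cat("Gene movement vs size-based null\n")
  cat("  retained in synteny:", x$n_retained, "\n")
  df <- as.data.frame(x$counts[, c("category", "observed", "expected")])
  print(df, row.names = FALSE)
  cat(sprintf("  Freeman-Halton exact P = %.3f (lenient: %.3f)\n",
              x$p_value, x$p_value_lenient))
  invisible(x)
}

#' @rdname movement_test
#' @param x A `synmito_movement` object.
#' @param ... Unused.
#' @export
tidy.synmito_movement <- function(x, ...) {
  x$counts
}

#' @rdname movement_test
#' @export
glance.synmito_movement <- function(x, ...) {
  tibble::tibble(
    n_moved = sum(x$counts$observed), n_retained = x$n_retained,
    p_value = x$p_value, p_value_lenient = x$p_value_lenient,
    p_source_x = x$p_source_x, p_target_x = x$p_target_x
  )
}

#' Plot observed vs expected movement counts
#'
#' @param object A `synmito_movement` object.
#' @param ... Unused.
#' @return A ggplot: paired bars of observed and expected counts per
#'   movement category.
#' @export
autoplot.synmito_movement <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$counts[, c("category", "observed", "expected")],
    c("observed", "expected"), names_to = "which", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "movement category", y = "genes", fill = NULL,
                  subtitle = sprintf("exact P = %.3f", object$p_value)) +
    ggplot2::theme_minimal()
}
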