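#' Mitonuclear gene-density bias of a region
#'
#' The bias of a region is the observed mitonuclear gene count divided by the
#' count expected if mt-N genes were spread uniformly over genes:
#' `expected = (n_genes / total_genes) * total_mtn`, `bias = n_mtn /
#' expected`. Bias below 1 means under-representation.
#'
#' @param n_mtn Observed mt-N genes in the region.
#' @param n_genes Total genes in the region (must be positive).
#' @param total_mtn Genome-wide mt-N gene count.
#' @param total_genes Genome-wide gene count.
#' @return A list with `expected_mtn` and `bias`.
#' @export
#' @examples
#' mtn_bias(4, 100, 50, 1000)  # expected 5, bias 0.8
mtn_bias <- function(n_mtn, n_genes, total_mtn, total_genes) {
  stopifnot(total_genes > 0, total_mtn > 0, n_mtn >= 0, n_mtn <= n_genes)
  if (n_genes == 0) stop("bias undefined for an empty region", call. = FALSE)
  expected <- (n_genes / total_genes) * total_mtn
  list(expected_mtn = expected, bias = n_mtn / expected)
}

#' Percentile bootstrap CI for a region's bias
#'
#' Resamples the region's genes with replacement, recomputing the bias each
#' iteration with the genome totals held fixed, and returns percentile
#' bounds. Deterministic for a given seed.
#'
#' @param flags Logical vector: the region's genes' mt-N flags.
#' @param total_mtn,total_genes Genome-wide totals.
#' @param n_boot Bootstrap iterations. Default 10000.
#' @param seed Optional integer seed.
#' @param level Confidence level. Default 0.95.
#' @return A list with `ci_low`, `ci_high` and the bootstrap `replicates`.
#' @export
bootstrap_bias_ci <- function(flags, total_mtn, total_genes, n_boot = 10000,
                              seed = NULL, level = 0.95) {
  stopifnot(is.logical(flags), n_boot >= 1, level > 0, level < 1)
  if (length(flags) == 0) stop("region has no genes", call. = FALSE)
  n <- length(flags)
  expected <- (n / total_genes) * total_mtn
  reps <- with_seed(seed, {
    draws <- matrix(sample(flags, n * n_boot, replace = TRUE), nrow = n)
    colSums(draws) / expected
  })
  qs <- stats::quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], replicates = reps)
}

#' Bias of a gene region with bootstrap CI
#'
#' Convenience wrapper producing a `synmito_bias` result from a region's
#' flags and genome totals.
#'
#' @inheritParams bootstrap_bias_ci
#' @param label Region label carried into reports.
#' @return An object of class `synmito_bias` (also a one-row tibble via
#'   [tidy.synmito_bias()]).
#' @export
bias_test <- function(flags, total_mtn, total_genes, n_boot = 10000,
                      seed = NULL, level = 0.95, label = "region") {
  b <- mtn_bias(sum(flags), length(flags), total_mtn, total_genes)
  ci <- bootstrap_bias_ci(flags, total_mtn, total_genes, n_boot = n_boot,
                          seed = seed, level = level)
  structure(
    list(region_label = label, n_mtn = sum(flags), n_genes = length(flags),
         total_mtn = total_mtn, total_genes = total_genes,
         expected_mtn = b$expected_mtn, bias = b$bias,
         ci_low = ci$ci_low, ci_high = ci$ci_high,
         n_boot = n_boot, seed = seed, level = level),
    class = "synmito_bias"
  )
}

#' @export
print.synmito_bias <- function(x, ...) {
  cat(sprintf(
    "mt-N bias of %s: %d mt-N / %d genes; expected %.1f; bias %.2f (%.0f%% CI %.2f-%.2f)\n",
    x$region_label, x$n_mtn, x$n_genes, x$expected_mtn, x$bias,
    100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' @rdname bias_test
#' @param x A `synmito_bias` object.
#' @param ... Unused.
#' @export
tidy.synmito_bias <- function(x, ...) {
  tibble::tibble(
    region = x$region_label, n_mtn = x$n_mtn, n_genes = x$n_genes,
    expected_mtn = x$expected_mtn, bias = x$bias,
    ci_low = x$ci_low, ci_high = x$ci_high
  )
}

#' @rdname bias_test
#' @export
glance.synmito_bias <- function(x, ...) {
  tibble::tibble(bias = x$bias, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_boot = x$n_boot, level = x$level)
}

#' Plot bias estimates with their confidence intervals
#'
#' @param object A `synmito_bias` object or a tibble of tidied bias rows.
#' @param ... Further `synmito_bias` objects to include.
#' @return A ggplot: point estimates with CI error bars per region, with a
#'   reference line at bias 1.
#' @export
autoplot.synmito_bias <- function(object, ...) {
  extra <- list(...)
  rows <- dplyr::bind_rows(c(list(tidy(object)),
                             purrr::map(extra, tidy)))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$region, y = .data$bias)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "mt-N bias (obs / expected)") +
    ggplot2::theme_minimal()
}

#' Exact 2x2 test comparing two regions' observed vs expected mt-N counts
#'
#' Rows are the two regions, columns are observed and (integer-rounded)
#' expected mt-N counts; the two-tailed exact p-value comes from the
#' hypergeometric distribution over tables with those margins.
#'
#' @param n_mtn_1,expected_1 Observed and expected counts for region 1
#'   (expected rounded to an integer).
#' @param n_mtn_2,expected_2 The same for region 2.
#' @return The two-tailed exact p-value.
#' @export
region_fisher <- function(n_mtn_1, expected_1, n_mtn_2, expected_2) {
  vals <- c(n_mtn_1, expected_1, n_mtn_2, expected_2)
  if (any(vals != round(vals))) {
    stop("counts must be integers; round expected counts first",
         call. = FALSE)
  }
  if (any(vals < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(vals) == 0) return(1)
  m <- matrix(as.integer(round(vals)), nrow = 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Exact two-tailed sign test
#'
#' Tests whether `n_under` under-representation outcomes among `n_total`
#' independent trials deviate from a fair coin:
#' `p = 2 * min(P(K <= n_under), P(K >= n_under))` with
#' `K ~ Binomial(n_total, 1/2)`, capped at 1.
#'
#' @param n_under Number of trials in the direction of interest.
#' @param n_total Total trials (positive).
#' @return The exact two-tailed p-value.
#' @export
#' @examples
#' sign_test(5, 7)  # 0.453125
sign_test <- function(n_under, n_total) {
  stopifnot(n_under >= 0, n_under <= n_total)
  if (n_total == 0) stop("sign test undefined for zero trials", call. = FALSE)
  lo <- stats::pbinom(n_under, n_total, 0.5)
  hi <- stats::pbinom(n_under - 1, n_total, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Per-region mt-N bias table over a catalog
#'
#' Computes the bias (with bootstrap CI) of each listed region of a genome:
#' a region is either a whole chromosome (`chrom`) or an explicit interval
#' (`chrom`, `start`, `end`; gene membership by midpoint). Totals default to
#' the whole catalog.
#'
#' @param catalog A [gene_catalog()] with `is_mtn` flags set.
#' @param regions Tibble with columns `region` (label), `chrom`, and
#'   optionally `start`/`end` (bp; whole chromosome when absent or `NA`).
#' @param n_boot,seed,level Bootstrap settings; see [bootstrap_bias_ci()].
#' @param total_mtn,total_genes Genome totals; default to the catalog's.
#' @return A tibble with one row per region (Table-style: region, n_mtn,
#'   n_genes, expected_mtn, bias, ci_low, ci_high).
#' @export
region_bias_table <- function(catalog, regions, n_boot = 10000, seed = NULL,
                              level = 0.95, total_mtn = NULL,
                              total_genes = NULL) {
  g <- catalog$genes
  if (is.null(total_mtn)) total_mtn <- sum(g$is_mtn)
  if (is.null(total_genes)) total_genes <- nrow(g)
  mid <- (g$start + g$end) / 2
  purrr::pmap_dfr(
    tibble::as_tibble(regions),
    function(region, chrom, start = NA, end = NA, ...) {
      sel <- g$chrom == chrom
      if (!is.na(start) && !is.na(end)) {
        sel <- sel & mid >= start & mid < end
      }
      flags <- g$is_mtn[sel]
      if (length(flags) == 0) {
        stop("region '", region, "' contains no genes", call. = FALSE)
      }
      tidy(bias_test(flags, total_mtn, total_genes, n_boot = n_boot,
                     seed = seed, level = level, label = region))
    })
}

#' Overlap fraction between two mitonuclear flag sets
#'
#' When mt-N status can be assigned two ways (orthology-projected vs
#' species-specific annotation), reports the fraction of the union of the
#' two gene sets on which they agree.
#'
#' @param ids_1,ids_2 Character vectors of flagged gene ids.
#' @return Jaccard overlap fraction in `[0, 1]` (1 when both are empty).
#' @export
flag_overlap <- function(ids_1, ids_2) {
  u <- union(ids_1, ids_2)
  if (length(u) == 0) return(1)
  length(intersect(ids_1, ids_2)) / length(u)
}
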