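#' Run the full synteny-based mitonuclear movement and abundance analysis
#'
#' Orchestrates the pipeline for one genome pair: reciprocal-best-hit
#' orthology, restriction to placed genes, anchor chaining into collinear
#' blocks, block merging into syntenic regions, extraction of the
#' focal-syntenic map, classification of mitonuclear gene movements against
#' the size-based null with the exact Freeman-Halton test, and bias (with
#' bootstrap CI) of the focal chromosome and its syntenic counterpart.
#'
#' Mitonuclear status of genome-B genes is taken from genome-A flags
#' projected through the ortholog map (`mtn_mode = "orthology"`, the
#' default) or from genome B's own annotation flags (`"annotation"`).
#'
#' @param catalog_a,catalog_b Gene catalogs; genome A carries the focal
#'   chromosome and the authoritative mt-N flags.
#' @param hits_ab,hits_ba Homology hit tables for the two directions.
#' @param focal_chrom_a Focal chromosome name in genome A.
#' @param max_evalue,min_identity rBBH thresholds; see
#'   [reciprocal_best_hits()].
#' @param min_block_anchors,max_gap_genes Chaining parameters; see
#'   [chain_anchors()].
#' @param merge_distance Region merge threshold (bp); see [merge_blocks()].
#' @param n_boot,seed Bootstrap settings for the bias CIs.
#' @param mtn_mode How genome-B mt-N flags are assigned.
#' @return An object of class `synmito_run`: list with `orthologs`,
#'   `anchors`, `blocks`, `regions`, `focal_regions`, `coverage`,
#'   `movement` (a `synmito_movement`), `bias` (tibble of `synmito_bias`
#'   rows for the focal chromosome and the focal-syntenic regions), and
#'   `params`.
#' @export
run_synmito <- function(catalog_a, catalog_b, hits_ab, hits_ba,
                        focal_chrom_a, max_evalue = 1e-10, min_identity = 30,
                        min_block_anchors = 5, max_gap_genes = 25,
                        merge_distance = 1e7, n_boot = 10000, seed = NULL,
                        mtn_mode = c("orthology", "annotation")) {
  mtn_mode <- match.arg(mtn_mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  orthologs <- stage("orthology",
    reciprocal_best_hits(hits_ab, hits_ba, max_evalue = max_evalue,
                         min_identity = min_identity))
  placed <- stage("orthology",
    restrict_to_placed(orthologs, catalog_a, catalog_b, quiet = TRUE))
  anchors <- stage("synteny", anchors_from_orthologs(placed, catalog_a,
                                                     catalog_b))
  blocks <- stage("synteny",
    chain_anchors(anchors, min_block_anchors = min_block_anchors,
                  max_gap_genes = max_gap_genes))
  regions <- stage("synteny", merge_blocks(blocks,
                                           merge_distance = merge_distance))
  focal <- stage("synteny", focal_syntenic_regions(regions, focal_chrom_a,
                                                   catalog_a))
  mtn_a <- catalog_a$genes$gene_id[catalog_a$genes$is_mtn]
  mtn_pairs <- dplyr::filter(placed, .data$gene_a %in% mtn_a)
  movement <- stage("movement",
    movement_test(mtn_pairs, regions, catalog_a, catalog_b, focal_chrom_a,
                  blocks = blocks, source_pairs = placed))

  bias <- stage("abundance", {
    ga <- catalog_a$genes
    flags_a <- ga$is_mtn[ga$chrom == focal_chrom_a]
    rows <- list()
    if (length(flags_a) > 0) {
      rows$a <- tidy(bias_test(
        flags_a, total_mtn = sum(ga$is_mtn), total_genes = nrow(ga),
        n_boot = n_boot, seed = seed,
        label = paste0(catalog_a$genome_label, ":", focal_chrom_a)))
    }
    gb <- catalog_b$genes
    is_mtn_b <- if (mtn_mode == "annotation") gb$is_mtn else
      gb$gene_id %in% placed$gene_b[placed$gene_a %in% mtn_a]
    if (nrow(focal) > 0) {
      mid_b <- (gb$start + gb$end) / 2
      in_focal <- vapply(seq_len(nrow(gb)), function(i) {
        any(focal$chrom_b == gb$chrom[i] &
              focal$start_b <= mid_b[i] & mid_b[i] < focal$end_b)
      }, logical(1))
      if (any(in_focal)) {
        rows$b <- tidy(bias_test(
          is_mtn_b[in_focal], total_mtn = sum(is_mtn_b),
          total_genes = nrow(gb), n_boot = n_boot, seed = seed,
          label = paste0(catalog_b$genome_label, ":focal-syntenic")))
      }
    }
    dplyr::bind_rows(rows)
  })

  structure(
    list(orthologs = orthologs, orthologs_placed = placed, anchors = anchors,
         blocks = blocks, regions = regions, focal_regions = focal,
         coverage = synteny_coverage(focal), movement = movement,
         bias = bias,
         params = list(focal_chrom_a = focal_chrom_a,
                       max_evalue = max_evalue, min_identity = min_identity,
                       min_block_anchors = min_block_anchors,
                       max_gap_genes = max_gap_genes,
                       merge_distance = merge_distance, n_boot = n_boot,
                       seed = seed, mtn_mode = mtn_mode)),
    class = "synmito_run"
  )
}

#' @export
print.synmito_run <- function(x, ...) {
  cat("<synmito_run> focal =", x$params$focal_chrom_a, "\n")
  cat("  orthologs:", nrow(x$orthologs), "(", nrow(x$orthologs_placed),
      "placed )\n")
  cat("  blocks:", nrow(x$blocks), "-> regions:", nrow(x$regions),
      "; focal regions:", nrow(x$focal_regions),
      sprintf("(coverage %.2f)\n", x$coverage))
  print(x$movement)
  if (nrow(x$bias) > 0) print(as.data.frame(x$bias), row.names = FALSE)
  invisible(x)
}

#' @rdname run_synmito
#' @param x A `synmito_run` object.
#' @param ... Unused.
#' @export
glance.synmito_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_orthologs = nrow(x$orthologs),
                   n_placed = nrow(x$orthologs_placed),
                   n_blocks = nrow(x$blocks), n_regions = nrow(x$regions),
                   coverage = x$coverage),
    glance(x$movement)
  )
}

#' Run the pipeline from input files
#'
#' Reads the gene tables, chromosome lengths, hit tables and GO annotation
#' from disk (the formats written by [write_sim_inputs()] or produced by
#' standard tools) and calls [run_synmito()].
#'
#' @param genes_a,genes_b Paths to BED (or GFF3) gene tables.
#' @param lengths_a,lengths_b Paths to chromosome length TSVs.
#' @param hits_ab,hits_ba Paths to 12-column tabular hit tables.
#' @param mtn_path Path to the gene-to-GO annotation TSV.
#' @param focal_chrom_a Focal chromosome in genome A.
#' @param format Gene table format.
#' @param placed_pattern_b Regex for placed sequences in genome B.
#' @param ... Passed on to [run_synmito()].
#' @return A `synmito_run`.
#' @export
run_synmito_files <- function(genes_a, lengths_a, genes_b, lengths_b,
                              hits_ab, hits_ba, mtn_path, focal_chrom_a,
                              format = "bed", placed_pattern_b = NULL, ...) {
  for (p in c(genes_a, lengths_a, genes_b, lengths_b, hits_ab, hits_ba,
              mtn_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  mtn_ids <- read_go_annotations(mtn_path)
  cat_a <- read_gene_table(genes_a, format, lengths_a, genome_label = "A",
                           mtn_ids = mtn_ids)
  cat_b <- read_gene_table(genes_b, format, lengths_b, genome_label = "B",
                           placed_pattern = placed_pattern_b)
  run_synmito(cat_a, cat_b, read_hit_table(hits_ab), read_hit_table(hits_ba),
              focal_chrom_a, ...)
}

#' Write the pipeline report bundle
#'
#' Writes `regions.tsv` (all merged regions), `movement.tsv` (observed vs
#' expected movement counts, strict and lenient), `bias.tsv`, and `run.log`
#' (parameters, stage tallies and p-values). Output is byte-identical across
#' runs with the same inputs and seed.
#'
#' @param run A `synmito_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(
    dplyr::select(run$regions, "region_id", "chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b", "n_blocks", "n_anchors"),
    file.path(dir, "regions.tsv"), progress = FALSE)
  mv <- dplyr::bind_rows(
    dplyr::mutate(run$movement$counts, tally = "strict"),
    dplyr::mutate(run$movement$counts_lenient, tally = "lenient"))
  readr::write_tsv(mv, file.path(dir, "movement.tsv"), progress = FALSE)
  readr::write_tsv(run$bias, file.path(dir, "bias.tsv"), progress = FALSE)
  p <- run$params
  log_lines <- c(
    paste0("synmito ", as.character(utils::packageVersion("synmito"))),
    paste0("focal_chrom_a=", p$focal_chrom_a),
    paste0("max_evalue=", p$max_evalue),
    paste0("min_identity=", p$min_identity),
    paste0("min_block_anchors=", p$min_block_anchors),
    paste0("max_gap_genes=", p$max_gap_genes),
    paste0("merge_distance=", p$merge_distance),
    paste0("n_boot=", p$n_boot),
    paste0("seed=", ifelse(is.null(p$seed), "NULL", p$seed)),
    paste0("mtn_mode=", p$mtn_mode),
    paste0("n_orthologs=", nrow(run$orthologs)),
    paste0("n_placed=", nrow(run$orthologs_placed)),
    paste0("n_blocks=", nrow(run$blocks)),
    paste0("n_regions=", nrow(run$regions)),
    sprintf("coverage=%.6f", run$coverage),
    sprintf("movement_p=%.6g", run$movement$p_value),
    sprintf("movement_p_lenient=%.6g", run$movement$p_value_lenient)
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Plot the focal-syntenic block map
#'
#' Draws each merged region as a pair of horizontal segments — its interval
#' on the genome-A chromosome and on the syntenic genome-B sequence —
#' a plain rendering of the classic synteny ribbon figure.
#'
#' @param regions A merged-regions tibble (e.g. `run$focal_regions`).
#' @return A ggplot.
#' @export
plot_synteny_blocks <- function(regions) {
  if (nrow(regions) == 0) stop("no regions to plot", call. = FALSE)
  seg <- dplyr::bind_rows(
    dplyr::transmute(regions, seq = paste0("A:", .data$chrom_a),
                     start = .data$start_a, end = .data$end_a,
                     region = factor(.data$region_id)),
    dplyr::transmute(regions, seq = paste0("B:", .data$chrom_b),
                     start = .data$start_b, end = .data$end_b,
                     region = factor(.data$region_id)))
  ggplot2::ggplot(seg, ggplot2::aes(y = .data$seq, yend = .data$seq,
                                    x = .data$start / 1e6,
                                    xend = .data$end / 1e6,
                                    colour = .data$region)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = "region") +
    ggplot2::theme_minimal()
}
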