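#' Configuration for the two-lineage genome-evolution simulator
#'
#' Defines an ancestral genome (chromosome count, genes per chromosome,
#' per-chromosome mitonuclear density biases) and how each of two descendant
#' lineages evolves from it: large-scale rearrangements (inversions and
#' translocations) plus independent single-gene movements whose rate can be
#' biased by category relative to the focal chromosome. The first chromosome
#' (`chrX`) is the focal one; the remainder are `chrA1`, `chrA2`, ...
#'
#' Defaults sketch a mammal-like comparison at reduced scale: 8 chromosomes
#' of 150 genes, a mitonuclear fraction of 0.08 (roughly the human
#' proportion), exponential gene lengths (mean 25 kb) and intergenic gaps
#' (mean 75 kb) giving ~15 Mb chromosomes, and a handful of rearrangements
#' per lineage.
#'
#' @param n_chroms Number of ancestral chromosomes.
#' @param genes_per_chrom Genes per chromosome (scalar or vector of length
#'   `n_chroms`).
#' @param mtn_fraction Genome-wide probability a gene is mitonuclear.
#' @param per_chrom_mtn_bias Per-chromosome multiplier on `mtn_fraction`
#'   (renormalised to gene-weighted mean 1, so the genome-wide fraction is
#'   preserved).
#' @param n_inversions,n_translocations Rearrangements per lineage.
#' @param move_rate Per-gene, per-lineage probability of a single-gene
#'   interchromosomal movement (before category bias).
#' @param move_bias Named multipliers on `move_rate` for the categories
#'   `off_focal` (source is the focal chromosome), `onto_focal` (destination
#'   is), and `auto_auto`.
#' @param mean_gene_len,mean_intergenic Means (bp) of the exponential gene
#'   length and intergenic gap distributions.
#' @param paralog_rate Fraction of spurious lower-scoring homology hits added
#'   per direction when emitting hit tables.
#' @param identity_mean,identity_sd Normal parameters for emitted percent
#'   identity (truncated to (30, 100]).
#' @param n_ultra Number of chromosome tails split off as placed
#'   `Ultra` contigs in lineage B (emulating a scaffold-level assembly).
#' @param n_unplaced Number of small tails split off as unplaced `scaf`
#'   contigs in lineage B.
#' @param seed Integer seed; one pseudo-random stream drives the whole
#'   simulation (ancestor, lineage A, lineage B, hit emission, in that
#'   order).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 8, genes_per_chrom = 150,
                       mtn_fraction = 0.08,
                       per_chrom_mtn_bias = rep(1, n_chroms),
                       n_inversions = 5, n_translocations = 2,
                       move_rate = 0,
                       move_bias = c(off_focal = 1, onto_focal = 1,
                                     auto_auto = 1),
                       mean_gene_len = 25e3, mean_intergenic = 75e3,
                       paralog_rate = 0.05, identity_mean = 70,
                       identity_sd = 10, n_ultra = 2, n_unplaced = 2,
                       seed = 1) {
  stopifnot(n_chroms >= 2, mtn_fraction > 0, mtn_fraction < 1,
            all(genes_per_chrom >= 2), n_inversions >= 0,
            n_translocations >= 0, move_rate >= 0, all(move_bias >= 0),
            mean_gene_len > 0, mean_intergenic > 0, paralog_rate >= 0,
            paralog_rate <= 1, identity_sd > 0, n_ultra >= 0,
            n_unplaced >= 0)
  genes_per_chrom <- rep(genes_per_chrom, length.out = n_chroms)
  per_chrom_mtn_bias <- rep(per_chrom_mtn_bias, length.out = n_chroms)
  # renormalise to gene-weighted mean 1 so the genome-wide fraction holds
  w <- genes_per_chrom / sum(genes_per_chrom)
  per_chrom_mtn_bias <- per_chrom_mtn_bias / sum(w * per_chrom_mtn_bias)
  if (any(mtn_fraction * per_chrom_mtn_bias > 1)) {
    stop("per-chromosome bias pushes the mt-N probability above 1",
         call. = FALSE)
  }
  if (!all(c("off_focal", "onto_focal", "auto_auto") %in% names(move_bias))) {
    stop("move_bias needs names off_focal, onto_focal, auto_auto",
         call. = FALSE)
  }
  structure(
    list(n_chroms = n_chroms, genes_per_chrom = genes_per_chrom,
         mtn_fraction = mtn_fraction,
         per_chrom_mtn_bias = per_chrom_mtn_bias,
         n_inversions = n_inversions, n_translocations = n_translocations,
         move_rate = move_rate, move_bias = move_bias,
         mean_gene_len = mean_gene_len, mean_intergenic = mean_intergenic,
         paralog_rate = paralog_rate, identity_mean = identity_mean,
         identity_sd = identity_sd, n_ultra = n_ultra,
         n_unplaced = n_unplaced, seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_chrom_names <- function(n) c("chrX", paste0("chrA", seq_len(n - 1)))

# lay genes out along each chromosome: exponential gaps, stored lengths
layout_genome <- function(genes, mean_intergenic) {
  genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(g, key) {
      g <- g[order(g$ord), ]
      gaps <- round(stats::rexp(nrow(g) + 1, 1 / mean_intergenic)) + 1
      start <- cumsum(gaps[-length(gaps)] ) + c(0, cumsum(g$len[-nrow(g)]))
      g$start <- as.numeric(start)
      g$end <- g$start + g$len
      g
    }) |>
    dplyr::ungroup()
}

chrom_lengths_of <- function(genes, tail_gap = 5e4) {
  genes |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(length = max(.data$end) + tail_gap, .groups = "drop")
}

sim_ancestor_impl <- function(config) {
  names_c <- sim_chrom_names(config$n_chroms)
  total <- sum(config$genes_per_chrom)
  ids <- sprintf("g%05d", seq_len(total))
  chrom <- rep(names_c, config$genes_per_chrom)
  p_mtn <- config$mtn_fraction *
    rep(config$per_chrom_mtn_bias, config$genes_per_chrom)
  genes <- tibble::tibble(
    gene_id = ids, chrom = chrom,
    ord = unlist(lapply(config$genes_per_chrom, seq_len)),
    len = round(stats::rexp(total, 1 / config$mean_gene_len)) + 200,
    strand = sample(c("+", "-"), total, replace = TRUE),
    is_mtn = stats::runif(total) < p_mtn
  )
  genes <- layout_genome(genes, config$mean_intergenic)
  gene_catalog(
    dplyr::select(genes, "gene_id", "chrom", "start", "end", "strand",
                  "is_mtn"),
    chrom_lengths_of(genes), genome_label = "ancestor"
  )
}

#' Simulate the ancestral genome
#'
#' Genes are placed sequentially with exponential intergenic gaps;
#' mitonuclear flags are Bernoulli draws at the per-chromosome biased rate.
#' Deterministic for a given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [gene_catalog()] labelled `"ancestor"`.
#' @export
simulate_ancestor <- function(config) {
  with_seed(config$seed, sim_ancestor_impl(config))
}

# internal gene state during evolution: gene_id (ancestral), chrom, ord,
# len, strand, is_mtn
catalog_to_state <- function(catalog) {
  catalog$genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(ord = dplyr::row_number(), len = .data$end - .data$start) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", "ord", "len", "strand", "is_mtn")
}

resequence <- function(state) {
  state |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$ord, .by_group = TRUE) |>
    dplyr::mutate(ord = dplyr::row_number()) |>
    dplyr::ungroup()
}

evolve_impl <- function(ancestor, config, lineage_label) {
  state <- catalog_to_state(ancestor)
  events <- list()
  log_event <- function(...) events[[length(events) + 1L]] <<-
      tibble::tibble(...)

  chrom_sizes <- function() table(state$chrom)

  # inversions: reverse gene order (and strand) in a random interval.
  # Breakpoints leave >= 5 genes on each flank so flanking runs stay
  # detectable as blocks.
  for (k in seq_len(config$n_inversions)) {
    sizes <- chrom_sizes()
    eligible <- names(sizes)[sizes >= 12]
    if (length(eligible) == 0) {
      log_event(type = "inversion_skipped", lineage = lineage_label,
                chrom_from = NA_character_, chrom_to = NA_character_,
                n_genes = 0L)
      next
    }
    ch <- sample(eligible, 1)
    n <- sizes[[ch]]
    ij <- sort(sample(6:(n - 5), 2))
    sel <- state$chrom == ch & state$ord >= ij[1] & state$ord <= ij[2]
    state$ord[sel] <- rev(state$ord[sel])
    state$strand[sel] <- ifelse(state$strand[sel] == "+", "-", "+")
    log_event(type = "inversion", lineage = lineage_label, chrom_from = ch,
              chrom_to = ch, n_genes = sum(sel))
    state <- resequence(state)
  }

  # translocations: reciprocal exchange of terminal segments between two
  # chromosomes (the common form; interstitial single-gene relocation is
  # modelled separately as gene movement). Breakpoints leave >= 5 genes on
  # each side so exchanged segments are detectable as synteny blocks.
  for (k in seq_len(config$n_translocations)) {
    sizes <- chrom_sizes()
    eligible <- names(sizes)[sizes >= 10]
    if (length(eligible) < 2) {
      log_event(type = "translocation_skipped", lineage = lineage_label,
                chrom_from = NA_character_, chrom_to = NA_character_,
                n_genes = 0L)
      next
    }
    pair <- sample(eligible, 2)
    n1 <- sizes[[pair[1]]]; n2 <- sizes[[pair[2]]]
    b1 <- sample(5:(n1 - 5), 1)
    b2 <- sample(5:(n2 - 5), 1)
    tail1 <- state$chrom == pair[1] & state$ord > b1
    tail2 <- state$chrom == pair[2] & state$ord > b2
    state$ord[tail1] <- b2 + rank(state$ord[tail1])
    state$ord[tail2] <- b1 + rank(state$ord[tail2])
    state$chrom[tail1] <- pair[2]
    state$chrom[tail2] <- pair[1]
    log_event(type = "translocation", lineage = lineage_label,
              chrom_from = pair[1], chrom_to = pair[2], n_genes = sum(tail1))
    log_event(type = "translocation", lineage = lineage_label,
              chrom_from = pair[2], chrom_to = pair[1], n_genes = sum(tail2))
    state <- resequence(state)
  }

  # single-gene movements
  moves <- list()
  if (config$move_rate > 0) {
    chroms <- unique(state$chrom)
    weight <- vapply(chroms, function(ch) sum(state$chrom == ch), numeric(1))
    for (i in seq_len(nrow(state))) {
      src <- state$chrom[i]
      others <- chroms != src
      dest <- sample(chroms[others], 1, prob = weight[others])
      cat_ <- if (src == "chrX") "off_focal"
        else if (dest == "chrX") "onto_focal" else "auto_auto"
      p <- min(1, config$move_rate * config$move_bias[[cat_]])
      if (stats::runif(1) < p) {
        moves[[length(moves) + 1L]] <- tibble::tibble(
          type = "gene_move", lineage = lineage_label, chrom_from = src,
          chrom_to = dest, n_genes = 1L, gene_id = state$gene_id[i],
          category = cat_)
        state$chrom[i] <- dest
        state$ord[i] <- sample.int(sum(state$chrom == dest), 1) - 0.5
        state <- resequence(state)
      }
    }
  }

  # lineage-B style assembly fragmentation: placed Ultra contigs and small
  # unplaced scaffolds split off chromosome tails
  splits <- config$n_ultra + config$n_unplaced
  for (k in seq_len(splits)) {
    is_ultra <- k <= config$n_ultra
    sizes <- chrom_sizes()
    big <- names(sizes)[sizes >= 10 & grepl("^chr", names(sizes))]
    if (length(big) == 0) next
    ch <- sample(big, 1)
    n <- sizes[[ch]]
    n_off <- if (is_ultra) max(3L, round(n * stats::runif(1, 0.1, 0.3)))
      else sample(1:3, 1)
    new_name <- if (is_ultra) paste0("Ultra", k)
      else paste0("scaf", k - config$n_ultra)
    sel <- state$chrom == ch & state$ord > n - n_off
    state$chrom[sel] <- new_name
    log_event(type = if (is_ultra) "ultra_split" else "unplaced_split",
              lineage = lineage_label, chrom_from = ch, chrom_to = new_name,
              n_genes = sum(sel))
    state <- resequence(state)
  }

  # with no events at all the descendant keeps the ancestral coordinates
  any_events <- length(events) > 0 || length(moves) > 0
  state <- if (any_events) {
    layout_genome(state, config$mean_intergenic)
  } else {
    dplyr::inner_join(
      dplyr::select(state, -"len"),
      dplyr::select(ancestor$genes, "gene_id", "start", "end"),
      by = "gene_id")
  }
  genes <- state |>
    dplyr::mutate(gene_id = paste0(lineage_label, "_", .data$gene_id)) |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "is_mtn")
  catalog <- gene_catalog(genes, chrom_lengths_of(state),
                          genome_label = lineage_label,
                          placed_pattern = "^(chr|Ultra)")
  move_tab <- dplyr::bind_rows(moves)
  if (nrow(move_tab) == 0) {
    move_tab <- tibble::tibble(type = character(), lineage = character(),
                               chrom_from = character(),
                               chrom_to = character(), n_genes = integer(),
                               gene_id = character(), category = character())
  }
  list(catalog = catalog,
       events = dplyr::bind_rows(dplyr::bind_rows(events), move_tab),
       moves = move_tab)
}

#' Evolve one descendant lineage from the ancestor
#'
#' Applies inversions, translocations and per-gene interchromosomal
#' movements, then splits off `Ultra`/unplaced contigs (lineage-B assembly
#' emulation applies whenever `n_ultra`/`n_unplaced` are positive), relays
#' coordinates, and prefixes gene ids with the lineage label. All events are
#' returned for the truth log.
#'
#' @param ancestor Catalog from [simulate_ancestor()].
#' @param config A [sim_config()].
#' @param lineage_label Short label (e.g. `"A"`); becomes the gene-id prefix.
#' @param seed Seed for this lineage's draws; defaults to a lineage-specific
#'   offset of `config$seed`.
#' @return A list with `catalog`, `events` (all operations) and `moves`
#'   (single-gene movements only).
#' @export
evolve_descendant <- function(ancestor, config, lineage_label,
                              seed = NULL) {
  if (is.null(seed)) {
    seed <- config$seed + 7919L * match(lineage_label, c("A", "B"),
                                        nomatch = 3L)
  }
  with_seed(seed, evolve_impl(ancestor, config, lineage_label))
}

emit_hits_impl <- function(catalog_a, catalog_b, truth_pairs, config) {
  n <- nrow(truth_pairs)
  identity <- pmin(100, pmax(
    0.1, stats::rnorm(n, config$identity_mean, config$identity_sd)))
  bitscore <- round(pmax(40, 50 + 4 * identity + stats::rnorm(n, 0, 5)), 1)
  evalue <- pmax(10^(-bitscore / 10), 1e-180)
  base <- tibble::tibble(pair = seq_len(n), pct_identity = round(identity, 1),
                         evalue = evalue, bitscore = bitscore)
  ab <- tibble::tibble(query_id = truth_pairs$gene_a,
                       subject_id = truth_pairs$gene_b)
  ba <- tibble::tibble(query_id = truth_pairs$gene_b,
                       subject_id = truth_pairs$gene_a)
  add_noise <- function(tab) {
    n_par <- stats::rbinom(1, n, config$paralog_rate)
    if (n_par == 0) return(tab)
    qi <- sample.int(n, n_par, replace = TRUE)
    subjects <- if (identical(tab$query_id[1], truth_pairs$gene_a[1]))
      truth_pairs$gene_b else truth_pairs$gene_a
    si <- vapply(qi, function(i) {
      s <- sample.int(n, 1)
      while (s == i) s <- sample.int(n, 1)
      s
    }, integer(1))
    par <- tibble::tibble(
      query_id = tab$query_id[qi], subject_id = subjects[si],
      pct_identity = round(pmin(100, pmax(
        0.1, stats::rnorm(n_par, config$identity_mean - 10,
                           config$identity_sd))), 1),
      bitscore = round(base$bitscore[qi] * stats::runif(n_par, 0.4, 0.8), 1)
    )
    par$evalue <- pmax(10^(-par$bitscore / 10), 1e-180)
    dplyr::bind_rows(tab, par[, names(tab)])
  }
  ab <- dplyr::bind_cols(ab, base[, -1])
  ba <- dplyr::bind_cols(ba, base[, -1])
  list(ab = add_noise(ab), ba = add_noise(ba))
}

#' Emit BLAST-style homology hit tables for a simulated genome pair
#'
#' Each true ortholog pair yields mutual high-scoring hits (identity drawn
#' from a truncated normal, bitscore increasing with identity, e-value
#' monotone decreasing in bitscore); spurious paralog hits with lower
#' bitscores are added at `paralog_rate` per direction.
#'
#' @param catalog_a,catalog_b Descendant catalogs.
#' @param truth_pairs Tibble with `gene_a`, `gene_b` true ortholog ids.
#' @param config A [sim_config()].
#' @param seed Seed; defaults to an offset of `config$seed`.
#' @return List of two hit tibbles, `ab` and `ba`, in [read_hit_table()]
#'   column format.
#' @export
emit_hits <- function(catalog_a, catalog_b, truth_pairs, config,
                      seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 104729L
  with_seed(seed, emit_hits_impl(catalog_a, catalog_b, truth_pairs, config))
}

#' Simulate a two-genome comparison with full ground truth
#'
#' Runs the whole generator: ancestor, two descendant lineages (`A`, of
#' which the focal chromosome analysis is done; `B`, which receives the
#' Ultra/unplaced splits), and both hit tables, all from a single seeded
#' stream. The truth log records ortholog pairs, every rearrangement and
#' movement event, and the realised per-chromosome mitonuclear bias of the
#' ancestor.
#'
#' @param config A [sim_config()].
#' @return An object of class `synmito_sim`: list with `config`, `ancestor`,
#'   `genome_a`, `genome_b`, `hits_ab`, `hits_ba`, and `truth` (elements
#'   `pairs`, `events`, `moves`, `per_chrom_bias`).
#' @export
simulate_genomes <- function(config) {
  sim <- with_seed(config$seed, {
    anc <- sim_ancestor_impl(config)
    config_a <- config
    config_a$n_ultra <- 0L
    config_a$n_unplaced <- 0L
    la <- evolve_impl(anc, config_a, "A")
    lb <- evolve_impl(anc, config, "B")
    pairs <- tibble::tibble(
      anc_id = anc$genes$gene_id,
      anc_chrom = anc$genes$chrom,
      gene_a = paste0("A_", anc$genes$gene_id),
      gene_b = paste0("B_", anc$genes$gene_id),
      is_mtn = anc$genes$is_mtn
    )
    hits <- emit_hits_impl(la$catalog, lb$catalog, pairs, config)
    list(anc = anc, la = la, lb = lb, pairs = pairs, hits = hits)
  })
  frac <- sim$anc$genes |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(n_genes = dplyr::n(), n_mtn = sum(.data$is_mtn),
                     .groups = "drop") |>
    dplyr::mutate(bias = (.data$n_mtn / .data$n_genes) /
                    (sum(.data$n_mtn) / sum(.data$n_genes)))
  structure(
    list(config = config, ancestor = sim$anc,
         genome_a = sim$la$catalog, genome_b = sim$lb$catalog,
         hits_ab = sim$hits$ab, hits_ba = sim$hits$ba,
         truth = list(pairs = sim$pairs,
                      events = dplyr::bind_rows(sim$la$events,
                                                sim$lb$events),
                      moves = dplyr::bind_rows(sim$la$moves, sim$lb$moves),
                      per_chrom_bias = frac)),
    class = "synmito_sim"
  )
}

#' @export
print.synmito_sim <- function(x, ...) {
  cat("<synmito_sim> seed", x$config$seed, "\n")
  print(x$genome_a); print(x$genome_b)
  cat("  true movements:", nrow(x$truth$moves), "; events:",
      nrow(x$truth$events), "\n")
  invisible(x)
}

#' True focal-syntenic intervals from a simulation
#'
#' The intervals of both descendant genomes spanned by orthologs that
#' descend from the ancestral focal chromosome and were never moved as
#' single genes — the ground truth the synteny stage should recover.
#'
#' @param sim A `synmito_sim`.
#' @return Tibble of hull intervals per (`chrom_a`, `chrom_b`) pair:
#'   `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b`, `n_genes`.
#' @export
truth_focal_map <- function(sim) {
  moved_ids <- sim$truth$moves$gene_id
  keep <- sim$truth$pairs |>
    dplyr::filter(.data$anc_chrom == "chrX", !.data$anc_id %in% moved_ids)
  ga <- sim$genome_a$genes
  gb <- sim$genome_b$genes
  keep |>
    dplyr::inner_join(
      dplyr::select(ga, gene_a = "gene_id", chrom_a = "chrom",
                    start_a = "start", end_a = "end"), by = "gene_a") |>
    dplyr::inner_join(
      dplyr::select(gb, gene_b = "gene_id", chrom_b = "chrom",
                    start_b = "start", end_b = "end"), by = "gene_b") |>
    dplyr::group_by(.data$chrom_a, .data$chrom_b) |>
    dplyr::summarise(start_a = min(.data$start_a), end_a = max(.data$end_a),
                     start_b = min(.data$start_b), end_b = max(.data$end_b),
                     n_genes = dplyr::n(), .groups = "drop")
}

#' Write every pipeline input file for a simulation
#'
#' Emits `A.bed`, `B.bed`, `A_chrom_lengths.tsv`, `B_chrom_lengths.tsv`,
#' 12-column hit tables `A_B.tsv` / `B_A.tsv`, a GO-style annotation table
#' `mtn.tsv` (mitonuclear genes of genome A under GO:0005739), and
#' `truth.json`.
#'
#' @param sim A `synmito_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$genome_a, file.path(dir, "A.bed"))
  write_gene_table(sim$genome_b, file.path(dir, "B.bed"))
  readr::write_tsv(sim$genome_a$chrom_lengths,
                   file.path(dir, "A_chrom_lengths.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(sim$genome_b$chrom_lengths,
                   file.path(dir, "B_chrom_lengths.tsv"), col_names = FALSE,
                   progress = FALSE)
  as_outfmt6 <- function(h) {
    tibble::tibble(
      qseqid = h$query_id, sseqid = h$subject_id, pident = h$pct_identity,
      length = 500L, mismatch = pmax(
        0L, as.integer(round(500 * (1 - h$pct_identity / 100)))),
      gapopen = 0L, qstart = 1L, qend = 500L, sstart = 1L, send = 500L,
      evalue = h$evalue, bitscore = h$bitscore
    )
  }
  readr::write_tsv(as_outfmt6(sim$hits_ab), file.path(dir, "A_B.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(as_outfmt6(sim$hits_ba), file.path(dir, "B_A.tsv"),
                   col_names = FALSE, progress = FALSE)
  ga <- sim$genome_a$genes
  readr::write_tsv(
    tibble::tibble(gene_id = ga$gene_id,
                   go_term = ifelse(ga$is_mtn, "GO:0005739", "GO:0005634")),
    file.path(dir, "mtn.tsv"), col_names = FALSE, progress = FALSE)
  truth <- list(
    pairs = sim$truth$pairs, events = sim$truth$events,
    per_chrom_bias = sim$truth$per_chrom_bias,
    focal_map = truth_focal_map(sim)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
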