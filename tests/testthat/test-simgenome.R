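test_that("config validation renormalises biases and rejects bad rates", {
  cfg <- sim_config(n_chroms = 2, genes_per_chrom = c(100, 100),
                    per_chrom_mtn_bias = c(1, 3))
  expect_equal(sum(cfg$per_chrom_mtn_bias) / 2, 1)
  expect_error(sim_config(mtn_fraction = 0.5,
                          per_chrom_mtn_bias = c(8, rep(0.5, 7))),
               "above 1")
  expect_error(sim_config(move_rate = -1))
  expect_error(sim_config(move_bias = c(a = 1, b = 1, c = 1)), "off_focal")
})

test_that("ancestor simulation is deterministic and respects layout
           invariants", {
  cfg <- sim_config(seed = 21)
  a1 <- simulate_ancestor(cfg)
  a2 <- simulate_ancestor(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_equal(nrow(a1$genes), sum(cfg$genes_per_chrom))
  # genes do not overlap within a chromosome
  by_chrom <- split(a1$genes, a1$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("unbiased simulation hits the target mt-N fraction; a bias vector
           skews per-chromosome counts as expected", {
  cfg <- sim_config(n_chroms = 2, genes_per_chrom = 2000,
                    mtn_fraction = 0.2, seed = 31)
  anc <- simulate_ancestor(cfg)
  expect_equal(mean(anc$genes$is_mtn), 0.2, tolerance = 0.15)

  cfg2 <- sim_config(n_chroms = 2, genes_per_chrom = 3000,
                     mtn_fraction = 0.2,
                     per_chrom_mtn_bias = c(0.5, 1.5), seed = 32)
  anc2 <- simulate_ancestor(cfg2)
  tab <- table(anc2$genes$chrom, anc2$genes$is_mtn)
  share_1 <- tab["chrX", "TRUE"] / sum(tab[, "TRUE"])
  # chrom 1 carries 0.5/(0.5+1.5) = 1/4 of mt-N genes in expectation
  expect_equal(share_1, 0.25, tolerance = 0.2)
})

test_that("null evolution returns the ancestor unchanged up to labels", {
  cfg <- sim_config(n_inversions = 0, n_translocations = 0, move_rate = 0,
                    n_ultra = 0, n_unplaced = 0, seed = 41)
  anc <- simulate_ancestor(cfg)
  d <- evolve_descendant(anc, cfg, "A")
  expect_equal(nrow(d$moves), 0)
  expect_equal(sub("^A_", "", d$catalog$genes$gene_id), anc$genes$gene_id)
  expect_equal(d$catalog$genes$start, anc$genes$start)
  expect_equal(d$catalog$genes$chrom, anc$genes$chrom)
  expect_equal(d$catalog$genes$is_mtn, anc$genes$is_mtn)
})

test_that("an inversion reverses gene order and is logged with its size", {
  cfg <- sim_config(n_inversions = 1, n_translocations = 0, move_rate = 0,
                    n_ultra = 0, n_unplaced = 0, seed = 51)
  anc <- simulate_ancestor(cfg)
  d <- evolve_descendant(anc, cfg, "A")
  ev <- d$events[d$events$type == "inversion", ]
  expect_equal(nrow(ev), 1)
  ch <- ev$chrom_from
  anc_order <- anc$genes$gene_id[anc$genes$chrom == ch][
    order(anc$genes$start[anc$genes$chrom == ch])]
  new_order <- sub("^A_", "", d$catalog$genes$gene_id[
    d$catalog$genes$chrom == ch][
      order(d$catalog$genes$start[d$catalog$genes$chrom == ch])])
  # same gene set, not the same order, and one contiguous run is reversed
  expect_setequal(new_order, anc_order)
  expect_false(identical(new_order, anc_order))
  differs <- which(new_order != anc_order)
  run <- seq(min(differs), max(differs))
  expect_equal(new_order[run], rev(anc_order[run]))
  expect_equal(length(run), ev$n_genes)
})

test_that("movement counts scale with move_rate as a binomial expectation", {
  cfg <- sim_config(move_rate = 20 / 1200, n_inversions = 0,
                    n_translocations = 0, n_ultra = 0, n_unplaced = 0,
                    seed = 61)
  anc <- simulate_ancestor(cfg)
  counts <- purrr::map_int(1:8, function(i) {
    nrow(evolve_descendant(anc, cfg, "A", seed = 1000 + i)$moves)
  })
  # E = 20 per lineage; allow generous Poisson-scale noise on the mean
  expect_gt(mean(counts), 10)
  expect_lt(mean(counts), 32)
})

test_that("lineage-B fragmentation produces placed Ultra and unplaced scaf
           contigs", {
  sim <- simulate_genomes(sim_config(seed = 71))
  chroms_b <- sim$genome_b$chrom_lengths$chrom
  expect_true(any(grepl("^Ultra", chroms_b)))
  expect_true(any(grepl("^scaf", chroms_b)))
  gb <- sim$genome_b$genes
  expect_true(all(gb$placed[grepl("^(chr|Ultra)", gb$chrom)]))
  expect_true(all(!gb$placed[grepl("^scaf", gb$chrom)]))
  # genome A is fully assembled
  expect_true(all(grepl("^chr", sim$genome_a$genes$chrom)))
})

test_that("emitted hits invert to the truth map under rBBH", {
  cfg <- sim_config(paralog_rate = 0, seed = 81)
  sim <- simulate_genomes(cfg)
  pairs <- reciprocal_best_hits(sim$hits_ab, sim$hits_ba)
  expect_equal(
    dplyr::arrange(pairs[, c("gene_a", "gene_b")], gene_a),
    dplyr::arrange(sim$truth$pairs[, c("gene_a", "gene_b")], gene_a)
  )
  # paralog noise at the default rate must not disturb recovery either
  cfg2 <- sim_config(paralog_rate = 0.1, seed = 82)
  sim2 <- simulate_genomes(cfg2)
  pairs2 <- reciprocal_best_hits(sim2$hits_ab, sim2$hits_ba)
  expect_gte(nrow(pairs2), 0.99 * nrow(sim2$truth$pairs))
})

test_that("hit identities below the top-hit rule yield no orthologs", {
  cfg <- sim_config(identity_mean = 15, identity_sd = 3, paralog_rate = 0,
                    seed = 91)
  sim <- simulate_genomes(cfg)
  expect_equal(nrow(reciprocal_best_hits(sim$hits_ab, sim$hits_ba)), 0)
})

test_that("simulation and emitted files are reproducible for a fixed seed", {
  cfg <- sim_config(seed = 13, move_rate = 0.01)
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$genome_a$genes, s2$genome_a$genes)
  expect_identical(s1$genome_b$genes, s2$genome_b$genes)
  expect_identical(s1$hits_ab, s2$hits_ab)
  expect_identical(s1$truth$moves, s2$truth$moves)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_inputs(s1, d1)
  write_sim_inputs(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # the files round-trip through the package's own readers
  mtn <- read_go_annotations(file.path(d1, "mtn.tsv"))
  cat_a <- read_gene_table(file.path(d1, "A.bed"), "bed",
                           file.path(d1, "A_chrom_lengths.tsv"),
                           mtn_ids = mtn)
  expect_equal(sum(cat_a$genes$is_mtn), sum(s1$genome_a$genes$is_mtn))
  hits <- read_hit_table(file.path(d1, "A_B.tsv"))
  expect_equal(nrow(hits), nrow(s1$hits_ab))
})

test_that("truth log events replay consistently: every gene appears exactly
           once per genome", {
  # no Ultra/scaf splits here: splits rename chromosomes after moves, which
  # the per-move log entries do not retrospectively track
  sim <- simulate_genomes(sim_config(seed = 17, move_rate = 0.02,
                                     n_ultra = 0, n_unplaced = 0))
  expect_equal(anyDuplicated(sim$genome_a$genes$gene_id), 0)
  expect_equal(anyDuplicated(sim$genome_b$genes$gene_id), 0)
  expect_equal(nrow(sim$genome_a$genes), nrow(sim$truth$pairs))
  expect_equal(nrow(sim$genome_b$genes), nrow(sim$truth$pairs))
  # moved genes really are where the log says they went
  for (i in seq_len(nrow(sim$truth$moves))) {
    mv <- sim$truth$moves[i, ]
    gcat <- if (mv$lineage == "A") sim$genome_a else sim$genome_b
    gid <- paste0(mv$lineage, "_", mv$gene_id)
    later <- sim$truth$moves[-seq_len(i), ]
    if (gid %in% paste0(later$lineage, "_", later$gene_id)) next
    expect_equal(gcat$genes$chrom[gcat$genes$gene_id == gid], mv$chrom_to)
  }
})
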