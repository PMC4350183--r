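make_anchors <- function(rank_a, rank_b, chrom_a = "chr1", chrom_b = "chr1",
                         spacing = 1e5) {
  n <- length(rank_a)
  tibble::tibble(
    gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
    chrom_a = chrom_a, chrom_b = chrom_b,
    start_a = rank_a * spacing, end_a = rank_a * spacing + 1e4,
    start_b = rank_b * spacing, end_b = rank_b * spacing + 1e4,
    rank_a = as.integer(rank_a), rank_b = as.integer(rank_b)
  )
}

test_that("anchors get 0-based start-sorted ranks and reject bad inputs", {
  cat_a <- run_of_genes(10, prefix = "a")
  cat_b <- run_of_genes(10, prefix = "b")
  pairs <- tibble::tibble(gene_a = paste0("a", 1:10),
                          gene_b = paste0("b", 1:10))
  anchors <- anchors_from_orthologs(pairs, cat_a, cat_b)
  expect_equal(anchors$rank_a, 0:9)
  expect_equal(anchors$rank_b, 0:9)
  expect_error(
    anchors_from_orthologs(tibble::tibble(gene_a = "aX", gene_b = "b1"),
                           cat_a, cat_b), "aX")
  cat_b$genes$placed[1] <- FALSE
  expect_error(anchors_from_orthologs(pairs, cat_a, cat_b), "unplaced")
})

test_that("chaining finds collinear runs in both orientations", {
  fwd <- chain_anchors(make_anchors(0:4, 0:4))
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$n_anchors, 5L)
  expect_equal(fwd$orientation, "same")

  rev <- chain_anchors(make_anchors(0:4, 4:0))
  expect_equal(rev$orientation, "inverted")
  expect_equal(rev$n_anchors, 5L)

  expect_equal(nrow(chain_anchors(make_anchors(0:3, 0:3))), 0)  # below min
  expect_equal(nrow(chain_anchors(make_anchors(0:4, 0:4)[0, ])), 0)
})

test_that("two interleaved collinear runs are split into two blocks", {
  # even ranks map low, odd ranks map high: two runs of 6
  ra <- 0:11
  rb <- ifelse(ra %% 2 == 0, ra / 2, 30 + (ra - 1) / 2)
  blocks <- chain_anchors(make_anchors(ra, rb))
  expect_equal(nrow(blocks), 2)
  expect_equal(sort(blocks$n_anchors), c(6L, 6L))
})

test_that("gap rule breaks chains further apart than max_gap_genes", {
  ra <- c(0:4, 40:44)
  blocks <- chain_anchors(make_anchors(ra, ra))
  expect_equal(nrow(blocks), 2)
  one <- chain_anchors(make_anchors(ra, ra), max_gap_genes = 50)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_anchors, 10L)
})

test_that("chaining matches the exhaustive monotone-chain oracle", {
  set.seed(303)
  for (rep in 1:80) {
    n <- sample(2:15, 1)
    ra <- sample.int(40, n)
    rb <- sample.int(40, n)
    anchors <- make_anchors(ra, rb)
    gap <- sample(c(5, 10, 25), 1)
    blocks <- chain_anchors(anchors, min_block_anchors = 2,
                            max_gap_genes = gap)
    want <- max_chain_oracle(ra, rb, gap)
    if (want < 2) {
      expect_equal(nrow(blocks), 0)
    } else {
      expect_equal(blocks$n_anchors[1], want)
    }
    # every block is a valid chain and anchors are never duplicated
    if (nrow(blocks) > 0) {
      for (i in seq_len(nrow(blocks))) {
        expect_true(is_valid_chain(blocks$anchors[[i]],
                                   blocks$orientation[i], gap))
      }
      all_ids <- unlist(purrr::map(blocks$anchors, "gene_a"))
      expect_equal(anyDuplicated(all_ids), 0)
    }
  }
})

test_that("blocks closer than the merge distance fuse on both genomes", {
  b <- function(id, sa, ea, sb, eb, cb = "chr6") tibble::tibble(
    block_id = id, chrom_a = "chrX", chrom_b = cb, orientation = "same",
    n_anchors = 5L, start_a = sa, end_a = ea, start_b = sb, end_b = eb,
    anchors = list(tibble::tibble())
  )
  near <- dplyr::bind_rows(b(1, 0, 1e6, 0, 1e6),
                           b(2, 6e6, 7e6, 6e6, 7e6))   # 5 Mb gaps
  expect_equal(nrow(merge_blocks(near)), 1)
  far <- dplyr::bind_rows(b(1, 0, 1e6, 0, 1e6),
                          b(2, 16e6, 17e6, 16e6, 17e6)) # 15 Mb gaps
  expect_equal(nrow(merge_blocks(far)), 2)
  # near on A but far on B: the two-genome gate refuses the merge
  mixed <- dplyr::bind_rows(b(1, 0, 1e6, 0, 1e6),
                            b(2, 6e6, 7e6, 30e6, 31e6))
  expect_equal(nrow(merge_blocks(mixed)), 2)
  # different B chromosome: never merged
  other <- dplyr::bind_rows(b(1, 0, 1e6, 0, 1e6),
                            b(2, 6e6, 7e6, 6e6, 7e6, cb = "chr7"))
  expect_equal(nrow(merge_blocks(other)), 2)
  # hull covers members
  m <- merge_blocks(near)
  expect_equal(c(m$start_a, m$end_a), c(0, 7e6))
  expect_equal(m$n_blocks, 2L)
})

test_that("merging is idempotent", {
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    starts <- sort(stats::runif(n, 0, 1e8))
    blocks <- tibble::tibble(
      block_id = seq_len(n), chrom_a = "chrX",
      chrom_b = sample(c("c1", "c2"), n, replace = TRUE),
      orientation = "same", n_anchors = 5L,
      start_a = starts, end_a = starts + stats::runif(n, 1e5, 5e6),
      start_b = starts, end_b = starts + stats::runif(n, 1e5, 5e6),
      anchors = list(tibble::tibble())
    )
    once <- merge_blocks(blocks)
    again <- merge_blocks(
      dplyr::mutate(once, block_id = region_id, orientation = "same",
                    anchors = list(tibble::tibble())))
    expect_equal(once[, c("chrom_a", "chrom_b", "start_a", "end_a",
                          "start_b", "end_b")],
                 again[, c("chrom_a", "chrom_b", "start_a", "end_a",
                           "start_b", "end_b")])
  }
})

test_that("focal regions report coverage of the focal chromosome", {
  cat_a <- run_of_genes(10, chrom = "chrX", prefix = "a")
  len_x <- cat_a$chrom_lengths$length[1]
  regions <- tibble::tibble(
    region_id = 1:2, chrom_a = c("chrX", "chr2"), chrom_b = "c6",
    start_a = c(0, 0), end_a = c(len_x, 100), start_b = c(0, 0),
    end_b = c(1000, 100), n_blocks = 1L, n_anchors = 5L,
    block_ids = list(1L, 2L)
  )
  focal <- focal_syntenic_regions(regions, "chrX", cat_a)
  expect_equal(nrow(focal), 1)
  expect_equal(synteny_coverage(focal), 1)
  none <- focal_syntenic_regions(regions[2, ], "chrX", cat_a)
  expect_equal(nrow(none), 0)
  expect_equal(synteny_coverage(none), 0)
  expect_error(focal_syntenic_regions(regions, "chrZ", cat_a), "chrZ")
})

test_that("overlapping focal intervals are not double-counted in coverage", {
  cat_a <- run_of_genes(10, chrom = "chrX", prefix = "a", spacing = 1000)
  len_x <- cat_a$chrom_lengths$length[1]
  regions <- tibble::tibble(
    region_id = 1:2, chrom_a = "chrX", chrom_b = c("c1", "c2"),
    start_a = c(0, 0), end_a = c(len_x, len_x), start_b = 0, end_b = 100,
    n_blocks = 1L, n_anchors = 5L, block_ids = list(1L, 2L)
  )
  focal <- focal_syntenic_regions(regions, "chrX", cat_a)
  expect_equal(synteny_coverage(focal), 1)
})
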