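# a two-chromosome scenario used across classification tests:
# genome A has chrX and chr2; genome B has c6 (X-syntenic) and c9
movement_fixture <- function() {
  ga <- tibble::tibble(
    gene_id = paste0("a", 1:8),
    chrom = c("chrX", "chrX", "chrX", "chrX", "chr2", "chr2", "chr2", "chrX"),
    start = c(0, 1000, 2000, 3000, 0, 1000, 2000, 4000) * 1000,
    end = c(0, 1000, 2000, 3000, 0, 1000, 2000, 4000) * 1000 + 1e4
  )
  gb <- tibble::tibble(
    gene_id = paste0("b", 1:8),
    chrom = c("c6", "c6", "c6", "c9", "c9", "c9", "c6", "c9"),
    start = c(0, 1000, 2000, 0, 1000, 2000, 9000, 3000) * 1000,
    end = c(0, 1000, 2000, 0, 1000, 2000, 9000, 3000) * 1000 + 1e4
  )
  lens_a <- tibble::tibble(chrom = c("chrX", "chr2"), length = c(5e6, 5e6))
  lens_b <- tibble::tibble(chrom = c("c6", "c9"), length = c(1e7, 5e6))
  regions <- tibble::tibble(
    region_id = 1:2, chrom_a = c("chrX", "chr2"), chrom_b = c("c6", "c9"),
    start_a = c(0, 0), end_a = c(3.2e6, 3.2e6),
    start_b = c(0, 0), end_b = c(3.2e6, 3.2e6),
    n_blocks = 1L, n_anchors = 3L, block_ids = list(1L, 2L)
  )
  list(
    cat_a = gene_catalog(ga, lens_a, "A"),
    cat_b = gene_catalog(gb, lens_b, "B"),
    regions = regions,
    pairs = tibble::tibble(gene_a = paste0("a", 1:8),
                           gene_b = paste0("b", 1:8))
  )
}

test_that("pairs inside corresponding region intervals are retained", {
  fx <- movement_fixture()
  cls <- classify_movements(fx$pairs, fx$regions, fx$cat_a, fx$cat_b, "chrX")
  by_gene <- stats::setNames(cls$status, cls$gene_a)
  # a1..a3 sit in the chrX<->c6 region; a5..a6 in the chr2<->c9 region
  expect_equal(unname(by_gene[c("a1", "a2", "a3", "a5", "a6")]),
               rep("retained", 5))
  # a4: on chrX but its ortholog b4 is on c9 -> movement off the X-syntenic
  # context; source c9 is not X-syntenic, destination chrX => A->X
  expect_equal(cls$category[cls$gene_a == "a4"], "A->X")
  # a7: on chr2, ortholog b7 on c6 but at 9 Mb, outside the X-syntenic
  # interval => A->A (and ambiguous: c6 is only partly X-syntenic)
  expect_equal(cls$category[cls$gene_a == "a7"], "A->A")
  expect_true(cls$ambiguous[cls$gene_a == "a7"])
  # a8: on chrX at 4 Mb (outside region hull), b8 on c9 => A->X
  expect_equal(cls$category[cls$gene_a == "a8"], "A->X")
})

test_that("anchor membership retains a pair even outside region hulls", {
  fx <- movement_fixture()
  blocks <- tibble::tibble(
    block_id = 1L, chrom_a = "chrX", chrom_b = "c9", orientation = "same",
    n_anchors = 1L, start_a = 4e6, end_a = 4.01e6, start_b = 3e6,
    end_b = 3.01e6,
    anchors = list(tibble::tibble(gene_a = "a8", gene_b = "b8"))
  )
  cls <- classify_movements(fx$pairs, fx$regions, fx$cat_a, fx$cat_b, "chrX",
                            blocks = blocks)
  expect_equal(cls$status[cls$gene_a == "a8"], "retained")
})

test_that("zero observed movements give a degenerate table with p = 1", {
  fx <- movement_fixture()
  pairs <- fx$pairs[c(1:3, 5:6), ]  # only retained pairs
  mt <- movement_test(pairs, fx$regions, fx$cat_a, fx$cat_b, "chrX")
  expect_equal(sum(mt$counts$observed), 0)
  expect_equal(mt$p_value, 1)
})

test_that("expected movements follow the size-based null with rescaling", {
  # degenerate: all probability mass on A->A
  ex0 <- expected_movements(0, 0, 50)
  expect_equal(unname(ex0$expected), c(0, 0, 50))
  # hand arithmetic: T=100, P=Q=0.05 -> raw (4.75, 4.75, 90.25), XX = 0.25,
  # rescale by 100/99.75
  ex <- expected_movements(0.05, 0.05, 100)
  expect_equal(unname(ex$expected), c(4.75, 4.75, 90.25) * 100 / 99.75,
               tolerance = 1e-12)
  expect_equal(ex$x_to_x, 0.25)
  expect_equal(sum(ex$expected), 100)
})

test_that("movement_test wires expected counts from catalog composition", {
  fx <- movement_fixture()
  mt <- movement_test(fx$pairs, fx$regions, fx$cat_a, fx$cat_b, "chrX")
  # P(target=X) = chrX bp share of genome A = 5e6 / 1e7
  expect_equal(mt$p_target_x, 0.5)
  # P(source=X): b-side genes inside the chrX<->c6 region interval:
  # b1,b2,b3 of 8 classified orthologs
  expect_equal(mt$p_source_x, 3 / 8)
  expect_equal(sum(mt$counts$expected_raw), sum(mt$counts$observed))
  expect_true(mt$p_value >= 0 && mt$p_value <= 1)
  # lenient tally drops the ambiguous a7 movement
  expect_equal(sum(mt$counts_lenient$observed),
               sum(mt$counts$observed) - 1)
})

test_that("Freeman-Halton enumeration matches printed-table p-values", {
  expect_equal(fisher_exact_2x3(c(0, 4, 132), c(2, 4, 130)), 0.640,
               tolerance = 0.005 / 0.640)
  expect_equal(fisher_exact_2x3(c(3, 3, 92), c(4, 4, 90)), 0.845,
               tolerance = 0.005 / 0.845)
})

test_that("Freeman-Halton agrees with the network-algorithm implementation", {
  set.seed(505)
  for (rep in 1:60) {
    obs <- stats::rpois(3, sample(c(2, 5, 20), 1))
    ex <- stats::rpois(3, sample(c(2, 5, 20), 1))
    if (sum(obs) == 0 || sum(ex) == 0) next
    got <- fisher_exact_2x3(obs, ex)
    want <- stats::fisher.test(rbind(obs, ex))$p.value
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("Freeman-Halton handles identity and degenerate margins", {
  expect_equal(fisher_exact_2x3(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(fisher_exact_2x3(c(0, 0, 0), c(1, 2, 3)), 1)
  # a zero column collapses to a 2x2 hypergeometric test
  got <- fisher_exact_2x3(c(3, 0, 10), c(9, 0, 4))
  want <- stats::fisher.test(matrix(c(3, 10, 9, 4), 2, byrow = TRUE))$p.value
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(fisher_exact_2x3(c(1.5, 2, 3), c(1, 2, 3)), "round")
  expect_error(fisher_exact_2x3(c(-1, 2, 3), c(1, 2, 3)), "non-negative")
})

test_that("the exact test never exceeds its nominal size under multinomial
           null sampling", {
  # comparing a multinomial draw against its own fixed expected row is a
  # conservative design: the expected row enters the margins, so the
  # conditional reference tracks (obs + exp) / 2 and absorbs half of any
  # deviation. The rejection rate must therefore sit well below nominal —
  # it can never be anti-conservative.
  set.seed(606)
  ex <- expected_movements(0.12, 0.12, 120)
  probs <- ex$expected / sum(ex$expected)
  n_rep <- 400
  rej <- 0
  for (i in seq_len(n_rep)) {
    obs <- as.vector(stats::rmultinom(1, 120, probs))
    p <- fisher_exact_2x3(obs, round(ex$expected))
    if (p < 0.05) rej <- rej + 1
  }
  expect_lt(rej / n_rep, 0.05)
})
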