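# small in-code fixtures shared across test files

toy_catalog <- function(genes, lengths = NULL, label = "toy", ...) {
  genes <- tibble::as_tibble(genes)
  if (is.null(lengths)) {
    lengths <- stats::aggregate(end ~ chrom, data = genes,
                                FUN = function(x) max(x) + 1000)
    names(lengths) <- c("chrom", "length")
  }
  gene_catalog(genes, lengths, label, ...)
}

# a catalog of n equally spaced genes on one chromosome
run_of_genes <- function(n, chrom = "chr1", prefix = "g", spacing = 1000,
                         width = 500, label = "toy") {
  toy_catalog(tibble::tibble(
    gene_id = paste0(prefix, seq_len(n)), chrom = chrom,
    start = (seq_len(n) - 1) * spacing,
    end = (seq_len(n) - 1) * spacing + width
  ), label = label)
}

hit_row <- function(q, s, identity = 80, evalue = 1e-50, bitscore = 200) {
  tibble::tibble(query_id = q, subject_id = s, pct_identity = identity,
                 evalue = evalue, bitscore = bitscore)
}

# random hit tables for property tests: n_a queries, n_b subjects.
# score_consistent = TRUE derives the e-value from the bitscore (monotone,
# as in real search output); FALSE draws them independently.
random_hits <- function(n_a, n_b, n_hits, score_consistent = FALSE) {
  bitscore <- round(stats::runif(n_hits, 50, 500), 1)
  evalue <- if (score_consistent) 10^(-bitscore / 5) else
    10^stats::runif(n_hits, -100, -5)
  tibble::tibble(
    query_id = paste0("a", sample.int(n_a, n_hits, replace = TRUE)),
    subject_id = paste0("b", sample.int(n_b, n_hits, replace = TRUE)),
    pct_identity = stats::runif(n_hits, 10, 100),
    evalue = evalue,
    bitscore = bitscore
  )
}

# definitional rBBH oracle: for each gene enumerate its hits, find the best
# by the documented cascade, and pair mutual bests passing the identity rule
rbbh_oracle <- function(hits_ab, hits_ba, max_evalue = 1e-10,
                        min_identity = 30) {
  best_of <- function(hits, q) {
    h <- hits[hits$query_id == q & hits$evalue < max_evalue, ]
    if (nrow(h) == 0) return(NA_character_)
    h <- h[order(-h$bitscore, h$evalue, -h$pct_identity, h$subject_id), ]
    if (h$pct_identity[1] <= min_identity) return(NA_character_)
    h$subject_id[1]
  }
  pairs <- list()
  for (a in unique(hits_ab$query_id)) {
    b <- best_of(hits_ab, a)
    if (is.na(b)) next
    if (identical(best_of(hits_ba, b), a)) {
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (length(pairs) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  m <- do.call(rbind, pairs)
  tibble::tibble(gene_a = m[, 1], gene_b = m[, 2]) |> dplyr::arrange(gene_a)
}

# exhaustive maximum monotone chain (DFS over all chains, both orientations)
max_chain_oracle <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  for (dir in c(1L, -1L)) {
    ord <- order(ra)
    extend <- function(i, len) {
      best <<- max(best, len)
      for (j in ord) {
        if (ra[j] > ra[i] && ra[j] - ra[i] <= max_gap &&
            (rb[j] - rb[i]) * dir > 0 && abs(rb[j] - rb[i]) <= max_gap) {
          extend(j, len + 1L)
        }
      }
    }
    for (i in ord) extend(i, 1L)
  }
  best
}

# valid-chain checker: strictly monotone in both ranks, gaps bounded
is_valid_chain <- function(anchors_tbl, orientation, max_gap) {
  ra <- anchors_tbl$rank_a
  rb <- anchors_tbl$rank_b
  o <- order(ra)
  ra <- ra[o]; rb <- rb[o]
  dra <- diff(ra)
  drb <- diff(rb)
  ok_a <- all(dra > 0) && all(dra <= max_gap)
  ok_b <- if (orientation == "same") all(drb > 0) && all(drb <= max_gap)
    else all(drb < 0) && all(-drb <= max_gap)
  ok_a && ok_b
}
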