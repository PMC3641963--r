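test_that("fractional methylation is c/(c+t) with coverage handling", {
  expect_equal(fractional_methylation(3, 1), 0.75)
  expect_equal(fractional_methylation(0, 5), 0)
  expect_true(is.na(fractional_methylation(0, 0)))
  expect_equal(fractional_methylation(c(3, 0, 0), c(1, 5, 0)),
               c(0.75, 0, NA))
  # min_coverage drops thin sites instead of erroring
  expect_true(is.na(fractional_methylation(1, 1, min_coverage = 5)))
  expect_error(fractional_methylation(-1, 2), "non-negative")
})

test_that("longest-transcript selection with deterministic tie-break", {
  tx <- make_transcripts(
    gene_id = c("gA", "gB", "gB", "gC", "gC"),
    tx_id = c("a1", "b2", "b1", "c2", "c1"),
    start = c(1, 100, 100, 900, 900),
    end = c(50, 5099, 2099, 1899, 1899))
  sel <- select_longest_transcript(tx)
  got <- S4Vectors::mcols(sel)
  expect_equal(got$gene_id, c("gA", "gB", "gC"))
  # single transcript -> itself; 5000 beats 2000
  expect_equal(got$tx_id[1:2], c("a1", "b2"))
  # equal lengths -> lexicographically smallest id, matching an oracle
  # that enumerates all of gC's transcripts
  cand <- got$tx_id[3]
  ids <- c("c2", "c1")
  widths <- c(1000, 1000)
  oracle <- sort(ids[widths == max(widths)])[1]
  expect_equal(cand, oracle)
  expect_error(select_longest_transcript(tx[0]), "empty")
})

test_that("promoter windows are strand-aware and clipped", {
  # plus strand, TSS at 0-based 10000: window [8500, 10500) 0-based
  g <- make_transcripts("g1", "t1", start = 10001, end = 20000, strand = "+")
  p <- promoter_interval(g)
  expect_equal(GenomicRanges::start(p), 8501)
  expect_equal(GenomicRanges::end(p), 10500)
  # minus strand, TSS at 0-based 10000 (txEnd): window [9500, 11500)
  g2 <- make_transcripts("g2", "t2", start = 2001, end = 10000, strand = "-")
  p2 <- promoter_interval(g2)
  expect_equal(GenomicRanges::start(p2), 9501)
  expect_equal(GenomicRanges::end(p2), 11500)
  # strand reflection oracle: the minus-strand window is the plus-strand
  # window mirrored through the TSS
  tss_plus <- 10000; w_plus <- c(tss_plus - 1500, tss_plus + 500)
  tss_minus <- 10000
  w_minus_oracle <- c(tss_minus - (w_plus[2] - tss_plus),
                      tss_minus + (tss_plus - w_plus[1]))
  expect_equal(c(GenomicRanges::start(p2) - 1, GenomicRanges::end(p2)),
               w_minus_oracle)
  # clipping at the chromosome start
  g3 <- make_transcripts("g3", "t3", start = 1001, end = 5000, strand = "+")
  p3 <- promoter_interval(g3)
  expect_equal(GenomicRanges::start(p3), 1)
  expect_equal(GenomicRanges::end(p3), 1500)
  g4 <- make_transcripts("g4", "t4", start = 1, end = 100, strand = "*")
  expect_error(promoter_interval(g4), "strand")
})

test_that("TE masking partitions the gene body exactly", {
  body <- make_granges(1, 100)          # 0-based [0, 100)
  # no TEs: non-TE part is the body
  m0 <- mask_te(body, make_granges(integer(0), integer(0)))
  expect_equal(sum(GenomicRanges::width(m0$non_te)), 100)
  expect_length(m0$te, 0)
  # TE covering the whole body
  m1 <- mask_te(body, make_granges(1, 100))
  expect_length(m1$non_te, 0)
  expect_equal(sum(GenomicRanges::width(m1$te)), 100)
  # overlapping TEs [10,20) + [15,30) merge to [10,30): 80 non-TE bases,
  # confirmed by the per-base membership oracle
  tes <- make_granges(c(11, 16), c(20, 30))
  m2 <- mask_te(body, tes)
  expect_equal(sum(GenomicRanges::width(m2$non_te)),
               nonte_bases_oracle(0, 100, c(10, 15), c(20, 30)))
  expect_equal(sum(GenomicRanges::width(m2$non_te)), 80)
})

test_that("partition conservation holds on random TE layouts", {
  set.seed(42)
  for (i in 1:25) {
    b0 <- sample(1000, 1); b1 <- b0 + sample(200:2000, 1)
    body <- make_granges(b0, b1)
    k <- sample(0:6, 1)
    if (k > 0) {
      ts <- sort(sample(b0:(b1 + 50), k))
      te <- make_granges(ts, ts + sample(10:300, k, replace = TRUE))
    } else {
      te <- make_granges(integer(0), integer(0))
    }
    m <- mask_te(body, te)
    te_in_body <- sum(GenomicRanges::width(
      GenomicRanges::intersect(body, GenomicRanges::reduce(te),
                               ignore.strand = TRUE)))
    expect_equal(sum(GenomicRanges::width(m$non_te)) + te_in_body,
                 sum(GenomicRanges::width(body)))
  }
})

test_that("feature aggregation equals the per-site brute-force loop", {
  # hand examples: mean of {0.2, 0.4, 0.9} is 0.5; empty feature is NA
  calls <- data.frame(chrom = "chrT", pos = c(10, 20, 30),
                      strand = "+", c_reads = c(2, 4, 9),
                      t_reads = c(8, 6, 1))
  feats <- make_granges(c(1, 500), c(100, 600))
  S4Vectors::mcols(feats)$feature_id <- c("f1", "f2")
  agg <- aggregate_feature(calls, feats)
  expect_equal(agg$meth, c(0.5, NA))
  expect_equal(agg$n_sites, c(3L, 0L))

  # 50-site random fixture against the site loop oracle
  set.seed(7)
  calls2 <- data.frame(
    chrom = "chrT", pos = sample(1000, 50),
    strand = sample(c("+", "-"), 50, TRUE),
    c_reads = rbinom(50, 20, 0.4), t_reads = rbinom(50, 20, 0.6))
  f2 <- make_granges(c(1, 301, 801), c(300, 800, 1000))
  S4Vectors::mcols(f2)$feature_id <- c("a", "b", "c")
  agg2 <- aggregate_feature(calls2, f2)
  for (i in 1:3) {
    expect_equal(agg2$meth[i],
                 aggregate_oracle(calls2, GenomicRanges::start(f2)[i],
                                  GenomicRanges::end(f2)[i]))
  }
})

test_that("aggregation is invariant to row order and table chunking", {
  set.seed(11)
  calls <- data.frame(
    chrom = "chrT", pos = sample(5000, 300),
    strand = sample(c("+", "-"), 300, TRUE),
    c_reads = rbinom(300, 30, 0.7), t_reads = rbinom(300, 30, 0.3))
  tx <- make_transcripts("g1", "t1", 2000, 4500, strand = "+")
  tes <- make_granges(2600, 3000)
  ref <- feature_methylation(calls, tx, tes)
  shuf <- feature_methylation(calls[sample(nrow(calls)), ], tx, tes)
  expect_equal(ref, shuf)
  # chunked aggregation: recombining per-chunk sums reproduces the total
  idx <- seq_len(nrow(calls)) %% 3
  parts <- lapply(0:2, function(k) {
    fm <- feature_methylation(calls[idx == k, ], tx, tes)
    c(s = fm$body_meth * fm$body_n, n = fm$body_n)
  })
  s <- sum(vapply(parts, function(p) ifelse(is.na(p["s"]), 0, p["s"]), 1))
  n <- sum(vapply(parts, `[`, 1, "n"))
  expect_equal(s / n, ref$body_meth)
})

test_that("full summarisation recovers planted feature truths", {
  cfg <- sim_config(n_genes = 120, seed = 31, coverage_mean = 40)
  tr <- simulate_truth(cfg)
  ann <- simulate_annotations(cfg, tr)
  calls <- simulate_methylome(cfg, ann, tr)
  fm <- feature_methylation(calls, ann$genes, ann$tes)
  m <- merge(fm, tr, by = "gene_id", suffixes = c("_est", "_true"))
  expect_gt(cor(m$body_meth_est, m$body_meth_true, use = "complete.obs"),
            0.95)
  expect_gt(cor(m$promoter_meth_est, m$promoter_meth_true,
                use = "complete.obs"), 0.98)
  expect_gt(cor(m$te_meth_est, m$te_meth_true, use = "complete.obs"), 0.75)
})
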