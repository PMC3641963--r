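test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(te_fraction = 1), "te_fraction")
  expect_error(sim_config(te_fraction = -0.1), "te_fraction")
  expect_error(sim_config(coverage_mean = 0), "coverage_mean")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(beta = 1:3), "beta")
})

test_that("truth table respects its invariants", {
  cfg <- sim_config(n_genes = 300, seed = 5)
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr), 300)
  expect_true(all(tr$abundance > 0))
  expect_true(all(tr$body_meth >= 0 & tr$body_meth <= 1))
  expect_true(all(tr$promoter_meth >= 0 & tr$promoter_meth <= 1))
  expect_true(all(tr$te_meth >= 0 & tr$te_meth <= 1))
  expect_true(all(tr$length >= 1))
  expect_false(anyDuplicated(tr$gene_id) > 0)
})

test_that("annotations: TE coverage tracks te_fraction, bodies do not overlap", {
  cfg <- sim_config(n_genes = 100, te_fraction = 0.3, seed = 1)
  tr <- simulate_truth(cfg)
  ann <- simulate_annotations(cfg, tr)
  bodies <- select_longest_transcript(ann$genes)
  # brute-force base counting of TE coverage inside bodies
  te_in_body <- GenomicRanges::intersect(ann$tes, bodies,
                                         ignore.strand = TRUE)
  cover <- sum(GenomicRanges::width(te_in_body)) /
    sum(GenomicRanges::width(bodies))
  expect_lt(abs(cover - 0.3), 0.05)
  ov <- GenomicRanges::findOverlaps(bodies, drop.self = TRUE,
                                    ignore.strand = TRUE)
  expect_length(ov, 0)
  # some genes carry a strict sub-interval second transcript
  expect_gt(length(ann$genes), length(bodies))
})

test_that("te_fraction = 0 yields an empty TE set", {
  cfg <- sim_config(n_genes = 20, te_fraction = 0, seed = 2)
  ann <- simulate_annotations(cfg)
  expect_length(ann$tes, 0)
})

test_that("generators are deterministic given config and seed", {
  cfg <- sim_config(n_genes = 40, seed = 9)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$calls, s2$calls)
  expect_identical(unclass(s1$expression), unclass(s2$expression))
  expect_identical(s1$nested, s2$nested)
})

test_that("degenerate methylation truths force degenerate read counts", {
  cfg <- sim_config(n_genes = 10, seed = 4, te_fraction = 0.2)
  tr <- simulate_truth(cfg)
  ann <- simulate_annotations(cfg, tr)
  tr0 <- tr
  tr0$body_meth <- 0; tr0$promoter_meth <- 0; tr0$te_meth <- 0
  calls0 <- simulate_methylome(cfg, ann, tr0)
  expect_true(all(calls0$c_reads == 0))
  tr1 <- tr
  tr1$body_meth <- 1; tr1$promoter_meth <- 1; tr1$te_meth <- 1
  calls1 <- simulate_methylome(cfg, ann, tr1)
  expect_true(all(calls1$t_reads == 0))
})

test_that("a missing truth row is an error", {
  cfg <- sim_config(n_genes = 5, seed = 4)
  tr <- simulate_truth(cfg)
  ann <- simulate_annotations(cfg, tr)
  expect_error(simulate_methylome(cfg, ann, tr[-3, ]), "missing truth")
})

test_that("aggregated body methylation converges to its truth value", {
  # one long TE-free gene, ~300 body sites at coverage 30: binomial SE of
  # the aggregate is ~0.003, so 0.6 +/- 0.03 is a ~5-sigma band
  cfg <- sim_config(n_genes = 1, te_fraction = 0, coverage_mean = 30,
                    cpg_density = 10, seed = 21)
  tr <- simulate_truth(cfg)
  tr$length <- 40000L
  tr$body_meth <- 0.6
  ann <- simulate_annotations(cfg, tr)
  calls <- simulate_methylome(cfg, ann, tr)
  fm <- feature_methylation(calls, ann$genes, ann$tes)
  expect_gte(fm$body_n, 200)
  expect_lt(abs(fm$body_meth - 0.6), 0.03)
})

test_that("expression generator enforces its preconditions", {
  cfg <- sim_config(n_genes = 10, n_arrays = 20, seed = 3)
  tr <- simulate_truth(cfg)
  cfg1 <- cfg; cfg1$n_arrays <- 1L
  expect_error(simulate_expression(cfg1, tr), "n_arrays")
  tr_bad <- tr; tr_bad$abundance[2] <- -1
  expect_error(simulate_expression(cfg, tr_bad), "positive")
})

test_that("degenerate linear predictor pins the target CV", {
  cfg <- sim_config(n_genes = 50, noise_sd = 0,
                    beta = c(-1.2, 0, 0, 0, 0), seed = 6)
  tr <- simulate_truth(cfg)
  expect_equal(tr$log_cv, rep(-1.2, 50))
  expect_equal(exp(unique(tr$log_cv)), exp(-1.2))
})

test_that("replicate draws hit the planted mean and CV marginally", {
  cfg <- sim_config(n_genes = 5, n_arrays = 4000, noise_sd = 0, seed = 8)
  tr <- simulate_truth(cfg)
  mat <- simulate_expression(cfg, tr)
  emp_cv <- apply(mat, 1, sd) / rowMeans(mat)
  expect_lt(max(abs(rowMeans(mat) / tr$abundance - 1)), 0.1)
  expect_lt(max(abs(emp_cv / exp(tr$log_cv) - 1)), 0.15)
})

test_that("nested generator validates the replicate structure", {
  cfg <- sim_config(n_genes = 10, n_bio = 1, seed = 2)
  tr <- simulate_truth(cfg)
  expect_error(simulate_nested_replicates(cfg, tr), "n_bio")
  cfg2 <- sim_config(n_genes = 10, n_tech = 1, seed = 2)
  expect_error(simulate_nested_replicates(cfg2, simulate_truth(cfg2)),
               "n_tech|n_bio")
})

test_that("zero variance components collapse the right sum of squares", {
  cfg <- sim_config(n_genes = 50, seed = 13)
  tr <- simulate_truth(cfg)
  # no technical noise: technical replicates identical within a sample
  nt <- simulate_nested_replicates(cfg, tr, sigma_tech = 0)
  dt <- decompose_replicates(nt)
  expect_true(all(abs(dt$ss_tech) < 1e-18))
  # neither component: every sum of squares is exactly zero
  n0 <- simulate_nested_replicates(cfg, tr, sigma_bio = 0, sigma_tech = 0)
  d0 <- decompose_replicates(n0)
  expect_true(all(d0$ss_total == 0 & d0$ss_bio == 0 & d0$ss_tech == 0))
})

test_that("doubling sigma_bio quadruples the biological sum of squares", {
  cfg <- sim_config(n_genes = 4000, seed = 17)
  tr <- simulate_truth(cfg)
  d1 <- decompose_replicates(
    simulate_nested_replicates(cfg, tr, sigma_bio = 0.5, sigma_tech = 0))
  cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
  d2 <- decompose_replicates(
    simulate_nested_replicates(cfg2, tr, sigma_bio = 1.0, sigma_tech = 0))
  expect_lt(abs(mean(d2$ss_bio) / mean(d1$ss_bio) - 4), 0.4)
})
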