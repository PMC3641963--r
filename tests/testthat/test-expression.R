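make_correlated_arrays <- function(n_genes = 200, n_good = 5, seed = 1) {
  set.seed(seed)
  base <- rlnorm(n_genes, log(200), 1)
  good <- vapply(seq_len(n_good),
                 function(i) base * rlnorm(n_genes, 0, 0.05),
                 numeric(n_genes))
  colnames(good) <- sprintf("good%02d", seq_len(n_good))
  rownames(good) <- sprintf("g%04d", seq_len(n_genes))
  good
}

test_that("qc keeps mutually correlated arrays and drops the stray one", {
  good <- make_correlated_arrays(seed = 3)
  noise <- rlnorm(nrow(good), log(200), 1)   # independent of the rest
  mat <- cbind(good, stray = noise)
  qc <- qc_filter(mat, threshold = 0.8)
  expect_false("stray" %in% colnames(qc$matrix))
  expect_equal(ncol(qc$matrix), 5)
  # exhaustive pairwise-correlation oracle: the removed array is the one
  # whose median correlation with the others is lowest
  cc <- cor(log2(mat + 1)); diag(cc) <- NA
  med <- apply(cc, 2, median, na.rm = TRUE)
  expect_equal(names(which.min(med)), "stray")
  rep <- qc$report
  expect_false(rep$kept[rep$array == "stray"])
})

test_that("qc edge cases: identical arrays, vacuous threshold, starvation", {
  good <- make_correlated_arrays(seed = 4)
  same <- cbind(a = good[, 1], b = good[, 1], c = good[, 1])
  qc <- qc_filter(same, threshold = 0.8)
  expect_equal(ncol(qc$matrix), 3)
  # threshold -1 never removes anything
  set.seed(5)
  junk <- matrix(rlnorm(400), 100, 4,
                 dimnames = list(NULL, paste0("a", 1:4)))
  expect_equal(ncol(qc_filter(junk, threshold = -1)$matrix), 4)
  expect_error(qc_filter(good[, 1, drop = FALSE]), "2 arrays")
  expect_error(qc_filter(junk, threshold = 0.999), "survive")
})

test_that("quantile normalization equalises array distributions", {
  # worked example: arrays (1,2,3) and (4,5,6) both become (2.5,3.5,4.5)
  m <- cbind(a = c(1, 2, 3), b = c(6, 5, 4))
  qn <- quantile_normalize(m)
  expect_equal(sort(qn[, "a"]), sort(qn[, "b"]))
  expect_equal(unname(sort(qn[, "a"])), c(2.5, 3.5, 4.5))
  # identical arrays are a fixed point
  m2 <- cbind(a = c(2, 7, 5), b = c(2, 7, 5))
  expect_equal(as.vector(quantile_normalize(m2)), as.vector(m2))
  # random matrix: sorted columns identical to machine precision,
  # within-array rank order preserved
  set.seed(8)
  m3 <- matrix(rlnorm(600), 100, 6)
  qn3 <- quantile_normalize(m3)
  ref <- sort(qn3[, 1])
  for (j in 2:6) expect_equal(sort(qn3[, j]), ref, tolerance = 1e-12)
  for (j in 1:6) expect_equal(rank(qn3[, j]), rank(m3[, j]))
  m3[5, 2] <- NA
  expect_error(quantile_normalize(m3), "missing")
})

test_that("CV noise table follows the definition", {
  m <- rbind(const = c(5, 5, 5, 5), two = c(1, 3, 1, 3))
  nz <- expression_noise(m)
  expect_equal(nz$cv[nz$gene_id == "const"], 0)
  # two-point formula on (1,3): mean 2, sd sqrt(2) -> cv = 0.7071
  g <- expression_noise(rbind(g1 = c(1, 3)))
  expect_equal(g$mean_abundance, 2)
  expect_equal(g$cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_true(is.na(nz$log_cv[nz$gene_id == "const"]))
  expect_error(expression_noise(matrix(1:3, ncol = 1)), "2 arrays")
  expect_warning(expression_noise(rbind(a = c(1, 2), b = c(0, 0))),
                 "non-positive")
})

test_that("CV is invariant to positive rescaling of a gene", {
  set.seed(9)
  x <- rlnorm(10, 3, 0.4)
  cv1 <- expression_noise(rbind(g = x))$cv
  cv2 <- expression_noise(rbind(g = 7.3 * x))$cv
  expect_equal(cv1, cv2, tolerance = 1e-14)
})

test_that("count noise reproduces the -1/2 scaling of log CV on log mean", {
  mat <- simulate_count_matrix(n_genes = 1500, n_arrays = 20, seed = 5)
  nz <- expression_noise(mat)
  fit <- fit_ols(log_cv ~ log_abundance, nz)
  slope <- fit$coefficients$estimate[2]
  expect_lt(abs(slope - (-0.5)), 0.05)
})
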