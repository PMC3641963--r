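# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (per-base loops, exhaustive
# enumeration, auxiliary regressions) and never call the implementation
# under test.

# Mann-Whitney two-sided p by full enumeration of which pooled positions
# belong to sample x (no ties assumed).
mw_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Exact check-loss minimum by enumerating every p-subset basis solution
# (the vertices of the quantile-regression linear program).
qr_bruteforce_objective <- function(X, y, tau) {
  p <- ncol(X)
  best <- Inf
  combs <- combn(nrow(X), p)
  for (k in seq_len(ncol(combs))) {
    S <- combs[, k]
    b <- tryCatch(solve(X[S, , drop = FALSE], y[S]),
                  error = function(e) NULL)
    if (is.null(b) || any(!is.finite(b))) next
    r <- y - drop(X %*% b)
    obj <- sum(r * (tau - (r < 0)))
    if (obj < best) best <- obj
  }
  best
}

# VIF by the definitional auxiliary regression of each predictor on all the
# others (with intercept).
vif_aux_regression <- function(P) {
  vapply(seq_len(ncol(P)), function(j) {
    r2 <- summary(lm(P[, j] ~ P[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# Per-base membership oracle: how many body bases (0-based half-open
# [start0, end0)) are NOT covered by any TE interval (0-based half-open).
nonte_bases_oracle <- function(start0, end0, te_start0, te_end0) {
  bases <- start0:(end0 - 1L)
  covered <- rep(FALSE, length(bases))
  for (k in seq_along(te_start0)) {
    covered <- covered | (bases >= te_start0[k] & bases < te_end0[k])
  }
  sum(!covered)
}

# Per-site aggregation oracle: loop over calls, keep covered sites inside
# the 1-based closed interval [lo, hi], average c/(c+t).
aggregate_oracle <- function(calls, lo, hi, min_coverage = 1L) {
  vals <- c()
  for (i in seq_len(nrow(calls))) {
    tot <- calls$c_reads[i] + calls$t_reads[i]
    if (tot < max(1L, min_coverage)) next
    if (calls$pos[i] >= lo && calls$pos[i] <= hi) {
      vals <- c(vals, calls$c_reads[i] / tot)
    }
  }
  if (length(vals)) mean(vals) else NA_real_
}

# Small GRanges transcript-set builder (1-based closed coordinates).
make_transcripts <- function(gene_id, tx_id, start, end,
                             strand = "+", chrom = "chrT") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start, end = end),
                               strand = rep_len(strand, length(start)))
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$tx_id <- tx_id
  gr
}

make_granges <- function(start, end, chrom = "chrT", strand = "*") {
  GenomicRanges::GRanges(rep_len(chrom, length(start)),
                         IRanges::IRanges(start = start, end = end),
                         strand = rep_len(strand, length(start)))
}
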