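#' Paired t test (closed form)
#'
#' Classical paired t statistic on per-gene differences:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-sided p
#' value. Zero variance of the differences (e.g. identical vectors) is an
#' error, not a silent zero.
#'
#' @param x,y equal-length paired numeric vectors (n >= 2).
#' @return list: `statistic`, `df`, `p.value`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired",
                                   call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  s <- sd(d)
  if (s == 0) stop("zero variance of differences: paired t undefined",
                   call. = FALSE)
  tstat <- mean(d) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1L,
       p.value = 2 * pt(abs(tstat), df = n - 1L, lower.tail = FALSE),
       n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic for `x`
#' is computed from mid-ranks of the pooled data. The p value is exact
#' (from the null U distribution) when the smaller sample has at most 20
#' observations and there are no ties; otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p value;
#'   default chooses by sample size and ties as above.
#' @return list: `statistic` (U for `x`), `p.value`, `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty",
                                 call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- length(unique(c(x, y))) < nx + ny
  if (is.null(exact)) exact <- min(nx, ny) <= 20L && !ties
  if (exact && ties) {
    stop("exact p value is unavailable with ties", call. = FALSE)
  }
  if (exact) {
    # two-sided doubling of the smaller exact tail of the U distribution
    lo <- pwilcox(U, nx, ny)
    hi <- pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- nx * ny / 12 *
      ((nx + ny + 1) - sum(tie_tab^3 - tie_tab) /
         ((nx + ny) * (nx + ny - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (sigma2 == 0) z <- 0
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = U, p.value = p, method = method)
}

#' Build the shared-gene paired table for two tissues
#'
#' Intersects two per-gene tables on exact gene id and keeps only genes
#' with complete noise and body-methylation values in both tissues.
#'
#' @param a,b data.frames with columns `gene_id`, `log_cv` (or `cv`) and
#'   `body_meth`.
#' @return data.frame: `gene_id`, `noise_a`, `noise_b`, `meth_a`, `meth_b`.
#' @export
make_paired_table <- function(a, b) {
  noise_col <- function(d) if ("log_cv" %in% names(d)) d$log_cv else d$cv
  da <- data.frame(gene_id = a$gene_id, noise_a = noise_col(a),
                   meth_a = a$body_meth, stringsAsFactors = FALSE)
  db <- data.frame(gene_id = b$gene_id, noise_b = noise_col(b),
                   meth_b = b$body_meth, stringsAsFactors = FALSE)
  m <- merge(da, db, by = "gene_id")
  m[complete.cases(m), , drop = FALSE]
}

#' Between-tissue comparison of noise and methylation
#'
#' On the genes shared between two tissues, compares transcriptional noise
#' and gene body methylation with both a paired t test and a Mann-Whitney
#' test, reported side by side.
#'
#' @param a,b per-gene tables for the two tissues (see
#'   [make_paired_table()]).
#' @param labels character(2) tissue names for the report.
#' @return data.frame report: `quantity`, `test`, `statistic`, `df`, `p`,
#'   `n_shared`.
#' @export
compare_tissues <- function(a, b, labels = c("tissueA", "tissueB")) {
  tab <- make_paired_table(a, b)
  n <- nrow(tab)
  if (n < 2L) stop("fewer than 2 shared genes", call. = FALSE)
  rows <- list()
  for (q in c("noise", "meth")) {
    va <- tab[[paste0(q, "_a")]]
    vb <- tab[[paste0(q, "_b")]]
    pt_res <- paired_t(va, vb)
    mw_res <- mann_whitney(va, vb)
    rows[[paste0(q, "_t")]] <- data.frame(
      quantity = q, test = "paired t", statistic = pt_res$statistic,
      df = pt_res$df, p = pt_res$p.value, n_shared = n)
    rows[[paste0(q, "_mw")]] <- data.frame(
      quantity = q, test = "Mann-Whitney", statistic = mw_res$statistic,
      df = NA_integer_, p = mw_res$p.value, n_shared = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}
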