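#' Quality-control filter of replicate arrays by pairwise correlation
#'
#' Only arrays agreeing well with the other replicates of the same tissue
#' are retained: Pearson correlations are computed between all array pairs
#' on log2 intensities, and the array with the lowest median correlation to
#' the others is removed, iteratively, until every retained array's median
#' pairwise correlation exceeds `threshold`. Iterative worst-first removal
#' makes the result deterministic and independent of array order.
#'
#' @param mat genes x arrays numeric matrix of positive intensities.
#' @param threshold minimum acceptable median pairwise correlation
#'   (default 0.8).
#' @return list of class `"methnoise_qc"`: `matrix` (retained arrays, with
#'   `qc_state = "filtered"`) and `report` (data.frame with `array`,
#'   `median_cor` at the time of the decision, and `kept`).
#' @export
qc_filter <- function(mat, threshold = 0.8) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 arrays", call. = FALSE)
  if (any(mat < 0)) stop("negative intensities", call. = FALSE)
  lmat <- log2(mat + 1)
  removed <- character(0)
  removed_cor <- numeric(0)
  repeat {
    cc <- cor(lmat)
    diag(cc) <- NA
    med <- apply(cc, 2, median, na.rm = TRUE)
    if (min(med) > threshold) break
    worst <- which.min(med)
    removed <- c(removed, colnames(lmat)[worst])
    removed_cor <- c(removed_cor, med[worst])
    lmat <- lmat[, -worst, drop = FALSE]
    mat <- mat[, -worst, drop = FALSE]
    if (ncol(mat) < 2L) {
      stop("fewer than 2 arrays survive QC at threshold ", threshold,
           call. = FALSE)
    }
  }
  cc <- cor(lmat); diag(cc) <- NA
  kept_cor <- apply(cc, 2, median, na.rm = TRUE)
  report <- data.frame(
    array = c(colnames(mat), removed),
    median_cor = c(kept_cor, removed_cor),
    kept = c(rep(TRUE, ncol(mat)), rep(FALSE, length(removed))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(mat, "qc_state") <- "filtered"
  structure(list(matrix = mat, report = report), class = "methnoise_qc")
}

#' Quantile normalization of an expression matrix
#'
#' Forces every array to share the same value distribution: each value is
#' replaced by the across-array mean of the order statistics at its rank,
#' ties receiving the mean reference value over their rank span. Conducted
#' within one tissue at a time. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat genes x arrays numeric matrix (complete; `NA` is an error).
#' @return normalized matrix with `qc_state = "normalized"`.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values: complete matrices only",
                       call. = FALSE)
  if (ncol(mat) < 2L) stop("need at least 2 arrays", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  attr(out, "tissue") <- attr(mat, "tissue")
  attr(out, "qc_state") <- "normalized"
  out
}

#' Per-gene transcriptional noise (coefficient of variation)
#'
#' Transcriptional noise is approximated by the coefficient of variation of
#' a gene's expression across replicate arrays: the sample standard
#' deviation (n - 1 denominator) divided by the mean, computed on the
#' normalized (unlogged) intensities. CV and abundance are also returned on
#' the natural-log scale for the modelling layer; genes with non-positive
#' mean are dropped with a warning, and `log_cv` is `NA` for genes with
#' zero variance.
#'
#' @param mat genes x arrays matrix (>= 2 arrays), typically the output of
#'   [quantile_normalize()].
#' @return data.frame: `gene_id`, `mean_abundance`, `cv`, `log_abundance`,
#'   `log_cv`.
#' @export
expression_noise <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) {
    stop("CV needs at least 2 arrays", call. = FALSE)
  }
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  bad <- mu <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-positive mean dropped")
    mat <- mat[!bad, , drop = FALSE]
    mu <- mu[!bad]; s <- s[!bad]
  }
  cv <- s / mu
  data.frame(
    gene_id = if (!is.null(rownames(mat))) rownames(mat)
              else sprintf("g%05d", seq_along(mu)),
    mean_abundance = mu,
    cv = cv,
    log_abundance = log(mu),
    log_cv = ifelse(cv > 0, log(cv), NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
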