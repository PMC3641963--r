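#' Biological/technical variance decomposition of nested replicates
#'
#' For a gene measured in `n_tech` technical replicates within each of
#' `n_bio` biological samples, the total sum of squares around the grand
#' mean splits exactly into a biological and a technical component:
#' \deqn{\sum_{ij} (y_{ij} - \bar{\bar y})^2 =
#'   n_{tech} \sum_i (\bar y_i - \bar{\bar y})^2 +
#'   \sum_{ij} (y_{ij} - \bar y_i)^2.}
#' The first right-hand term is the biological sum of squares (between
#' biological samples) and the second the technical sum of squares (within
#' samples). The layout must be complete and balanced.
#'
#' @param nested long data.frame with columns `gene_id`, `bio`, `tech`,
#'   `value`.
#' @return data.frame per gene: `gene_id`, `ss_total`, `ss_bio`, `ss_tech`,
#'   `n_bio`, `n_tech`.
#' @export
#' @examples
#' d <- data.frame(gene_id = "g", bio = c(1, 1, 2, 2), tech = c(1, 2, 1, 2),
#'                 value = c(1, 3, 5, 7))
#' decompose_replicates(d)  # ss_total 20 = ss_bio 16 + ss_tech 4
decompose_replicates <- function(nested) {
  req <- c("gene_id", "bio", "tech", "value")
  if (!all(req %in% names(nested))) {
    stop("nested table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(nested$gene_id, nested$bio)
  n_tech <- unique(as.vector(tab))
  n_bio <- ncol(tab)
  if (length(n_tech) != 1L || n_tech < 1L) {
    stop("unbalanced layout: every gene needs the same technical replicate",
         " count in every biological sample", call. = FALSE)
  }
  if (n_bio < 2L || n_tech < 2L) {
    stop("decomposition needs >= 2 biological samples and >= 2 technical",
         " replicates", call. = FALSE)
  }
  key_g <- factor(nested$gene_id, levels = unique(nested$gene_id))
  key_gb <- interaction(key_g, nested$bio, drop = FALSE, lex.order = TRUE)

  grand <- tapply(nested$value, key_g, mean)
  bio_mean <- tapply(nested$value, key_gb, mean)
  gene_of_gb <- rep(levels(key_g), each = n_bio)

  y <- nested$value
  dev_tot <- y - grand[as.integer(key_g)]
  dev_tech <- y - bio_mean[as.integer(key_gb)]
  ss_total <- tapply(dev_tot^2, key_g, sum)
  ss_tech <- tapply(dev_tech^2, key_g, sum)
  dev_bio <- (bio_mean - grand[gene_of_gb])^2
  ss_bio <- n_tech * tapply(dev_bio, factor(gene_of_gb, levels(key_g)), sum)

  data.frame(
    gene_id = levels(key_g),
    ss_total = as.numeric(ss_total),
    ss_bio = as.numeric(ss_bio),
    ss_tech = as.numeric(ss_tech),
    n_bio = n_bio, n_tech = n_tech,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Merge decomposition with per-gene predictors and log-transform one SS
# column, dropping non-positive values with a warning.
prep_ss_response <- function(decomp, predictors, ss_col) {
  d <- merge(decomp, predictors, by = "gene_id")
  bad <- !is.finite(d[[ss_col]]) | d[[ss_col]] <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero ", ss_col,
            " dropped from the log-scale fit")
    d <- d[!bad, , drop = FALSE]
  }
  d[[paste0("log_", ss_col)]] <- log(d[[ss_col]])
  d
}

#' Model the biological variance component (model 1)
#'
#' OLS regression of the log biological sum of squares on log expression
#' abundance, gene body methylation and promoter methylation — asking
#' whether methylation predicts purely biological expression variability.
#'
#' @param decomp output of [decompose_replicates()].
#' @param predictors per-gene data.frame with `gene_id`, `log_abundance`,
#'   `body_meth`, `promoter_meth`.
#' @return a [fit_ols()] result.
#' @export
fit_biological_model <- function(decomp, predictors) {
  d <- prep_ss_response(decomp, predictors, "ss_bio")
  fit_ols(log_ss_bio ~ log_abundance + body_meth + promoter_meth, data = d)
}

#' Model total variation adjusted for technical noise (model 2)
#'
#' OLS regression of the log total sum of squares on log abundance, body
#' methylation, promoter methylation and the log technical sum of squares;
#' conditioning on the technical component isolates the biological part of
#' the methylation effect.
#'
#' @inheritParams fit_biological_model
#' @return a [fit_ols()] result.
#' @export
fit_technical_adjusted_model <- function(decomp, predictors) {
  d <- prep_ss_response(decomp, predictors, "ss_total")
  bad <- !is.finite(d$ss_tech) | d$ss_tech <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with zero ss_tech dropped")
    d <- d[!bad, , drop = FALSE]
  }
  d$log_ss_tech <- log(d$ss_tech)
  fit_ols(log_ss_total ~ log_abundance + body_meth + promoter_meth +
            log_ss_tech, data = d)
}
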