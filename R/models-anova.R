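#' Sequential-SS ANOVA with individual-by-methylation interaction
#'
#' Tests whether between-individual variability of gene body methylation
#' affects the noise model: log CV is regressed on expression abundance,
#' log gene length, gene body methylation, promoter methylation, an
#' individual factor, and the individual-by-body-methylation interaction,
#' in that fixed order, using sequential (Type I) sums of squares with F
#' tests against the residual mean square. A non-significant interaction
#' means the methylation effect is shared across individuals.
#'
#' @param data stacked data.frame with columns `log_cv`, `log_abundance`,
#'   `log_length`, `body_meth`, `promoter_meth`, `individual` (factor or
#'   character with >= 2 levels); see [simulate_individual_table()].
#' @return list of class `"methnoise_anova"`: `table` (data.frame `term`,
#'   `ss`, `df`, `f`, `p`), `adj_r2`, and the underlying `lm` in `$lm`.
#' @export
fit_individual_anova <- function(data) {
  req <- c("log_cv", "log_abundance", "log_length", "body_meth",
           "promoter_meth", "individual")
  if (!all(req %in% names(data))) {
    stop("data needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  data <- data[complete.cases(data[req]), , drop = FALSE]
  data$individual <- factor(data$individual)
  if (nlevels(data$individual) < 2L) {
    stop("'individual' needs at least 2 levels", call. = FALSE)
  }
  fml <- log_cv ~ log_abundance + log_length + body_meth + promoter_meth +
    individual + individual:body_meth
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit)) || fit$df.residual < 1L) {
    stop("no residual degrees of freedom: too few genes per individual",
         call. = FALSE)
  }
  at <- anova(fit)
  term_names <- sub("^body_meth:individual$", "individual:body_meth",
                    rownames(at))
  tab <- data.frame(
    term = term_names,
    ss = at$`Sum Sq`,
    df = at$Df,
    f = at$`F value`,
    p = at$`Pr(>F)`,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = tab, adj_r2 = summary(fit)$adj.r.squared,
                 lm = fit, n = nrow(data)),
            class = "methnoise_anova")
}

#' @export
print.methnoise_anova <- function(x, ...) {
  cat(sprintf("<methnoise_anova: n = %d, adj R2 = %.3f>\n", x$n, x$adj_r2))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
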