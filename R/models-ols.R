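#' Fitted regression result container
#'
#' All fitting functions return a `methnoise_fit`: a list with a per-term
#' `coefficients` data.frame (`term`, `estimate`, `se`, `t`, `p`, `vif`),
#' `adj_r2`, `method`, `n`, and convergence information.
#'
#' @param x a `methnoise_fit`.
#' @param ... ignored.
#' @export
print.methnoise_fit <- function(x, ...) {
  cat(sprintf("<methnoise_fit: %s, n = %d%s>\n", x$method, x$n,
              if (isTRUE(x$converged)) "" else ", NOT CONVERGED"))
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$adj_r2) && is.finite(x$adj_r2)) {
    cat(sprintf("Adjusted R-squared: %.4f\n", x$adj_r2))
  }
  invisible(x)
}

new_fit <- function(method, coefficients, adj_r2, n, converged = TRUE,
                    ...) {
  structure(list(method = method, coefficients = coefficients,
                 adj_r2 = adj_r2, n = n, converged = converged, ...),
            class = "methnoise_fit")
}

# Full-rank check with an informative error naming the collinear columns.
assert_full_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(qrx)
}

#' Ordinary least squares with VIF diagnostics
#'
#' Multiple linear regression with classical standard errors, two-sided t
#' tests, adjusted R-squared, and a variance inflation factor for every
#' non-intercept term. Rows with missing values are dropped
#' (complete-case analysis) and the count of dropped rows is recorded.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @return a `methnoise_fit` (method `"ols"`); the underlying `lm` object
#'   is kept in `$lm`.
#' @export
#' @examples
#' d <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
#' fit_ols(y ~ x, d)$coefficients
fit_ols <- function(formula, data) {
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  n_dropped <- nrow(data) - nrow(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  y <- model.response(mf)
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than model terms", call. = FALSE)
  }
  assert_full_rank(X)
  fit <- lm(formula, data = data, na.action = stats::na.omit)
  sm <- summary(fit)
  ct <- sm$coefficients
  vifs <- vif_from_matrix(X)
  coefs <- data.frame(
    term = rownames(ct),
    estimate = ct[, 1], se = ct[, 2], t = ct[, 3], p = ct[, 4],
    vif = vifs[rownames(ct)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  new_fit("ols", coefs, adj_r2 = sm$adj.r.squared, n = nrow(X),
          lm = fit, n_dropped = n_dropped, sigma = sm$sigma)
}

# VIFs from a model matrix (intercept column allowed and ignored):
# diagonal of the inverse correlation matrix of the predictors, the closed
# form of 1 / (1 - R^2_j) from regressing predictor j on the others.
vif_from_matrix <- function(X) {
  terms_all <- colnames(X)
  keep <- terms_all != "(Intercept)"
  out <- setNames(rep(NA_real_, length(terms_all)), terms_all)
  P <- X[, keep, drop = FALSE]
  if (ncol(P) == 0L) return(out)
  if (any(apply(P, 2, sd) == 0)) {
    stop("constant predictor column; VIF undefined", call. = FALSE)
  }
  if (ncol(P) == 1L) {
    out[keep] <- 1
    return(out)
  }
  R <- cor(P)
  v <- tryCatch(diag(solve(R)), error = function(e) rep(Inf, ncol(P)))
  v[v > 1e12] <- Inf
  out[keep] <- v
  if (any(is.finite(v) & v > 5)) {
    warning("VIF > 5 for: ",
            paste(colnames(P)[is.finite(v) & v > 5], collapse = ", "))
  }
  if (any(!is.finite(v))) {
    warning("perfect collinearity: infinite VIF for: ",
            paste(colnames(P)[!is.finite(v)], collapse = ", "))
  }
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all remaining predictors (with intercept). Computed via the
#' inverse of the predictor correlation matrix. A VIF above 5 signals
#' worrying multicollinearity and triggers a warning; perfect collinearity
#' is reported as `Inf`.
#'
#' @param x a formula (with `data`), a `methnoise_fit`, or a numeric matrix
#'   of predictors (no intercept column needed).
#' @param data data.frame when `x` is a formula.
#' @return named numeric vector of VIFs (one per non-intercept term).
#' @export
vif <- function(x, data = NULL) {
  if (inherits(x, "methnoise_fit")) {
    v <- x$coefficients$vif
    names(v) <- x$coefficients$term
    return(v[x$coefficients$term != "(Intercept)"])
  }
  if (inherits(x, "formula")) {
    mf <- model.frame(x, data, na.action = stats::na.omit)
    X <- model.matrix(attr(mf, "terms"), mf)
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  v <- vif_from_matrix(X)
  v[names(v) != "(Intercept)"]
}
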