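#' Check (pinball) loss of quantile regression
#'
#' `rho_tau(r) = r * (tau - 1(r < 0))`, summed over residuals. At
#' `tau = 0.5` this is half the absolute-error loss, whose minimizer is the
#' conditional median.
#'
#' @param r numeric residuals.
#' @param tau quantile level in (0, 1).
#' @return the summed loss.
#' @export
check_loss <- function(r, tau = 0.5) {
  sum(r * (tau - (r < 0)))
}

#' Quantile regression by smoothed IRLS with vertex polish
#'
#' Minimizes the check loss with an epsilon-smoothed iteratively reweighted
#' least squares core (weights `|tau - 1(r<0)| / max(|r|, eps)`), then
#' polishes the solution by exact interpolation: a check-loss minimizer
#' passes through `p` observations (a basis of the equivalent linear
#' program), so the `p`-subsets of the observations with smallest IRLS
#' residuals are enumerated, solved exactly and the best objective kept.
#' Standard errors come from a seeded xy-pair bootstrap.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param tau quantile level in (0, 1); 0.5 (median regression) by default.
#' @param eps smoothing floor for the IRLS weights.
#' @param maxit,tol IRLS iteration cap and coefficient-change tolerance.
#' @param nboot bootstrap replicates for standard errors (0 disables).
#' @param boot_seed seed of the bootstrap stream.
#' @return a `methnoise_fit` (method `"quantile"`) with `tau` and the
#'   attained `objective`.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 4, 8, 9))
#' fit_quantile(y ~ 1, d, nboot = 0)$coefficients$estimate  # the median 4
fit_quantile <- function(formula, data, tau = 0.5, eps = 1e-6,
                         maxit = 200L, tol = 1e-8,
                         nboot = 200L, boot_seed = 1L) {
  if (!is.numeric(tau) || tau <= 0 || tau >= 1) {
    stop("'tau' must lie strictly between 0 and 1", call. = FALSE)
  }
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  X <- model.matrix(attr(mf, "terms"), mf)
  y <- model.response(mf)
  assert_full_rank(X)
  sol <- qr_irls(X, y, tau, eps, maxit, tol, polish = TRUE)

  se <- rep(NA_real_, ncol(X))
  if (nboot > 0L) {
    n <- nrow(X)
    bcoef <- with_seed(sub_seed(boot_seed, "qr-boot"), {
      vapply(seq_len(nboot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        qr_irls(X[idx, , drop = FALSE], y[idx], tau, eps, maxit, tol,
                polish = FALSE, init = sol$coef)$coef
      }, numeric(ncol(X)))
    })
    se <- apply(matrix(bcoef, nrow = ncol(X)), 1, sd)
  }
  tval <- sol$coef / se
  pval <- 2 * pt(abs(tval), df = nrow(X) - ncol(X), lower.tail = FALSE)
  coefs <- data.frame(
    term = colnames(X),
    estimate = sol$coef, se = se, t = tval, p = pval, vif = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  vifs <- vif_from_matrix(X)
  coefs$vif <- vifs[coefs$term]
  new_fit("quantile", coefs, adj_r2 = NA_real_, n = nrow(X),
          converged = sol$converged, tau = tau, objective = sol$objective,
          nboot = nboot)
}

# IRLS core for the check loss; optional exact basis polish.
qr_irls <- function(X, y, tau, eps, maxit, tol, polish = TRUE,
                    init = NULL) {
  p <- ncol(X)
  b <- if (is.null(init)) qr.coef(qr(X), y) else init
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% b)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
    fitw <- stats::lm.wfit(X, y, w)
    b_new <- fitw$coefficients
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      converged <- TRUE
      break
    }
    b <- b_new
  }
  r <- y - drop(X %*% b)
  obj <- check_loss(r, tau)

  if (polish) {
    extra <- if (p <= 6L) 10L else 4L  # cap the enumeration for wide designs
    cand <- order(abs(r))[seq_len(min(nrow(X), p + extra))]
    combs <- combn(cand, p)
    for (k in seq_len(ncol(combs))) {
      S <- combs[, k]
      bk <- tryCatch(solve(X[S, , drop = FALSE], y[S]),
                     error = function(e) NULL)
      if (is.null(bk) || any(!is.finite(bk))) next
      ok <- check_loss(y - drop(X %*% bk), tau)
      if (ok < obj - 1e-12) {
        obj <- ok
        b <- bk
        converged <- TRUE
      }
    }
  }
  list(coef = setNames(as.numeric(b), colnames(X)), objective = obj,
       converged = converged)
}
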