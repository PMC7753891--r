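#' Ordinary least squares on a prepared design
#'
#' Fits the linear model by QR decomposition of the (already full-rank)
#' design matrix. Standard errors come from the unbiased residual variance
#' and the inverse cross-product; P-values are two-sided t-tests on the
#' residual degrees of freedom.
#'
#' @param design a `bca_design` from [build_design()], or a plain numeric
#'   matrix (then `response` must be given).
#' @param response numeric response vector when `design` is a matrix.
#' @return object of class `bca_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `r_squared`, `residual_df`,
#'   `vcov`, `sigma2`, `n_used`, `fitted`, `residuals`, `term_map`.
#' @export
fit_ols <- function(design, response = NULL) {
  if (inherits(design, "bca_design")) {
    X <- design$X
    y <- design$y
    term_map <- design$term_map
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    y <- response
    if (is.null(y)) bca_stop("response required when design is a matrix")
    term_map <- data.frame(column = colnames(X), term = colnames(X),
                           type = "fixed", stringsAsFactors = FALSE)
  }
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bca_stop("design matrix is rank deficient; build_design should have ",
             "dropped aliased columns")
  }
  df_res <- n - qx$rank
  if (df_res <= 0) bca_stop("zero residual degrees of freedom")
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  sigma2 <- rss / df_res
  # qr.R's columns follow qx$pivot; undo the pivot after inverting X'X
  piv <- qx$pivot
  XtX_inv <- chol2inv(qr.R(qx))[order(piv), order(piv), drop = FALSE]
  vcov <- sigma2 * XtX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  has_int <- "(Intercept)" %in% colnames(X)
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(coefficients = data.frame(term = colnames(X),
                                           estimate = unname(beta),
                                           se = unname(se), t = unname(tval),
                                           p = unname(pval),
                                           stringsAsFactors = FALSE),
                 r_squared = r2, residual_df = df_res, vcov = vcov,
                 sigma2 = sigma2, n_used = n, fitted = fitted,
                 residuals = resid, term_map = term_map),
            class = "bca_fit")
}

#' @export
print.bca_fit <- function(x, ...) {
  cat("OLS fit: n =", x$n_used, " rank =", nrow(x$coefficients),
      " R2 =", round(x$r_squared, 4), "\n")
  invisible(x)
}

# coefficient rows for the SNP terms of a fit
snp_coefficients <- function(fit) {
  stopifnot(inherits(fit, "bca_fit"))
  snp_cols <- fit$term_map$column[fit$term_map$type == "snp"]
  fit$coefficients[match(snp_cols, fit$coefficients$term), , drop = FALSE]
}
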