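#' SNP-based heritability by REML
#'
#' Fits `Var(y) = sigma_g^2 K + sigma_e^2 I` by restricted maximum
#' likelihood with fixed covariates, using the shared eigendecomposition
#' scheme of [reml_fit()], and reports
#' `h2_snp = sigma_g2 / (sigma_g2 + sigma_e2)` with a delta-method
#' standard error from the expected information matrix. Estimates on the
#' boundary (h2 ~ 0 or ~ 1) are flagged.
#'
#' `K` is typically a [weighted_kinship()] built from [ld_weights()], so
#' that redundantly tagged variants do not dominate the genetic
#' covariance.
#'
#' @param y trait vector (e.g. log bilirubin).
#' @param K kinship matrix (PSD, mean diagonal ~1).
#' @param covariates optional covariate matrix/data.frame (age, sex, BMI,
#'   T2D in the default workflow); an intercept is always included.
#' @return object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `h2_snp`, `se_h2`, `loglik`, `n_iter`, `boundary`.
#' @export
reml_h2 <- function(y, K, covariates = NULL) {
  n <- length(y)
  W <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  storage.mode(W) <- "double"
  fit <- reml_fit(y, W, K)
  info <- reml_information(fit)
  se_h2 <- tryCatch({
    Vcov <- solve(info)
    s <- fit$sigma_g2 + fit$sigma_e2
    grad <- c(fit$sigma_e2, -fit$sigma_g2) / s^2
    sqrt(drop(t(grad) %*% Vcov %*% grad))
  }, error = function(e) NA_real_)
  structure(list(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 h2_snp = fit$h2, se_h2 = se_h2, loglik = fit$loglik,
                 n_iter = fit$n_iter, boundary = fit$boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("h2_snp = %.3f (SE %.3f)  sigma_g2 = %.3f  sigma_e2 = %.3f%s\n",
              x$h2_snp, x$se_h2, x$sigma_g2, x$sigma_e2,
              if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}
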