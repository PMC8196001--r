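#' First-stage regression of exposure on instrument
#'
#' OLS of the exposure on the instrument dosage plus covariates. Reports
#' the fitted exposure values, the partial F-statistic for the instrument
#' alone (1 numerator df; the instrument-strength measure, conventionally
#' adequate when F > 10) and the partial R2 for the instrument. With no
#' covariates, `F = (n - 2) R2 / (1 - R2)`.
#'
#' @param x exposure vector.
#' @param z instrument dosage vector.
#' @param covariates optional covariate matrix/data.frame.
#' @return list with `fitted`, `F`, `r2`, `beta_zx`, `n`.
#' @export
first_stage <- function(x, z, covariates = NULL) {
  n <- length(x)
  if (length(z) != n) stop("exposure and instrument misaligned")
  if (anyNA(x) || anyNA(z)) stop("missing values not allowed")
  if (stats::sd(z) < 1e-12) stop("instrument is constant")
  W <- matrix(1, n, 1)
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  X <- cbind(W, z = z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient first-stage design")
  fit <- stats::lm.fit(X, x)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum(stats::lm.fit(W, x)$residuals^2)
  df2 <- n - ncol(X)
  Fstat <- (rss0 - rss1) / (rss1 / df2)
  r2 <- (rss0 - rss1) / rss0
  list(fitted = drop(X %*% ifelse(is.na(fit$coefficients), 0,
                                  fit$coefficients)),
       F = Fstat, r2 = r2,
       beta_zx = fit$coefficients[["z"]], n = n)
}

#' Second-stage regression of binary outcome on fitted exposure
#'
#' Logistic regression of the outcome on the first-stage fitted exposure
#' plus covariates; the coefficient of the fitted exposure is the
#' two-stage causal estimate on the log-odds scale. The maximum-likelihood
#' (plug-in) SE is reported; it ignores first-stage uncertainty, so a
#' joint two-stage bootstrap SE is also available via `mr_study()`.
#'
#' @param y binary outcome (0/1).
#' @param xhat fitted exposure from [first_stage()].
#' @param covariates optional covariate matrix/data.frame.
#' @param conf_level confidence level for the Wald CI.
#' @return list with `beta`, `se`, `ci` (length 2), `p`, `separation` flag.
#' @export
second_stage <- function(y, xhat, covariates = NULL, conf_level = 0.95) {
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  if (stats::sd(xhat) < 1e-12)
    stop("fitted exposure is constant; causal effect not identified")
  X <- cbind(1, xhat = xhat, if (!is.null(covariates)) as.matrix(covariates))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients[["xhat"]]
  # Wald covariance from the final IRLS weights
  Wd <- fit$weights
  XtWX <- crossprod(X * sqrt(Wd))
  vc <- solve(XtWX)
  se <- sqrt(vc[2, 2])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(beta = beta, se = se, ci = c(beta - zq * se, beta + zq * se),
       p = 2 * stats::pnorm(-abs(beta / se)),
       separation = sep && (max(fit$fitted.values) > 1 - 1e-8 ||
                              min(fit$fitted.values) < 1e-8))
}

#' Exclusion-restriction diagnostic
#'
#' Logistic regression of the outcome on the instrument, adjusting for the
#' exposure and covariates. Under a valid instrument (no direct path from
#' variant to outcome) the per-allele odds ratio should be compatible with
#' 1.
#'
#' @param y binary outcome (0/1).
#' @param z instrument dosage.
#' @param x exposure.
#' @param covariates optional covariate matrix/data.frame.
#' @param conf_level confidence level.
#' @return list with `or`, `ci` (length 2, OR scale), `p`, `beta`, `se`.
#' @export
exclusion_check <- function(y, z, x, covariates = NULL, conf_level = 0.95) {
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  X <- cbind(1, z = z, x = x,
             if (!is.null(covariates)) as.matrix(covariates))
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients[["z"]]
  XtWX <- crossprod(X * sqrt(fit$weights))
  se <- sqrt(solve(XtWX)[2, 2])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(beta), ci = exp(c(beta - zq * se, beta + zq * se)),
       p = 2 * stats::pnorm(-abs(beta / se)), beta = beta, se = se)
}

#' Per-study two-stage Mendelian randomization analysis
#'
#' Runs [first_stage()], [second_stage()] and [exclusion_check()] on one
#' study and optionally adds a joint two-stage bootstrap SE (resampling
#' individuals and refitting both stages).
#'
#' @param x exposure; @param y binary outcome; @param z instrument dosage.
#' @param covariates optional covariate matrix/data.frame.
#' @param n_boot bootstrap replicates for the two-stage SE (0 = skip).
#' @param seed seed for the bootstrap.
#' @return object of class `mr_study_result`: list with `F`, `r2`, `beta`,
#'   `se` (ML), `se_boot` (or NA), `ci`, `p`, `exclusion` (list), `n`.
#' @export
mr_study <- function(x, y, z, covariates = NULL, n_boot = 0L, seed = 1L) {
  fs <- first_stage(x, z, covariates)
  ss <- second_stage(y, fs$fitted, covariates)
  ex <- exclusion_check(y, z, x, covariates)
  se_boot <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(x)
    W <- if (!is.null(covariates)) as.matrix(covariates)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      Wb <- if (!is.null(W)) W[idx, , drop = FALSE]
      out <- tryCatch({
        fsb <- first_stage(x[idx], z[idx], Wb)
        second_stage(y[idx], fsb$fitted, Wb)$beta
      }, error = function(e) NA_real_)
      out
    }, numeric(1))
    se_boot <- stats::sd(bs, na.rm = TRUE)
  }
  structure(list(F = fs$F, r2 = fs$r2, beta = ss$beta, se = ss$se,
                 se_boot = se_boot, ci = ss$ci, p = ss$p,
                 separation = ss$separation, exclusion = ex, n = fs$n),
            class = "mr_study_result")
}

#' @export
print.mr_study_result <- function(x, ...) {
  cat(sprintf("mr_study_result (n = %d): F = %.2f, R2 = %.3f\n",
              x$n, x$F, x$r2))
  cat(sprintf("  causal beta = %.3f (SE %.3f), 95%% CI [%.3f, %.3f], p = %.4g\n",
              x$beta, x$se, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  exclusion OR = %.3f [%.3f, %.3f], p = %.4f\n",
              x$exclusion$or, x$exclusion$ci[1], x$exclusion$ci[2],
              x$exclusion$p))
  invisible(x)
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combined estimate `sum(beta/se^2) / sum(1/se^2)` with
#' `SE = 1/sqrt(sum(1/se^2))`, Wald CI and p-value, plus Cochran's Q and
#' I2 heterogeneity statistics.
#'
#' @param betas study estimates.
#' @param ses study standard errors (positive).
#' @param conf_level confidence level.
#' @return object of class `meta_result`: list with `beta`, `se`, `ci`,
#'   `p`, `weights` (normalized), `Q`, `Q_p`, `I2`, `k`.
#' @export
ivw_meta <- function(betas, ses, conf_level = 0.95) {
  k <- length(betas)
  if (k < 1) stop("need at least one study")
  if (length(ses) != k || any(ses <= 0)) stop("ses must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  Q <- sum(w * (betas - beta)^2)
  Q_p <- if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_
  I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  structure(list(beta = beta, se = se,
                 ci = c(beta - zq * se, beta + zq * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 weights = w / sum(w), Q = Q, Q_p = Q_p, I2 = I2, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "meta_result (%d studies): beta = %.3f (SE %.3f), 95%% CI [%.3f, %.3f], p = %.4f\n",
    x$k, x$beta, x$se, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  Q = %.2f (p = %.3f), I2 = %.1f%%\n", x$Q, x$Q_p,
              100 * x$I2))
  invisible(x)
}

#' Analytic power of Mendelian randomization with a binary outcome
#'
#' Asymptotic non-centrality power for a binary outcome: the two-stage
#' z-statistic for a true odds ratio
#' `or_per_sd` per exposure SD has non-centrality
#' `sqrt(n * r2 * K * (1 - K)) * |log(or_per_sd)|`, where `K(1 - K)` is
#' the variance of the binary outcome at prevalence `K` (equivalently the
#' case/control-ratio form `ratio / (1 + ratio)^2`), and `r2` is the
#' exposure variance explained by the instrument. Two-sided power at level
#' `alpha` is `pnorm(ncp - z) + pnorm(-ncp - z)` with
#' `z = qnorm(1 - alpha/2)`; as `r2 -> 0` power tends to `alpha`.
#'
#' @param n total sample size.
#' @param alpha significance level.
#' @param prevalence outcome prevalence `K` in (0, 1).
#' @param or_per_sd odds ratio of the outcome per SD of the exposure.
#' @param r2 exposure variance explained by the instrument, in (0, 1).
#' @return scalar power.
#' @export
mr_power_binary <- function(n, alpha = 0.05, prevalence, or_per_sd, r2) {
  if (n <= 0) stop("n must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  if (or_per_sd <= 0) stop("or_per_sd must be positive")
  if (r2 < 0 || r2 >= 1) stop("r2 must be in [0, 1)")
  ncp <- sqrt(n * r2 * prevalence * (1 - prevalence)) * abs(log(or_per_sd))
  zq <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - zq) + stats::pnorm(-ncp - zq)
}
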