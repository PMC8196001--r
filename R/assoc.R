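#' Kinship-aware genome-wide association scan
#'
#' EMMAX-style mixed-model association: the variance components of the
#' null model `y = W alpha + u + e`, `Var(u) = sigma_g^2 K`, are estimated
#' once by REML ([reml_fit()]); each variant is then tested by a
#' generalized-least-squares Wald test with the variance ratio held fixed.
#' In the rotated (whitened) model the per-variant test is an ordinary
#' regression t-test, so with `K = I` the scan reduces exactly to OLS.
#' Variants collinear with the fixed effects (or monomorphic) are flagged
#' and reported with `NA` statistics.
#'
#' @param g a [genotype_matrix()].
#' @param y transformed trait vector (see [residualize()] and
#'   [rank_inverse_normal()]), aligned with `g$samples`.
#' @param covariates optional matrix/data.frame of fixed covariates (an
#'   intercept is always included).
#' @param K kinship matrix (default: computed from `g`).
#' @param test_variants optional character vector of variant IDs to test
#'   (default: all).
#' @return object of class `assoc_result`: list with `results` (data.frame
#'   of chrom, pos, id, ea, oa, eaf, beta, se, p, n, flag), `lambda_gc`,
#'   `sigma_g2`, `sigma_e2`, `h2_null`.
#' @export
lmm_assoc <- function(g, y, covariates = NULL, K = NULL,
                      test_variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(y)
  if (n != nrow(g$dosage)) stop("trait and genotypes misaligned")
  W <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) W <- cbind(W, as.matrix(covariates))
  storage.mode(W) <- "double"
  if (is.null(K)) K <- kinship(g)
  fit <- reml_fit(y, W, K)

  idx <- if (is.null(test_variants)) seq_len(ncol(g$dosage)) else {
    pos <- match(test_variants, g$variants$id)
    if (anyNA(pos)) stop("unknown variant ID(s): ",
                         paste(test_variants[is.na(pos)], collapse = ", "))
    pos
  }

  sw <- 1 / sqrt(fit$ratio * fit$d + 1)
  U <- fit$eig$vectors
  ysw <- fit$ys * sw
  Wsw <- fit$Ws * sw
  qrW <- qr(Wsw)
  Q <- qr.Q(qrW)
  yt <- ysw - Q %*% crossprod(Q, ysw)

  p_fixed <- ncol(W)
  df <- n - p_fixed - 1L
  m <- length(idx)
  beta <- se <- pval <- rep(NA_real_, m)
  flag <- rep("", m)
  chunk <- 1024L
  syy <- sum(yt^2)
  for (start in seq(1L, m, by = chunk)) {
    jj <- start:min(start + chunk - 1L, m)
    G <- g$dosage[, idx[jj], drop = FALSE]
    Gs <- crossprod(U, G) * sw
    Gt <- Gs - Q %*% crossprod(Q, Gs)
    sxx <- colSums(Gt^2)
    sxy <- drop(crossprod(Gt, yt))
    ok <- sxx > 1e-8 * n
    b <- sxy[ok] / sxx[ok]
    rss <- syy - b^2 * sxx[ok]
    sigma2 <- pmax(rss, 0) / df
    beta[jj][ok] <- b
    se[jj][ok] <- sqrt(sigma2 / sxx[ok])
    pval[jj][ok] <- 2 * stats::pt(-abs(b / sqrt(sigma2 / sxx[ok])), df)
    flag[jj][!ok] <- "collinear"
  }

  v <- g$variants[idx, , drop = FALSE]
  results <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                        ea = v$alt, oa = v$ref, eaf = v$eaf,
                        beta = beta, se = se, p = pval, n = n,
                        flag = flag, stringsAsFactors = FALSE)
  lam <- if (sum(!is.na(pval)) >= 100) genomic_control(pval[!is.na(pval)])
         else NA_real_
  structure(list(results = results, lambda_gc = lam,
                 sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                 h2_null = fit$h2),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  ok <- !is.na(x$results$p)
  cat("assoc_result:", nrow(x$results), "variants tested, lambda_GC =",
      round(x$lambda_gc, 3), "\n")
  top <- x$results[ok, ][which.min(x$results$p[ok]), ]
  cat(sprintf("  top hit: %s beta=%.3f se=%.3f p=%.3g\n",
              top$id, top$beta, top$se, top$p))
  invisible(x)
}

#' Genomic control inflation factor
#'
#' `lambda_GC`: the median association chi-square (1 df, from two-sided
#' p-values) divided by its null median `qchisq(0.5, 1) = 0.4549`.
#'
#' @param pvals vector of at least 100 p-values.
#' @return scalar inflation factor.
#' @export
genomic_control <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 100) stop("need at least 100 p-values")
  stats::median(stats::qchisq(pvals, 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, 1)
}

#' Conditional association scan
#'
#' Re-runs [lmm_assoc()] with the dosage of an index variant appended to
#' the fixed effects, to test for secondary signals independent of it. The
#' conditioning variant is excluded from the output; perfect proxies of it
#' come back flagged `"collinear"` with `NA` statistics.
#'
#' @inheritParams lmm_assoc
#' @param condition_on variant ID to condition on.
#' @return an `assoc_result` (without the conditioning variant).
#' @export
conditional_scan <- function(g, y, covariates = NULL, K = NULL,
                             condition_on) {
  j <- match(condition_on, g$variants$id)
  if (is.na(j)) stop("conditioning variant not found: ", condition_on)
  z <- g$dosage[, j]
  if (stats::sd(z) < 1e-12)
    stop("conditioning variant is monomorphic: ", condition_on)
  covar <- if (is.null(covariates)) cbind(cond = z)
           else cbind(as.matrix(covariates), cond = z)
  res <- lmm_assoc(g, y, covariates = covar, K = K,
                   test_variants = g$variants$id[-j])
  res
}
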