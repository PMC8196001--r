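#' Residualize a trait on covariates
#'
#' Ordinary-least-squares residuals of `y` on the covariate matrix (an
#' intercept is appended when absent). Residuals are orthogonal to every
#' covariate column.
#'
#' @param y numeric trait vector without missing values.
#' @param covariates numeric matrix or data.frame of covariates.
#' @return numeric residual vector.
#' @export
residualize <- function(y, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (anyNA(y) || anyNA(X)) stop("missing values in trait or covariates")
  if (nrow(X) != length(y)) stop("covariates and trait length differ")
  has_intercept <- any(apply(X, 2, function(c) all(abs(c - c[1]) < 1e-12)))
  if (!has_intercept) X <- cbind(1, X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient covariate matrix")
  stats::lm.fit(X, y)$residuals
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal scores `qnorm((rank - c) / (n - 2c + 1))` with the
#' Blom offset `c = 3/8` by default; ties receive average ranks. The
#' transform is strictly monotone on distinct values, and the result has
#' mean ~0 and variance ~1.
#'
#' @param values numeric vector, length >= 3, not all identical.
#' @param offset rank offset constant (Blom 3/8 by default).
#' @return transformed numeric vector.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (anyNA(values)) stop("missing values not allowed")
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (max(values) - min(values) < .Machine$double.eps * max(1, abs(values[1])))
    stop("all values identical; transformation undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}
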