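# Single-variance-component REML machinery shared by the association scan
# and the heritability module. The model is
#   y = W alpha + u + e,  Var(y) = sigma_g^2 K + sigma_e^2 I.
# K is eigendecomposed once; the restricted likelihood is profiled down to
# the variance ratio r = sigma_g^2 / sigma_e^2 and maximized by Brent
# search on log r.

#' Fit a one-component linear mixed model by REML
#'
#' Estimates `sigma_g^2` and `sigma_e^2` in
#' `Var(y) = sigma_g^2 K + sigma_e^2 I` by restricted maximum likelihood,
#' using the eigendecomposition of `K` and 1-D optimization of the
#' log variance ratio (Brent, tolerance 1e-8). Deterministic.
#'
#' @param y numeric response vector.
#' @param W fixed-effect design matrix (must include an intercept column).
#' @param K symmetric PSD kinship matrix, or a precomputed
#'   `eigen(K, symmetric = TRUE)` object.
#' @param log_ratio_bounds search interval for `log(sigma_g^2/sigma_e^2)`.
#' @return list with `sigma_g2`, `sigma_e2`, `ratio`, `h2`
#'   (`sigma_g2 / (sigma_g2 + sigma_e2)`), `loglik` (restricted), `n_iter`,
#'   `boundary` flag, and the rotated quantities needed by callers
#'   (`eig`, `d`, `ys`, `Ws`).
#' @keywords internal
reml_fit <- function(y, W, K, log_ratio_bounds = c(-12, 12)) {
  W <- as.matrix(W)
  n <- length(y)
  stopifnot(nrow(W) == n)
  if (qr(W)$rank < ncol(W)) stop("rank-deficient fixed-effect matrix")
  eig <- if (is.list(K) && !is.null(K$vectors)) K else {
    if (!isTRUE(all.equal(K, t(K), tolerance = 1e-10)))
      stop("K must be symmetric")
    eigen(K, symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-6)
    warning("K has eigenvalue ", signif(min(eig$values), 3),
            "; truncated at 0")
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  p <- ncol(W)
  ldWW <- determinant(crossprod(W), logarithm = TRUE)$modulus

  evals <- 0L
  nll <- function(logr) {
    evals <<- evals + 1L
    r <- exp(logr)
    D <- r * d + 1
    sw <- 1 / sqrt(D)
    ysw <- ys * sw
    Wsw <- Ws * sw
    fit <- stats::lm.fit(Wsw, ysw)
    rss <- sum(fit$residuals^2)
    sigma_e2 <- rss / (n - p)
    XtX <- crossprod(Wsw)
    ldX <- determinant(XtX, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(2 * pi * sigma_e2) + sum(log(D)) +
             ldX - ldWW + (n - p))
  }

  # bracket then Brent
  opt <- stats::optimize(nll, interval = log_ratio_bounds, tol = 1e-8)
  # compare against the boundaries (h2 ~ 0 or ~ 1)
  cand <- c(opt$minimum, log_ratio_bounds)
  vals <- c(opt$objective, nll(log_ratio_bounds[1]), nll(log_ratio_bounds[2]))
  best <- cand[which.min(vals)]
  boundary <- best %in% log_ratio_bounds
  r <- exp(best)
  D <- r * d + 1
  sw <- 1 / sqrt(D)
  fit <- stats::lm.fit(Ws * sw, ys * sw)
  sigma_e2 <- sum(fit$residuals^2) / (n - p)
  sigma_g2 <- r * sigma_e2
  if (!is.finite(sigma_e2) || sigma_e2 < 0)
    stop("REML did not converge; evaluations so far: ", evals)
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, ratio = r,
       h2 = sigma_g2 / (sigma_g2 + sigma_e2),
       loglik = -min(vals), n_iter = evals, boundary = boundary,
       eig = eig, d = d, ys = ys, Ws = Ws, n = n, p = p)
}

# Expected information of (sigma_g2, sigma_e2) at the REML optimum, in the
# eigenbasis of K. Returns the 2x2 matrix I with
# I[j,k] = tr(P V_j P V_k) / 2, V_1 = K, V_2 = I.
reml_information <- function(fit) {
  d <- fit$d
  V <- fit$sigma_g2 * d + fit$sigma_e2
  Vi <- 1 / V
  Ws <- fit$Ws
  A <- Ws * Vi # V^-1 W
  XtVX <- crossprod(Ws, A)
  B <- A %*% solve(XtVX, t(A)) # V^-1 W (W'V^-1 W)^-1 W'V^-1
  P <- diag(Vi) - B
  P2 <- P * P
  i11 <- 0.5 * sum(P2 * outer(d, d))
  i12 <- 0.5 * sum(P2 * rep(d, each = length(d)))
  i22 <- 0.5 * sum(P2)
  matrix(c(i11, i12, i12, i22), 2, 2)
}
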