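#' Region statistics for fine mapping
#'
#' Bundles the marginal z-scores (`beta/se` from an association scan), the
#' LD correlation matrix, the sample size and optional binary annotations
#' for a region to be fine mapped.
#'
#' @param z numeric vector of per-variant z-scores.
#' @param R `m x m` LD correlation matrix (symmetric, unit diagonal).
#' @param n GWAS sample size.
#' @param annotations optional `m x a` 0/1 matrix (presence/absence of
#'   regulatory marks per variant).
#' @param ids optional variant IDs.
#' @return list of class `region_stats`.
#' @export
region_stats <- function(z, R, n, annotations = NULL, ids = NULL) {
  R <- as.matrix(R)
  m <- length(z)
  if (!all(dim(R) == m)) stop("R must be m x m with m = length(z)")
  if (any(!is.finite(z))) stop("z-scores must be finite")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-6) stop("R must have unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
    stop("R must be positive semidefinite")
  if (!is.null(annotations)) {
    annotations <- as.matrix(annotations)
    if (nrow(annotations) != m) stop("annotations must have m rows")
    if (!all(annotations %in% c(0, 1))) stop("annotations must be 0/1")
  }
  if (is.null(ids)) ids <- if (!is.null(rownames(R))) rownames(R)
                           else paste0("v", seq_len(m))
  structure(list(z = z, R = R, n = n, annotations = annotations, ids = ids),
            class = "region_stats")
}

#' Log Bayes factor of a causal configuration
#'
#' Approximate multivariate Bayes factor for the hypothesis that exactly
#' the variants in `config` are causal: under H0 the configuration's
#' z-scores are `N(0, R_cc)`, under H1 they are
#' `N(0, R_cc + n * sd^2 * R_cc R_cc)` (the multivariate extension of
#' Wakefield's approximate Bayes factor to correlated variants). When
#' `prior_sd` is a vector the Bayes factor is averaged over the grid with
#' equal weights, in log space. A singular `R_cc` is ridge-regularized.
#'
#' @param stats a [region_stats()].
#' @param config integer indices (or variant IDs) of the causal subset.
#' @param prior_sd prior SD(s) of the standardized effect size; default
#'   grid `c(0.1, 0.2, 0.4)`.
#' @param ridge regularization added to `R_cc` diagonals if needed.
#' @return scalar log Bayes factor (natural log).
#' @export
config_log_bf <- function(stats, config, prior_sd = c(0.1, 0.2, 0.4),
                          ridge = 1e-6) {
  stopifnot(inherits(stats, "region_stats"))
  if (is.character(config)) config <- match(config, stats$ids)
  if (length(config) < 1 || anyNA(config)) stop("invalid configuration")
  if (any(prior_sd <= 0)) stop("prior_sd must be positive")
  Rcc <- stats$R[config, config, drop = FALSE]
  zc <- stats$z[config]
  ch0 <- tryCatch(chol(Rcc), error = function(e) NULL)
  if (is.null(ch0)) {
    Rcc <- Rcc + diag(ridge, nrow(Rcc))
    ch0 <- chol(Rcc)
  }
  ld0 <- 2 * sum(log(diag(ch0)))
  q0 <- sum(backsolve(ch0, zc, transpose = TRUE)^2)
  logbfs <- vapply(prior_sd, function(sd) {
    S1 <- Rcc + stats$n * sd^2 * (Rcc %*% Rcc)
    ch1 <- chol(S1)
    ld1 <- 2 * sum(log(diag(ch1)))
    q1 <- sum(backsolve(ch1, zc, transpose = TRUE)^2)
    -0.5 * (ld1 - ld0) - 0.5 * (q1 - q0)
  }, numeric(1))
  logsumexp(logbfs) - log(length(logbfs))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Posterior inclusion probabilities by configuration enumeration
#'
#' Enumerates every causal configuration of size 1..`max_causal` (plus the
#' null model), scores each by `prior(config) * BF(config)` and reports the
#' marginal posterior inclusion probability of each variant. The prior is
#' an independent-inclusion prior with per-variant probability
#' `prior_inclusion` (default `1/m`); binary annotations multiply a
#' variant's prior odds by the corresponding `annotation_odds` factor.
#'
#' @param stats a [region_stats()].
#' @param max_causal maximum number of causal variants per configuration
#'   (default 1).
#' @param prior_inclusion scalar or per-variant prior inclusion
#'   probability; default `1/m`.
#' @param annotation_odds multiplicative prior-odds factor per annotation
#'   column (length = number of annotation columns).
#' @param prior_sd passed to [config_log_bf()].
#' @param max_configs guard on the number of enumerated configurations.
#' @return object of class `finemap_result`: list with `pip` (named
#'   vector), `configs` (data.frame of configurations, log BF and
#'   posterior), `prior` (per-variant prior inclusion probabilities),
#'   `log_bf_single` (per-variant single-causal log BFs).
#' @export
pip <- function(stats, max_causal = 1L, prior_inclusion = NULL,
                annotation_odds = NULL, prior_sd = c(0.1, 0.2, 0.4),
                max_configs = 1e6) {
  stopifnot(inherits(stats, "region_stats"))
  m <- length(stats$z)
  if (max_causal < 1) stop("max_causal must be >= 1")
  max_causal <- min(max_causal, m)
  n_configs <- sum(vapply(seq_len(max_causal),
                          function(k) choose(m, k), numeric(1)))
  if (n_configs > max_configs)
    stop("enumeration of ", format(n_configs, big.mark = ","),
         " configurations exceeds the guard; reduce max_causal or the region")

  pi_j <- if (is.null(prior_inclusion)) rep(1 / m, m)
          else rep(prior_inclusion, length.out = m)
  if (any(pi_j <= 0 | pi_j >= 1))
    stop("prior inclusion probabilities must be in (0, 1)")
  if (!is.null(annotation_odds)) {
    if (is.null(stats$annotations)) stop("no annotations in region_stats")
    if (length(annotation_odds) != ncol(stats$annotations))
      stop("annotation_odds must match annotation columns")
    if (any(annotation_odds <= 0)) stop("annotation_odds must be positive")
    log_odds <- log(pi_j / (1 - pi_j)) +
      drop(stats$annotations %*% log(annotation_odds))
    pi_j <- stats::plogis(log_odds)
  }

  log_pi <- log(pi_j)
  log_1mpi <- log1p(-pi_j)
  base_null <- sum(log_1mpi)

  configs <- list(integer(0))
  for (k in seq_len(max_causal))
    configs <- c(configs, utils::combn(m, k, simplify = FALSE))

  log_post <- vapply(configs, function(cfg) {
    lp <- base_null + sum(log_pi[cfg] - log_1mpi[cfg])
    lbf <- if (length(cfg)) config_log_bf(stats, cfg, prior_sd) else 0
    lp + lbf
  }, numeric(1))
  log_z <- logsumexp(log_post)
  post <- exp(log_post - log_z)

  pip_j <- numeric(m)
  for (i in seq_along(configs))
    pip_j[configs[[i]]] <- pip_j[configs[[i]]] + post[i]
  names(pip_j) <- stats$ids

  single <- vapply(seq_len(m),
                   function(j) config_log_bf(stats, j, prior_sd), numeric(1))
  cfg_df <- data.frame(
    config = vapply(configs, function(cfg)
      paste(stats$ids[cfg], collapse = ","), character(1)),
    size = lengths(configs),
    log_posterior = log_post - log_z,
    posterior = post)
  structure(list(pip = pip_j, configs = cfg_df, prior = pi_j,
                 log_bf_single = stats::setNames(single, stats$ids),
                 max_causal = max_causal, prior_sd = prior_sd),
            class = "finemap_result")
}

#' @export
print.finemap_result <- function(x, ...) {
  top <- order(x$pip, decreasing = TRUE)[seq_len(min(5, length(x$pip)))]
  cat("finemap_result: max_causal =", x$max_causal, "\n")
  print(round(x$pip[top], 4))
  invisible(x)
}
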