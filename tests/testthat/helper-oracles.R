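# Brute-force posterior oracle: enumerates configurations and evaluates the
# two multivariate normal densities directly with solve()/determinant(),
# independently of the package's cholesky-based log-space implementation.
oracle_pip <- function(z, R, n, max_causal, prior_sd = c(0.1, 0.2, 0.4),
                       pi_j = NULL) {
  m <- length(z)
  if (is.null(pi_j)) pi_j <- rep(1 / m, m)
  dens <- function(zc, S) {
    k <- length(zc)
    as.numeric(exp(-0.5 * t(zc) %*% solve(S, zc)) /
                 sqrt((2 * pi)^k * det(S)))
  }
  configs <- list(integer(0))
  for (k in seq_len(max_causal))
    configs <- c(configs, utils::combn(m, k, simplify = FALSE))
  wts <- vapply(configs, function(cfg) {
    prior <- prod(pi_j[cfg]) * prod(1 - pi_j[setdiff(seq_len(m), cfg)])
    if (!length(cfg)) return(prior)
    Rcc <- R[cfg, cfg, drop = FALSE]
    bf <- mean(vapply(prior_sd, function(sd) {
      dens(z[cfg], Rcc + n * sd^2 * Rcc %*% Rcc) / dens(z[cfg], Rcc)
    }, numeric(1)))
    prior * bf
  }, numeric(1))
  post <- wts / sum(wts)
  out <- numeric(m)
  for (i in seq_along(configs))
    out[configs[[i]]] <- out[configs[[i]]] + post[i]
  out
}

# one fine-mapping region: single causal variant in block LD, summary
# statistics from an OLS-limit scan
block_region <- function(n = 2000, m = 20, rho = 0.5, causal = 10,
                         beta = 0.35, seed = 1) {
  cfg <- sim_config(n_samples = n, n_variants = m, causal_index = causal,
                    exposure_effect = beta, polygenic_h2 = 0,
                    confounder_on_exposure = 0, within_block_rho = rho,
                    ld_block_size = 5, fst = 0, n_subpops = 1,
                    n_sib_pairs = 0, seed = seed)
  co <- simulate_cohort(cfg)
  scan <- lmm_assoc(co$genotypes, scale(co$phenotypes$bilirubin)[, 1],
                    K = diag(n))
  list(stats = region_stats(scan$results$beta / scan$results$se,
                            ld_matrix(co$genotypes), n,
                            ids = co$genotypes$variants$id),
       causal_id = co$genotypes$variants$id[causal])
}
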