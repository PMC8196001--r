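#' Simulate genotypes with LD blocks, population structure and relatedness
#'
#' Haplotypes are generated from a Gaussian copula: within each LD block of
#' `ld_block_size` consecutive variants, latent normals share an
#' exchangeable correlation `within_block_rho` and are thresholded at the
#' allele-frequency quantile, giving tunable within-block r2 and
#' independence across blocks. Subpopulation allele frequencies follow the
#' Balding-Nichols model with parameter `fst`; the last `2 * n_sib_pairs`
#' samples are sibling pairs formed by transmitting whole parental
#' haplotypes (expected kinship 1/4). Output is deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with subpopulation labels in
#'   `attr(, "subpop")`.
#' @export
simulate_genotypes <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants
  rho <- config$within_block_rho

  p_anc <- stats::runif(m, 0.05, 0.95)
  p_anc[config$causal_index] <- config$causal_eaf

  # Balding-Nichols subpopulation frequencies
  K <- config$n_subpops
  if (config$fst > 0 && K > 1) {
    Fst <- config$fst
    P <- t(vapply(seq_len(K), function(k) {
      stats::rbeta(m, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
    }, numeric(m)))
    P <- pmin(pmax(P, 1e-4), 1 - 1e-4)
  } else {
    P <- matrix(rep(p_anc, each = K), nrow = K)
  }
  subpop <- rep(seq_len(K), length.out = n)
  subpop <- sort(subpop)
  thresholds <- stats::qnorm(P) # K x m

  n_blocks <- ceiling(m / config$ld_block_size)
  block_of <- rep(seq_len(n_blocks), each = config$ld_block_size)[seq_len(m)]

  draw_haplotypes <- function(pop) {
    nh <- length(pop)
    shared <- matrix(stats::rnorm(nh * n_blocks), nh, n_blocks)
    latent <- sqrt(rho) * shared[, block_of, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(nh * m), nh, m)
    (latent < thresholds[pop, , drop = FALSE]) * 1L
  }

  G <- draw_haplotypes(subpop) + draw_haplotypes(subpop)

  if (config$n_sib_pairs > 0) {
    ns <- config$n_sib_pairs
    first <- n - 2L * ns + seq(1L, 2L * ns, by = 2L)
    second <- first + 1L
    pop_pair <- subpop[first]
    pat1 <- draw_haplotypes(pop_pair); pat2 <- draw_haplotypes(pop_pair)
    mat1 <- draw_haplotypes(pop_pair); mat2 <- draw_haplotypes(pop_pair)
    pick <- function(h1, h2) {
      sel <- stats::rbinom(length(pop_pair), 1L, 0.5) == 1L
      out <- h2; out[sel, ] <- h1[sel, , drop = FALSE]; out
    }
    G[first, ] <- pick(pat1, pat2) + pick(mat1, mat2)
    G[second, ] <- pick(pat1, pat2) + pick(mat1, mat2)
  }

  bases <- c("A", "C", "G", "T")
  variants <- data.frame(
    chrom = "1",
    pos = seq_len(m) * 10000L,
    id = paste0("rs", seq_len(m)),
    ref = bases[(seq_len(m) - 1L) %% 4L + 1L],
    alt = bases[seq_len(m) %% 4L + 1L],
    stringsAsFactors = FALSE)

  g <- genotype_matrix(G, variants,
                       samples = sprintf("S%04d", seq_len(n)))
  attr(g, "subpop") <- subpop
  g
}

#' Simulate exposure and binary outcome phenotypes
#'
#' The exposure (serum bilirubin, in SD-scale units) is
#' `X = a*Z + polygenic + covariate effects + u_x*U + noise`, where `Z` is
#' the causal-variant dosage, the polygenic term spreads small effects over
#' standardized non-causal variants, and `U` is a standard-normal
#' confounder shared with the outcome. `a` is calibrated so the causal
#' variant explains `target_iv_r2` of the exposure variance (or set
#' directly via `exposure_effect`); the polygenic term is scaled to a
#' variance fraction of `polygenic_h2`. The binary outcome follows a
#' logistic liability `logit P(Y=1) = c + log_or_per_sd*(X/SD(X)) + u_y*U +
#' covariate effects`, with the intercept `c` solved by root finding so the
#' population-averaged prevalence matches `outcome_prevalence` (tolerance
#' 1e-4).
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return data.frame with columns `sample_id`, `bilirubin`,
#'   `hypertension`, `sex`, `age`, `bmi`, `t2d`; generative components are
#'   kept in `attr(, "components")` for [realized_truth()].
#' @export
simulate_phenotypes <- function(genotypes, config) {
  config <- validate_sim_config(config)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (config$causal_index > ncol(genotypes$dosage))
    stop("causal_index exceeds the number of variants")
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosage)

  sex <- stats::rbinom(n, 1L, 0.327)
  age <- stats::rnorm(n, 55.3, 12.8)
  bmi <- stats::rnorm(n, 28.9, 6.0)
  t2d <- stats::rbinom(n, 1L, 0.54)

  Z <- genotypes$dosage[, config$causal_index]
  sd_z <- stats::sd(Z)
  want_iv <- !is.null(config$exposure_effect) || config$target_iv_r2 > 0
  if (want_iv && sd_z < 1e-12)
    stop("causal variant is monomorphic; cannot place an exposure effect")
  if (!is.null(config$exposure_effect)) {
    a <- config$exposure_effect
    iv_var <- a^2 * sd_z^2
  } else if (config$target_iv_r2 > 0) {
    a <- sqrt(config$target_iv_r2) / sd_z
    iv_var <- config$target_iv_r2
  } else {
    a <- 0
    iv_var <- 0
  }
  genetic_iv <- a * (Z - mean(Z))

  # polygenic background excludes the causal variant's whole LD block, so
  # the region carries a single association signal
  causal_block <- (config$causal_index - 1L) %/% config$ld_block_size
  block_of <- (seq_len(ncol(genotypes$dosage)) - 1L) %/% config$ld_block_size
  poly_idx <- which(block_of != causal_block)
  m_poly <- round(config$polygenic_fraction * length(poly_idx))
  if (config$polygenic_h2 > 0 && m_poly > 0) {
    poly_idx <- sort(sample(poly_idx, m_poly))
    Xp <- genotypes$dosage[, poly_idx, drop = FALSE]
    mu <- colMeans(Xp)
    sds <- sqrt(colMeans(Xp^2) - mu^2)
    ok <- sds > 1e-12
    Zp <- sweep(Xp[, ok, drop = FALSE], 2, mu[ok], "-")
    Zp <- sweep(Zp, 2, sds[ok], "/")
    b <- stats::rnorm(ncol(Zp))
    g_raw <- drop(Zp %*% b)
    polygenic <- g_raw * sqrt(config$polygenic_h2) / stats::sd(g_raw)
  } else {
    polygenic <- numeric(n)
  }

  u <- stats::rnorm(n)
  noise_var <- 1 - iv_var - config$polygenic_h2 -
    config$confounder_on_exposure^2
  if (noise_var <= 0)
    stop("generative variance fractions exceed 1; reduce effect sizes")
  noise <- stats::rnorm(n, 0, sqrt(noise_var))

  covar_part <- config$sex_effect * sex +
    config$age_effect * (age - mean(age)) +
    config$bmi_effect * (bmi - mean(bmi))
  x <- genetic_iv + polygenic + config$confounder_on_exposure * u +
    noise + covar_part

  eta <- config$log_or_per_sd * (x - mean(x)) / stats::sd(x) +
    config$confounder_on_outcome * u +
    config$age_effect_outcome * (age - mean(age)) +
    config$bmi_effect_outcome * (bmi - mean(bmi))
  f <- function(c0) mean(stats::plogis(c0 + eta)) - config$outcome_prevalence
  if (f(-30) > 0 || f(30) < 0)
    stop("prevalence intercept solver failed to bracket ",
         config$outcome_prevalence)
  c0 <- stats::uniroot(f, c(-30, 30), tol = 1e-6)$root
  if (abs(f(c0)) > 1e-4)
    stop("prevalence intercept solver did not reach tolerance 1e-4")
  y <- stats::rbinom(n, 1L, stats::plogis(c0 + eta))

  pheno <- data.frame(sample_id = genotypes$samples,
                      bilirubin = x,
                      hypertension = y,
                      sex = sex, age = age, bmi = bmi, t2d = t2d,
                      stringsAsFactors = FALSE)
  attr(pheno, "components") <- list(genetic_iv = genetic_iv,
                                    polygenic = polygenic,
                                    confounder = u,
                                    noise = noise,
                                    covariate = covar_part,
                                    intercept = c0,
                                    liability = c0 + eta)
  pheno
}

#' Simulate a complete cohort
#'
#' Runs [simulate_genotypes()] then [simulate_phenotypes()] and attaches
#' the realized generative truth.
#'
#' @param config a [sim_config()].
#' @return list of class `simulated_cohort` with elements `genotypes`,
#'   `phenotypes`, `truth` and `config`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  p <- simulate_phenotypes(g, config)
  cohort <- structure(list(genotypes = g, phenotypes = p, config = config),
                      class = "simulated_cohort")
  cohort$truth <- realized_truth(cohort)
  cohort
}

#' Realized generative parameters of a simulated cohort
#'
#' Recomputes, from the generated data and stored generative components,
#' the quantities the generator targeted: effect-allele frequency of the
#' causal variant, fraction of exposure variance explained by it, total
#' genetic variance fraction (causal + polygenic, i.e. the generative SNP
#' heritability) and outcome prevalence.
#'
#' @param cohort a `simulated_cohort` (or list with `genotypes`,
#'   `phenotypes`, `config`).
#' @return list with `realized_eaf`, `realized_iv_r2`, `realized_h2`,
#'   `realized_prevalence`.
#' @export
realized_truth <- function(cohort) {
  comp <- attr(cohort$phenotypes, "components")
  if (is.null(comp)) stop("phenotypes lack generative components")
  vx <- stats::var(cohort$phenotypes$bilirubin)
  list(realized_eaf =
         mean(cohort$genotypes$dosage[, cohort$config$causal_index]) / 2,
       realized_iv_r2 = stats::var(comp$genetic_iv) / vx,
       realized_h2 = stats::var(comp$genetic_iv + comp$polygenic) / vx,
       realized_prevalence = mean(cohort$phenotypes$hypertension))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", nrow(x$genotypes$dosage), "samples,",
      ncol(x$genotypes$dosage), "variants\n")
  t <- x$truth
  cat(sprintf("  realized: EAF %.3f, IV R2 %.3f, h2 %.3f, prevalence %.3f\n",
              t$realized_eaf, t$realized_iv_r2, t$realized_h2,
              t$realized_prevalence))
  invisible(x)
}
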