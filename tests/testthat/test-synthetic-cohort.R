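test_that("identical configs give bit-identical cohorts", {
  cfg <- sim_config(n_samples = 120, n_variants = 80, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(causal_eaf = 1.2), "causal_eaf")
  expect_error(sim_config(within_block_rho = 1), "within_block_rho")
  expect_error(sim_config(target_iv_r2 = 0.5, polygenic_h2 = 0.6),
               "polygenic_h2")
  expect_error(sim_config(n_sib_pairs = 100, n_samples = 100), "n_sib_pairs")
})

test_that("without LD, structure or relatedness, genotypes are independent", {
  cfg <- sim_config(n_samples = 900, n_variants = 40, fst = 0,
                    n_subpops = 1, n_sib_pairs = 0, within_block_rho = 0,
                    seed = 3)
  g <- simulate_genotypes(cfg)
  R <- cor(g$dosage)
  off <- abs(R[upper.tri(R)])
  # each pairwise correlation is ~N(0, 1/n); across the 780 pairs nearly
  # all should sit inside 3/sqrt(n) and none far outside
  expect_gte(mean(off < 3 / sqrt(cfg$n_samples)), 0.99)
  expect_lt(max(off), 6 / sqrt(cfg$n_samples))
})

test_that("realized causal-variant EAF tracks the configured frequency", {
  cfg <- sim_config(n_samples = 5000, n_variants = 60, causal_index = 30,
                    causal_eaf = 0.49, fst = 0, n_subpops = 1,
                    n_sib_pairs = 0, seed = 21)
  g <- simulate_genotypes(cfg)
  eaf <- mean(g$dosage[, 30]) / 2
  expect_lt(abs(eaf - 0.49), 0.02)
})

test_that("two subpopulations at fst = 0.1 separate on the leading PC", {
  cfg <- sim_config(n_samples = 400, n_variants = 2000, fst = 0.1,
                    n_subpops = 2, n_sib_pairs = 0, within_block_rho = 0,
                    seed = 31)
  g <- simulate_genotypes(cfg)
  sub <- attr(g, "subpop")
  # PCA oracle: leading eigenvector of the standardized genotype covariance
  poly <- apply(g$dosage, 2, sd) > 0
  Z <- scale(g$dosage[, poly])
  pc1 <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = 1)$x[, 1]
  expect_gt(abs(cor(pc1, sub)), 0.9)
})

test_that("sibling pairs carry elevated kinship", {
  cfg <- sim_config(n_samples = 200, n_variants = 2000, n_sib_pairs = 30,
                    fst = 0, n_subpops = 1, within_block_rho = 0, seed = 41)
  g <- simulate_genotypes(cfg)
  K <- kinship(g)
  n <- cfg$n_samples
  first <- n - 60 + seq(1, 60, by = 2)
  sib_k <- K[cbind(first, first + 1)]
  unrel_k <- K[cbind(1:50, 51:100)]
  expect_gt(mean(sib_k), 0.3) # expected ~0.5 for full sibs
  expect_lt(abs(mean(unrel_k)), 0.05)
})

test_that("exposure variance explained by the instrument matches the target", {
  cfg <- sim_config(n_samples = 3000, n_variants = 40, causal_index = 20,
                    target_iv_r2 = 0.12, fst = 0, n_subpops = 1,
                    n_sib_pairs = 0, seed = 51)
  co <- simulate_cohort(cfg)
  z <- co$genotypes$dosage[, 20]
  r2 <- summary(lm(co$phenotypes$bilirubin ~ z))$r.squared
  expect_gt(r2, 0.09)
  expect_lt(r2, 0.15)
})

test_that("outcome prevalence matches the target", {
  cfg <- sim_config(n_samples = 3000, n_variants = 40,
                    outcome_prevalence = 0.26, fst = 0, n_subpops = 1,
                    n_sib_pairs = 0, seed = 61)
  co <- simulate_cohort(cfg)
  prev <- mean(co$phenotypes$hypertension)
  expect_gt(prev, 0.23)
  expect_lt(prev, 0.29)
})

test_that("null exposure-outcome effect yields odds ratios compatible with 1", {
  covered <- vapply(1:100, function(r) {
    cfg <- sim_config(n_samples = 800, n_variants = 10, log_or_per_sd = 0,
                      confounder_on_exposure = 0, confounder_on_outcome = 0,
                      fst = 0, n_subpops = 1, n_sib_pairs = 0,
                      seed = 7000 + r)
    co <- simulate_cohort(cfg)
    p <- co$phenotypes
    fit <- suppressWarnings(
      glm(hypertension ~ scale(bilirubin), family = binomial, data = p))
    ci <- coef(summary(fit))[2, 1] + c(-1.96, 1.96) * coef(summary(fit))[2, 2]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 93)
})

test_that("realized truth is recomputable and behaves at the extremes", {
  co <- quick_cohort(n = 300, m = 40, seed = 71)
  tr <- realized_truth(co)
  expect_identical(tr$realized_prevalence, mean(co$phenotypes$hypertension))
  # all effects zero: no instrument variance explained
  cfg0 <- sim_config(n_samples = 300, n_variants = 40, target_iv_r2 = 0,
                     polygenic_h2 = 0, log_or_per_sd = 0, fst = 0,
                     n_subpops = 1, n_sib_pairs = 0, seed = 72)
  tr0 <- simulate_cohort(cfg0)$truth
  expect_equal(tr0$realized_iv_r2, 0)
  expect_equal(tr0$realized_h2, 0)
})

test_that("realized SNP heritability tracks the configured fraction", {
  cfg <- sim_config(n_samples = 2000, n_variants = 2000, target_iv_r2 = 0,
                    polygenic_h2 = 0.385, fst = 0, n_subpops = 1,
                    n_sib_pairs = 0, seed = 81)
  tr <- simulate_cohort(cfg)$truth
  expect_lt(abs(tr$realized_h2 - 0.385), 0.05)
})

test_that("downstream association p-values are uniform under the null", {
  cfg <- sim_config(n_samples = 400, n_variants = 5000, target_iv_r2 = 0,
                    polygenic_h2 = 0, within_block_rho = 0, fst = 0,
                    n_subpops = 1, n_sib_pairs = 0, seed = 91)
  co <- simulate_cohort(cfg)
  scan <- lmm_assoc(co$genotypes, scale(co$phenotypes$bilirubin)[, 1],
                    K = diag(cfg$n_samples))
  ks <- suppressWarnings(ks.test(scan$results$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the confounder biases naive estimation away from the generative effect", {
  # U loads positively on the outcome and positively on the exposure, so
  # naive logistic regression of Y on X is biased upward (toward the null
  # and beyond for a protective exposure)
  bias <- vapply(1:50, function(r) {
    cfg <- sim_config(n_samples = 1500, n_variants = 10,
                      target_iv_r2 = 0.2, polygenic_h2 = 0,
                      fst = 0, n_subpops = 1, n_sib_pairs = 0,
                      seed = 9000 + r)
    co <- simulate_cohort(cfg)
    p <- co$phenotypes
    fit <- suppressWarnings(
      glm(hypertension ~ scale(bilirubin) + sex + age + bmi,
          family = binomial, data = p))
    coef(fit)[2] - cfg$log_or_per_sd
  }, numeric(1))
  expect_gt(mean(bias > 0), 0.9)
})

test_that("an unsolvable prevalence intercept raises an error", {
  cfg <- sim_config(n_samples = 100, n_variants = 10,
                    outcome_prevalence = 1e-12, fst = 0, n_subpops = 1,
                    n_sib_pairs = 0, seed = 5)
  cfg$outcome_prevalence <- 1e-16 # below what the bracket can reach
  g <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(g, cfg), "bracket|outcome_prevalence")
})
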