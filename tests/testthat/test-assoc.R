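test_that("with K = I the mixed-model scan equals OLS exactly", {
  co <- quick_cohort(n = 150, m = 60, seed = 33)
  g <- co$genotypes
  set.seed(1)
  y <- rnorm(150)
  covar <- cbind(co$phenotypes$age, co$phenotypes$sex)
  scan <- lmm_assoc(g, y, covariates = covar, K = diag(150))
  for (j in c(1, 17, 60)) {
    o <- summary(lm(y ~ g$dosage[, j] + covar))$coefficients[2, ]
    expect_equal(scan$results$beta[j], unname(o[1]), tolerance = 1e-6)
    expect_equal(scan$results$se[j], unname(o[2]), tolerance = 1e-6)
    expect_equal(scan$results$p[j], unname(o[4]), tolerance = 1e-6)
  }
})

test_that("genomic control is definitional on uniform quantiles and monotone", {
  p_unif <- (1:5000 - 0.5) / 5000
  expect_equal(genomic_control(p_unif), 1, tolerance = 1e-3)
  expect_gt(genomic_control(p_unif / 2), 1)
  expect_error(genomic_control(runif(50)), "100")
})

test_that("a spiked scan keeps lambda close to 1", {
  # 1% strong signals should barely move the median-based inflation factor
  set.seed(44)
  p <- c(runif(4950), 10^(-runif(50, 8, 30)))
  lam <- genomic_control(p)
  expect_gte(lam, 0.95)
  expect_lte(lam, 1.1)
})

test_that("the mixed model stays calibrated under cryptic relatedness where OLS inflates", {
  set.seed(5)
  cfg <- sim_config(n_samples = 500, n_variants = 24000,
                    within_block_rho = 0, fst = 0, n_subpops = 1,
                    n_sib_pairs = 200, target_iv_r2 = 0,
                    polygenic_h2 = 0.7, confounder_on_exposure = 0,
                    ld_block_size = 1, seed = 5)
  g <- simulate_genotypes(cfg)
  m <- cfg$n_variants
  even <- seq(2, m, by = 2)
  odd <- seq(1, m, by = 2)
  # heritable trait built from the even variants; odd variants are null
  Ze <- scale(g$dosage[, even])
  bw <- rnorm(ncol(Ze))
  gpoly <- drop(Ze %*% bw)
  gpoly <- gpoly * sqrt(0.7) / sd(gpoly)
  y <- gpoly + rnorm(cfg$n_samples, 0, sqrt(0.3))
  K <- kinship(g)
  scan <- lmm_assoc(g, y, K = K, test_variants = g$variants$id[odd])
  t1_lmm <- mean(scan$results$p < 0.05, na.rm = TRUE)
  expect_gte(t1_lmm, 0.04)
  expect_lte(t1_lmm, 0.06)
  ols <- lmm_assoc(subset_variants(g, odd), y, K = diag(cfg$n_samples))
  t1_ols <- mean(ols$results$p < 0.05, na.rm = TRUE)
  expect_gt(t1_ols, 0.06)
  expect_gt(ols$lambda_gc, scan$lambda_gc)
})

test_that("an injected causal effect of 0.59 SD per allele is recovered", {
  cfg <- sim_config(n_samples = 2000, n_variants = 400, causal_index = 200,
                    exposure_effect = 0.59, causal_eaf = 0.49,
                    n_sib_pairs = 40, fst = 0.01, seed = 55)
  co <- simulate_cohort(cfg)
  p <- co$phenotypes
  y <- rank_inverse_normal(residualize(p$bilirubin, cbind(p$age, p$sex)))
  K <- kinship(co$genotypes)
  scan <- lmm_assoc(co$genotypes, y, covariates = cbind(p$bmi, p$t2d), K = K)
  hit <- scan$results[200, ]
  expect_lt(abs(hit$beta - 0.59), 3 * hit$se)
  expect_equal(scan$results$id[which.min(scan$results$p)], "rs200")
})

test_that("conditioning on an orthogonal variant leaves effects unchanged", {
  # construct exactly orthogonal centered dosage columns
  z1 <- rep(c(0, 2), each = 40)
  z2 <- rep(rep(c(0, 2), each = 20), 2)
  z3 <- rep(rep(c(0, 2), each = 10), 4)
  D <- cbind(z1, z2, z3)
  expect_equal(max(abs(crossprod(scale(D, scale = FALSE)))[upper.tri(diag(3))]), 0)
  g <- genotype_matrix(D, data.frame(chrom = "1", pos = 1:3 * 100,
                                     id = paste0("v", 1:3), ref = "A",
                                     alt = "G"))
  set.seed(66)
  y <- 0.3 * z3 + rnorm(80)
  plain <- lmm_assoc(g, y, K = diag(80))
  cond <- conditional_scan(g, y, K = diag(80), condition_on = "v1")
  expect_equal(cond$results$beta[cond$results$id == "v3"],
               plain$results$beta[plain$results$id == "v3"],
               tolerance = 1e-6)
})

test_that("conditioning on the causal variant removes the signal; proxies are flagged", {
  co <- quick_cohort(n = 600, m = 100, seed = 67, target_iv_r2 = 0.15)
  g <- co$genotypes
  p <- co$phenotypes
  y <- rank_inverse_normal(residualize(p$bilirubin, cbind(p$age, p$sex)))
  causal_id <- g$variants$id[co$config$causal_index]
  cond <- conditional_scan(g, y, K = diag(600), condition_on = causal_id)
  expect_false(causal_id %in% cond$results$id)
  expect_true(all(cond$results$p > 5e-8, na.rm = TRUE))
  # perfect proxy: duplicate the causal column
  D <- cbind(g$dosage, proxy = g$dosage[, co$config$causal_index])
  v <- rbind(g$variants[, 1:5],
             data.frame(chrom = "1", pos = 99999L, id = "proxy",
                        ref = "A", alt = "G"))
  g2 <- genotype_matrix(D, v)
  cond2 <- conditional_scan(g2, y, K = diag(600), condition_on = causal_id)
  proxy_row <- cond2$results[cond2$results$id == "proxy", ]
  expect_equal(proxy_row$flag, "collinear")
  expect_true(is.na(proxy_row$beta))
  expect_error(conditional_scan(g, y, K = diag(600), condition_on = "nope"),
               "not found")
})
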