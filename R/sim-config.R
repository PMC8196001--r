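#' Simulation configuration for the synthetic cohort
#'
#' Defines the generative model for a cohort whose causal chain is
#' variant -> serum bilirubin -> hypertension. Defaults reproduce the
#' architecture the downstream analyses assume: a single common causal
#' variant (effect-allele frequency 0.49) explaining ~12% of the exposure
#' variance, a polygenic background with SNP heritability 0.385, a binary
#' outcome with prevalence 0.26 whose liability decreases with the exposure
#' (odds ratio 0.46 per exposure SD), LD blocks, two subpopulations and a
#' handful of sibling pairs providing cryptic relatedness.
#'
#' @param n_samples number of samples.
#' @param n_variants number of variants.
#' @param causal_index column index of the causal variant.
#' @param causal_eaf effect-allele frequency of the causal variant, in (0,1).
#' @param exposure_effect optional per-allele effect on the exposure in
#'   exposure-SD units. When `NULL` (default) the effect is calibrated so
#'   the causal variant explains `target_iv_r2` of the exposure variance.
#' @param target_iv_r2 fraction of exposure variance explained by the causal
#'   variant, in `[0, 1)`. Ignored when `exposure_effect` is given.
#' @param polygenic_h2 fraction of exposure variance from the polygenic
#'   background, in `[0, 1)`.
#' @param outcome_prevalence target outcome prevalence in (0,1).
#' @param log_or_per_sd log odds of the outcome per SD of the exposure
#'   (negative = protective).
#' @param ld_block_size number of consecutive variants per LD block.
#' @param within_block_rho latent (copula) correlation within an LD block,
#'   in `[0, 1)`.
#' @param n_subpops number of subpopulations.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param n_sib_pairs number of sample pairs sharing parental haplotypes.
#' @param confounder_on_exposure,confounder_on_outcome loadings of the
#'   standard-normal confounder U on exposure and outcome liability. U is a
#'   common cause of both, so naive outcome-on-exposure regression is
#'   biased; instrument-based estimation is not.
#' @param sex_effect,age_effect,bmi_effect fixed covariate effects on the
#'   exposure (male indicator; per year, centered; per kg/m^2, centered).
#'   The positive default sex effect mirrors the higher mean bilirubin in
#'   men.
#' @param age_effect_outcome,bmi_effect_outcome covariate effects on the
#'   outcome liability (log-odds per centered unit).
#' @param polygenic_fraction fraction of non-causal variants carrying
#'   polygenic effects.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   cohorts.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1500L,
                       n_variants = 5000L,
                       causal_index = NULL,
                       causal_eaf = 0.49,
                       exposure_effect = NULL,
                       target_iv_r2 = 0.12,
                       polygenic_h2 = 0.385,
                       outcome_prevalence = 0.26,
                       log_or_per_sd = log(0.46),
                       ld_block_size = 25L,
                       within_block_rho = 0.6,
                       n_subpops = 2L,
                       fst = 0.01,
                       n_sib_pairs = 50L,
                       confounder_on_exposure = 0.3,
                       confounder_on_outcome = 0.5,
                       sex_effect = 0.25,
                       age_effect = 0.004,
                       bmi_effect = -0.01,
                       age_effect_outcome = 0.02,
                       bmi_effect_outcome = 0.02,
                       polygenic_fraction = 1.0,
                       seed = 1L) {
  if (is.null(causal_index)) causal_index <- max(1L, n_variants %/% 2L)
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              causal_index = as.integer(causal_index),
              causal_eaf = causal_eaf,
              exposure_effect = exposure_effect,
              target_iv_r2 = target_iv_r2,
              polygenic_h2 = polygenic_h2,
              outcome_prevalence = outcome_prevalence,
              log_or_per_sd = log_or_per_sd,
              ld_block_size = as.integer(ld_block_size),
              within_block_rho = within_block_rho,
              n_subpops = as.integer(n_subpops),
              fst = fst,
              n_sib_pairs = as.integer(n_sib_pairs),
              confounder_on_exposure = confounder_on_exposure,
              confounder_on_outcome = confounder_on_outcome,
              sex_effect = sex_effect,
              age_effect = age_effect,
              bmi_effect = bmi_effect,
              age_effect_outcome = age_effect_outcome,
              bmi_effect_outcome = bmi_effect_outcome,
              polygenic_fraction = polygenic_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", why,
                          call. = FALSE)
  }
  chk(cfg$n_samples >= 2, "n_samples", "must be >= 2")
  chk(cfg$n_variants >= 1, "n_variants", "must be >= 1")
  chk(cfg$causal_index >= 1 && cfg$causal_index <= cfg$n_variants,
      "causal_index", "must index a variant")
  chk(cfg$causal_eaf > 0 && cfg$causal_eaf < 1, "causal_eaf",
      "must be in (0, 1)")
  chk(cfg$target_iv_r2 >= 0 && cfg$target_iv_r2 < 1, "target_iv_r2",
      "must be in [0, 1)")
  chk(cfg$polygenic_h2 >= 0 && cfg$polygenic_h2 < 1, "polygenic_h2",
      "must be in [0, 1)")
  chk(cfg$polygenic_h2 + cfg$target_iv_r2 < 1, "polygenic_h2",
      "polygenic_h2 + target_iv_r2 must be < 1")
  chk(cfg$outcome_prevalence > 0 && cfg$outcome_prevalence < 1,
      "outcome_prevalence", "must be in (0, 1)")
  chk(cfg$ld_block_size >= 1, "ld_block_size", "must be >= 1")
  chk(cfg$within_block_rho >= 0 && cfg$within_block_rho < 1,
      "within_block_rho", "must be in [0, 1)")
  chk(cfg$n_subpops >= 1, "n_subpops", "must be >= 1")
  chk(cfg$fst >= 0 && cfg$fst < 1, "fst", "must be in [0, 1)")
  chk(cfg$n_sib_pairs >= 0 && 2L * cfg$n_sib_pairs <= cfg$n_samples,
      "n_sib_pairs", "needs 2 * n_sib_pairs <= n_samples")
  leftover <- 1 - cfg$target_iv_r2 - cfg$polygenic_h2 -
    cfg$confounder_on_exposure^2
  chk(leftover > 0, "confounder_on_exposure",
      "iv R2 + polygenic h2 + confounder loading^2 must leave positive noise variance")
  chk(cfg$polygenic_fraction > 0 && cfg$polygenic_fraction <= 1,
      "polygenic_fraction", "must be in (0, 1]")
  cfg
}
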