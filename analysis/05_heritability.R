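#!/usr/bin/env Rscript
# Stage 5: SNP heritability of log bilirubin by REML under
# Var(y) = sigma_g^2 G + sigma_e^2 I, with G the LD-weighted kinship
# (inverse local LD score weights, common variants MAF > 0.05) and age,
# sex, BMI and T2D as fixed covariates.
suppressPackageStartupMessages(library(bilicausal))

g <- read_vcf("results/cohort.vcf")
pheno <- read_phenotypes("results/phenotypes.tsv")

g <- filter_variants(g, maf_min = 0.05)
w <- ld_weights(g, window_bp = 1e6)
Kw <- weighted_kinship(g, w)
trait <- log(pheno$bilirubin - min(pheno$bilirubin) + 1)
vc <- reml_h2(trait, Kw,
              covariates = cbind(pheno$age, pheno$sex, pheno$bmi, pheno$t2d))
print(vc)
jsonlite::write_json(list(h2_snp = vc$h2_snp, se_h2 = vc$se_h2,
                          sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                          n_variants = ncol(g$dosage)),
                     "results/h2.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/h2.json\n")
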