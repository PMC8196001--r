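#!/usr/bin/env Rscript
# Stage 2: descriptive comparison of the cohort by sex — mean (SD) with
# Welch t for continuous traits, N (%) with uncorrected chi-square for
# binary traits, plus the sex-split goodness of fit.
suppressPackageStartupMessages(library(bilicausal))

pheno <- read_phenotypes("results/phenotypes.tsv")
tab <- table1(pheno, group = "sex")
data.table::fwrite(tab, "results/table1.tsv", sep = "\t")
print(tab, digits = 4)
cat("wrote results/table1.tsv\n")
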