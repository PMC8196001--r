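#!/usr/bin/env Rscript
# Stage 6: additive Bayesian network over the seven nodes (causal-variant
# dosage, bilirubin, hypertension, sex, age, BMI, T2D). Greedy
# hill-climbing searches with BIC-penalized GLM scores; edges present in
# at least half of the locally optimal networks form the consensus. The
# genotype node is constrained parentless.
suppressPackageStartupMessages(library(bilicausal))

g <- read_vcf("results/cohort.vcf")
pheno <- read_phenotypes("results/phenotypes.tsv")
truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)

net_data <- data.frame(variant = g$dosage[, truth$causal_id],
                       bilirubin = pheno$bilirubin,
                       hypertension = pheno$hypertension,
                       sex = pheno$sex, age = pheno$age, bmi = pheno$bmi,
                       t2d = pheno$t2d)
specs <- node_specs(names(net_data),
                    c("gaussian", "gaussian", "bernoulli", "bernoulli",
                      "gaussian", "gaussian", "bernoulli"),
                    no_parents = "variant")
net <- consensus(net_data, specs, n_searches = 200, threshold = 0.5,
                 seed = 2026)
print(net)
writeLines(network_dot(net), "results/network.dot")
jsonlite::write_json(list(edges = net$edge_freq, n_searches = net$n_searches),
                     "results/network.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/network.json and results/network.dot\n")
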