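#!/usr/bin/env Rscript
# Stage 4: Bayes-factor fine mapping of the top associated region.
# Takes the marginal z-scores and the LD matrix of the 51-variant window
# around the index variant (MAF >= 1%), enumerates single-causal
# configurations and reports marginal posterior inclusion probabilities.
suppressPackageStartupMessages(library(bilicausal))

g <- read_vcf("results/cohort.vcf")
ss <- read_summary_stats("results/sumstats.tsv")

top_idx <- which.min(ss$p)
idx <- max(1, top_idx - 25):min(nrow(ss), top_idx + 25)
keep_ids <- ss$id[idx]
gpos <- match(keep_ids, g$variants$id)
region <- subset_variants(g, gpos)
maf_ok <- pmin(region$variants$eaf, 1 - region$variants$eaf) >= 0.01
region <- subset_variants(region, which(maf_ok))
sub <- ss[idx, ][maf_ok, ]

rs <- region_stats(z = sub$beta / sub$se, R = ld_matrix(region),
                   n = sub$n[1], ids = sub$id)
fm <- pip(rs, max_causal = 1)
data.table::fwrite(data.frame(id = names(fm$pip),
                              logBF_single = unname(fm$log_bf_single),
                              pip = unname(fm$pip)),
                   "results/finemap.tsv", sep = "\t")
best <- which.max(fm$pip)
cat(sprintf("region: %d variants around %s\n", length(fm$pip),
            ss$id[top_idx]))
cat(sprintf("top PIP: %s = %.3f\n", names(fm$pip)[best], fm$pip[best]))
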