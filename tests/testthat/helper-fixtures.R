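# Shared fixture builders: everything is generated in code at test time.

vcf_header <- function(samples, format_id = "GT") {
  c("##fileformat=VCFv4.2",
    if (format_id == "GT")
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
    else
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_toy_vcf <- function(records, samples = c("S1", "S2", "S3"),
                          format_id = "GT") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(samples, format_id), records), path)
  path
}

vcf_record <- function(chrom = "1", pos = 100, id = "rs1", ref = "A",
                       alt = "G", info = ".", format_id = "GT",
                       calls = c("0/0", "0/1", "1/1")) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, format_id, calls),
        collapse = "\t")
}

# small unstructured cohort used by several tests
quick_cohort <- function(n = 400, m = 200, seed = 1, ...) {
  simulate_cohort(sim_config(n_samples = n, n_variants = m, seed = seed,
                             fst = 0, n_subpops = 1, n_sib_pairs = 0,
                             within_block_rho = 0,
                             causal_index = max(1, m %/% 2), ...))
}
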