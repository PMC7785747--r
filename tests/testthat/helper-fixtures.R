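# Shared fixtures, built in code at test time.

# canonical seed for all stochastic tests
TEST_SEED <- 42L

# Table-1-style worked example: FI at the ZNF12 lead SNP, women then men
znf12 <- list(beta = c(0.0262, 0.0067), se = c(0.0046, 0.0051))

write_toy_sumstats <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# a small valid panel data.frame for harmonization / QC tests
toy_records <- function(n = 5) {
  data.frame(marker_id = sprintf("rs%d", seq_len(n)),
             chrom = rep(1, n), pos = seq_len(n) * 1000,
             effect_allele = rep("A", n), other_allele = rep("G", n),
             eaf = rep(0.3, n), beta = rep(0.1, n), se = rep(0.05, n),
             n = rep(1000, n), info = rep(0.9, n), strand = rep("+", n),
             call_rate = rep(0.99, n), hwe_p = rep(0.5, n),
             mac = rep(500, n), stringsAsFactors = FALSE)
}
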