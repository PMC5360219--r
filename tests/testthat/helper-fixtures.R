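# Shared fixtures, built in code at test time.

# The classic 4-record toy problem: three events, one censored, binary x.
toy_records <- function() {
  data.frame(exit_age = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
             x = c(1, 0, 1, 0))
}

# Vectorized Breslow partial log-likelihood for the toy problem, for
# grid-search oracles (independent of the package's fitting path).
toy_partial_loglik <- function(b) {
  # risk sets at event times 1, 2, 3 for toy_records()
  (b - log(2 * exp(b) + 2)) + (0 - log(exp(b) + 2)) + (b - log(exp(b) + 1))
}

# Small simulated cohort with a single causal covariate.
single_snp_cohort <- function(n = 2000, beta = 0.5, freq = 0.3, seed = 1) {
  panel <- data.frame(id = "snp1", freq = freq, beta = beta)
  cfg <- sim_config(n, variants = panel, apoe_betas = c(e2 = 0, e4 = 0),
                    followup = c(70, 95), seed = seed)
  simulate_onset(simulate_genotypes(cfg), cfg)
}

# Minimal VCF written to a temp file; returns the path.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rsA", "G", "A", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("2", "200", "rsB", "T", "C", ".", ".", ".", "GT",
          "0/1", "./.", "1|1", sep = "\t")), path)
  path
}

# Two-point score distribution with explicit weights.
two_point_dist <- function(s = c(0, log(2)), w = c(0.5, 0.5)) {
  s <- s - sum(w * s) + sum(w * s)  # keep as supplied (no re-centering)
  o <- order(s)
  structure(list(s = s[o], w = w[o], cumw = cumsum(w[o]),
                 e4 = c(FALSE, TRUE)[o], mean_raw = 0, method = "exact"),
            class = "phs_dist")
}
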