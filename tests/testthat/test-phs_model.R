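# Score derivation: prescreen, stepwise selection, bootstrap averaging,
# scoring, and the reference distribution.

test_that("prescreen filters on the p-value threshold and direction", {
  tab <- data.frame(snp = c("a", "b", "c", "d"),
                    beta = c(0.2, -0.1, 0.3, 0.1),
                    p = c(1e-7, 1e-6, 1e-4, 0.5))
  expect_equal(prescreen(tab), c("a", "b"))
  expect_equal(prescreen(tab, p_threshold = 1 - 1e-12), tab$snp)
  expect_equal(prescreen(tab, direction_filter = TRUE), "a")
  expect_equal(prescreen(tab[0, ]), character(0))
  expect_error(prescreen(data.frame(snp = "a", p = 0)), "0, 1")
  expect_error(prescreen(tab, p_threshold = 2), "p_threshold")
})

test_that("stepwise selection finds a causal SNP first and halts on nulls", {
  set.seed(61)
  base <- c("sex", "apoe_e2", "apoe_e4", paste0("pc", 1:5))
  first_causal <- replicate(5, {
    panel <- data.frame(id = sprintf("v%02d", 1:21),
                        freq = runif(21, 0.1, 0.5),
                        beta = c(0.6, rep(0, 20)))
    cfg <- sim_config(3000, variants = panel, followup = c(70, 95),
                      seed = sample.int(1e6, 1))
    co <- simulate_onset(simulate_genotypes(cfg), cfg)
    sel <- stepwise_select(co, panel$id, base, max_steps = 1)
    identical(sel$selected[1], "v01")
  })
  expect_true(all(first_causal))
  # all-null candidates: selection stays essentially empty
  n_sel <- replicate(5, {
    panel <- data.frame(id = sprintf("n%02d", 1:15),
                        freq = runif(15, 0.1, 0.5), beta = 0)
    cfg <- sim_config(1500, variants = panel, followup = c(70, 95),
                      seed = sample.int(1e6, 1))
    co <- simulate_onset(simulate_genotypes(cfg), cfg)
    length(stepwise_select(co, panel$id, base)$selected)
  })
  expect_true(all(n_sel <= 2))
  # empty candidate pool: immediate halt recorded in the trace
  co <- single_snp_cohort(n = 300, beta = 0, seed = 1)
  co$sex <- rbinom(300, 1, 0.5)
  sel0 <- stepwise_select(co, character(0), c("sex"))
  expect_length(sel0$selected, 0)
  expect_match(sel0$trace$reason[1], "empty")
})

test_that("selection criterion decreases strictly along accepted steps", {
  set.seed(62)
  panel <- data.frame(id = sprintf("v%02d", 1:10),
                      freq = runif(10, 0.2, 0.5),
                      beta = c(0.4, 0.3, 0.25, rep(0, 7)))
  cfg <- sim_config(2500, variants = panel, followup = c(70, 95), seed = 63)
  co <- simulate_onset(simulate_genotypes(cfg), cfg)
  sel <- stepwise_select(co, panel$id, c("sex", "apoe_e2", "apoe_e4"))
  acc <- sel$trace[sel$trace$accepted, ]
  expect_true(all(acc$criterion_after < acc$criterion_before))
  expect_true(all(diff(acc$criterion_after) < 0) || nrow(acc) <= 1)
})

test_that("bootstrap averaging is consistent and reduces to the full fit", {
  co <- single_snp_cohort(n = 4000, beta = 0.4, seed = 64)
  co$sex <- rbinom(nrow(co), 1, 0.5)
  # resample-free debug mode equals the full-data fit
  full <- fit_cox(co, c("sex", "snp1"))
  bb1 <- bootstrap_betas(co, "snp1", "sex", B = 1, seed = 1, resample = FALSE)
  expect_equal(bb1$beta[bb1$id == "snp1"], unname(full$beta["snp1"]),
               tolerance = 1e-10)
  expect_error(bootstrap_betas(co, "snp1", "sex", B = 0), "B must be")
  # bootstrap mean near truth, bootstrap SE near the analytic SE
  bb <- bootstrap_betas(co, "snp1", "sex", B = 150, seed = 2)
  row <- bb[bb$id == "snp1", ]
  expect_lt(abs(row$beta - 0.4), 3 * row$se)
  expect_lt(abs(row$se - full$se[["snp1"]]) / full$se[["snp1"]], 0.3)
  # two seeds agree within Monte-Carlo error
  bb_b <- bootstrap_betas(co, "snp1", "sex", B = 150, seed = 99)
  mc_se <- row$se / sqrt(150)
  expect_lt(abs(row$beta - bb_b$beta[bb_b$id == "snp1"]), 3 * sqrt(2) * mc_se)
})

test_that("compute_phs sums the published weights correctly", {
  w <- phs_weights_ad()
  snps <- w$id[!w$id %in% c("APOE_e2", "APOE_e4")]
  zero <- matrix(0, 1, length(snps), dimnames = list("i1", snps))
  expect_equal(unname(compute_phs(w, zero, apoe_e2 = 0, apoe_e4 = 0)), 0)
  # single e4 copy scores exactly its published weight
  expect_equal(unname(compute_phs(w, zero, apoe_e2 = 0, apoe_e4 = 1)), 1.03)
  # hand sum: 2 x (-0.15) + 0.17 + 1.03 = 0.90
  g <- zero; g[1, "rs6733839"] <- 2; g[1, "rs115124923"] <- 1
  expect_equal(unname(compute_phs(w, g, apoe_e2 = 0, apoe_e4 = 1)), 0.90,
               tolerance = 1e-12)
})

test_that("compute_phs is linear, imputes missing dosages, aligns alleles", {
  bt <- data.frame(id = c("x1", "x2"), beta = c(0.3, -0.2))
  g1 <- matrix(c(1, 2, 0, 1), 2, 2, dimnames = list(NULL, c("x1", "x2")))
  g2 <- matrix(c(1, 0, 2, 1), 2, 2, dimnames = list(NULL, c("x1", "x2")))
  s12 <- compute_phs(bt, g1 + g2)
  expect_equal(s12, compute_phs(bt, g1) + compute_phs(bt, g2))
  # mean imputation at 2f
  gna <- g1; gna[1, "x2"] <- NA
  s <- compute_phs(bt, gna, freqs = c(x2 = 0.25))
  expect_equal(unname(s[1]), 0.3 * 1 - 0.2 * 0.5)
  expect_error(compute_phs(bt, gna), "imputation")
  # allele mismatch resolved by flip; unresolvable raises a named error
  geno <- structure(list(
    dosage = matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
                    dimnames = list(NULL, c("x1", "x2"))),
    variants = data.frame(id = c("x1", "x2"), effect_allele = c("A", "C"),
                          other_allele = c("G", "T")),
    individuals = 1:3, apoe_e2 = rep(0, 3), apoe_e4 = rep(0, 3)),
    class = "phs_genotypes")
  bt2 <- data.frame(id = c("x1", "x2"), beta = c(0.5, 1),
                    effect_allele = c("G", "C"))
  s2 <- compute_phs(bt2, geno)
  expect_equal(unname(s2), 0.5 * (2 - c(0, 1, 2)) + c(2, 1, 0))
  bt3 <- data.frame(id = "x1", beta = 0.5, effect_allele = "T")
  expect_error(compute_phs(bt3, geno), "x1")
})

test_that("reference distribution enumerates exactly and matches Monte Carlo", {
  # single SNP, f = 0.5, beta = ln 2: support at dosage x ln2, centered
  bt <- data.frame(id = "v", beta = log(2))
  d <- reference_distribution(bt, c(v = 0.5), apoe_betas = c(e2 = 0, e4 = 0),
                              method = "exact")
  expect_equal(sort(unique(round(d$s + d$mean_raw, 10))),
               round(log(2) * 0:2, 10))
  agg <- tapply(d$w, round(d$s, 10), sum)
  expect_equal(unname(as.vector(agg)), c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(d$mean_raw, log(2))  # 2 f beta with zero APOE expectation
  expect_equal(sum(d$w * d$s), 0, tolerance = 1e-12)
  # mean of the uncentered distribution is linear in the weights
  bt8 <- data.frame(id = paste0("v", 1:8), beta = seq(-0.3, 0.4, length.out = 8))
  f8 <- stats::setNames(seq(0.1, 0.45, length.out = 8), bt8$id)
  ab <- c(e2 = -0.47, e4 = 1.03)
  d8 <- reference_distribution(bt8, f8, apoe_betas = ab, method = "exact")
  apoe_mean <- 2 * 0.08 * ab[["e2"]] + 2 * 0.14 * ab[["e4"]]
  expect_equal(d8$mean_raw, sum(2 * f8 * bt8$beta) + apoe_mean,
               tolerance = 1e-10)
  # Monte-Carlo CDF within the DKW bound of the exact CDF
  n_mc <- 4e4
  dmc <- reference_distribution(bt8, f8, apoe_betas = ab,
                                method = "monte_carlo", n_mc = n_mc, seed = 9)
  qs <- seq(-1.5, 2.5, by = 0.05)
  gap <- max(abs(dist_cdf(dmc, qs) - dist_cdf(d8, qs)))
  expect_lt(gap, 3 / sqrt(n_mc))
  expect_error(reference_distribution(
    data.frame(id = paste0("w", 1:13), beta = 0.1),
    stats::setNames(rep(0.2, 13), paste0("w", 1:13)), method = "exact"),
    "monte_carlo")
})

test_that("percentiles behave as a probability integral transform", {
  w <- phs_weights_ad()
  fr <- synthetic_snp_freqs()
  dist <- reference_distribution(w, fr, method = "monte_carlo", n_mc = 1e5,
                                 seed = 10)
  med <- dist_quantile(dist, 0.5)
  expect_lt(abs(percentile_of(med, dist) - 50), 0.5)
  expect_lt(abs(percentile_of(dist_quantile(dist, 0.99), dist) - 99), 0.5)
  # scores of an independently simulated population are uniform percentiles
  set.seed(11)
  n <- 2000
  snps <- w[!w$id %in% c("APOE_e2", "APOE_e4"), ]
  G <- sapply(snps$id, function(id) rbinom(n, 2, fr[[id]]))
  al <- matrix(sample(c("e2", "e3", "e4"), 2 * n, TRUE,
                      prob = c(0.08, 0.78, 0.14)), ncol = 2)
  s <- compute_phs(w, G, apoe_e2 = rowSums(al == "e2"),
                   apoe_e4 = rowSums(al == "e4"), center = dist)
  pct <- percentile_of(s, dist)
  # occasional tied scores only blunt the KS test slightly
  ks <- suppressWarnings(stats::ks.test(pct / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
  # conditioning on carrier status shifts the distribution upward
  d4 <- condition_apoe(dist, TRUE)
  d0 <- condition_apoe(dist, FALSE)
  expect_gt(sum(d4$w * d4$s), sum(d0$w * d0$s))
})
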