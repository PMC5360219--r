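# Synthetic genotype + age-of-onset cohort generator. Genotypes are drawn
# under Hardy-Weinberg and linkage equilibrium; onset ages follow a Gompertz
# baseline hazard with proportional polygenic effects; last-visit ages give
# non-informative right censoring; cohort or case-control ascertainment.

#' Default SNP panel for simulation
#'
#' A fixed panel of common variants whose effect sizes are scaled so the
#' SNP-only score has a chosen population standard deviation (default 0.35,
#' the scale implied by a top-versus-bottom-decile hazard ratio near 3.3
#' within a fixed APOE stratum).
#'
#' @param n_snps number of SNPs (recycled from the fixed panel, max 15).
#' @param score_sd target standard deviation of the SNP score under HWE/LE.
#' @return data frame with `id`, `freq`, `beta`.
#' @export
default_variant_panel <- function(n_snps = 15, score_sd = 0.35) {
  freq <- c(0.12, 0.33, 0.41, 0.18, 0.27, 0.09, 0.46, 0.22, 0.38, 0.15,
            0.30, 0.25, 0.35, 0.20, 0.43)
  beta <- c(0.30, -0.12, 0.09, 0.22, -0.18, 0.28, 0.07, -0.15, 0.11, 0.25,
            -0.09, 0.17, -0.08, 0.20, 0.10)
  stopifnot(n_snps >= 1, n_snps <= length(freq))
  freq <- freq[seq_len(n_snps)]
  beta <- beta[seq_len(n_snps)]
  v <- sum(beta^2 * 2 * freq * (1 - freq))
  beta <- beta * score_sd / sqrt(v)
  data.frame(id = sprintf("sim_snp_%02d", seq_len(n_snps)),
             freq = freq, beta = beta)
}

#' Simulation configuration
#'
#' Defines the generating model for synthetic cohorts: the variant panel
#' (effect-allele frequencies and true log hazard ratios), the APOE
#' three-allele system, the Gompertz baseline hazard
#' \eqn{h(t) = \lambda e^{\gamma (t - 60)}} anchored at age 60, the
#' last-visit (censoring) window, and the study design.
#'
#' Defaults anchor the baseline to the published US incidence endpoints
#' (0.08 per 100 person-years at 60, 12.10 at 95): \eqn{\lambda = 8\times
#' 10^{-4}}/yr and \eqn{\gamma = \ln(12.10/0.08)/35 \approx 0.1434}/yr.
#'
#' @param n_individuals cohort (or pool) size.
#' @param variants data frame `id`, `freq`, `beta`; default panel via
#'   [default_variant_panel()].
#' @param apoe_freqs allele frequencies `c(e2, e3, e4)` (sum to 1).
#' @param apoe_betas log hazard ratios `c(e2, e4)` per allele copy.
#' @param lambda baseline hazard per year at age 60 (> 0).
#' @param gamma exponential growth of the hazard per year (> 0).
#' @param followup `c(min, max)` age of last clinical visit (max > min >= 60).
#' @param sex_beta log hazard ratio for sex (0/1 coded), default 0.
#' @param study_design `"cohort"` or `"case_control"`.
#' @param n_cases,n_controls case-control ascertainment counts.
#' @param seed integer seed; every simulation call is reproducible under it.
#' @return object of class `phs_sim_config`.
#' @export
sim_config <- function(n_individuals,
                       variants = default_variant_panel(),
                       apoe_freqs = c(e2 = 0.08, e3 = 0.78, e4 = 0.14),
                       apoe_betas = c(e2 = -0.47, e4 = 1.03),
                       lambda = 8e-4,
                       gamma = log(12.10 / 0.08) / 35,
                       followup = c(65, 95),
                       sex_beta = 0,
                       study_design = c("cohort", "case_control"),
                       n_cases = NULL, n_controls = NULL,
                       seed = 1L) {
  study_design <- match.arg(study_design)
  stopifnot(is.data.frame(variants),
            all(c("id", "freq", "beta") %in% names(variants)))
  if (any(variants$freq < 0 | variants$freq > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  if (abs(sum(apoe_freqs) - 1) > 1e-8 || any(apoe_freqs < 0)) {
    stop("APOE allele frequencies must be nonnegative and sum to 1")
  }
  if (lambda <= 0) stop("gompertz rate lambda must be > 0")
  if (gamma <= 0) stop("gompertz slope gamma must be > 0")
  if (length(followup) != 2 || followup[2] <= followup[1] || followup[1] < 60) {
    stop("followup window must satisfy max > min >= 60")
  }
  if (study_design == "case_control" &&
      (is.null(n_cases) || is.null(n_controls))) {
    stop("case_control design needs n_cases and n_controls")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 variants = variants, apoe_freqs = apoe_freqs,
                 apoe_betas = apoe_betas, lambda = lambda, gamma = gamma,
                 followup = followup, sex_beta = sex_beta,
                 study_design = study_design,
                 n_cases = n_cases, n_controls = n_controls,
                 seed = as.integer(seed)),
            class = "phs_sim_config")
}

#' Simulate genotype dosages under HWE and linkage equilibrium
#'
#' Effect-allele dosages are independent Binomial(2, f_j) across variants
#' and individuals. APOE is sampled as a three-allele genotype (two alleles
#' from the e2/e3/e4 frequencies), so the e2 + e4 dosage never exceeds 2.
#'
#' @param config a [sim_config()].
#' @return object of class `phs_genotypes`: dosage matrix (individuals x
#'   variants), variant table, individual ids, and `apoe_e2`/`apoe_e4`
#'   dosage vectors.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "phs_sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- nrow(config$variants)
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(config$variants$freq, each = n)),
                   nrow = n, ncol = m,
                   dimnames = list(sprintf("id_%06d", seq_len(n)),
                                   config$variants$id))
  alleles <- matrix(sample(c("e2", "e3", "e4"), 2 * n, replace = TRUE,
                           prob = config$apoe_freqs), ncol = 2)
  variants <- config$variants
  variants$effect_allele <- rep("A", m)
  variants$other_allele <- rep("G", m)
  structure(list(dosage = dosage,
                 variants = variants,
                 individuals = rownames(dosage),
                 apoe_e2 = rowSums(alleles == "e2"),
                 apoe_e4 = rowSums(alleles == "e4")),
            class = "phs_genotypes")
}

# Population mean of the raw genetic score under HWE/LE (used to center s).
population_score_mean <- function(config) {
  f <- config$apoe_freqs
  sum(2 * config$variants$freq * config$variants$beta) +
    2 * f[["e2"]] * config$apoe_betas[["e2"]] +
    2 * f[["e4"]] * config$apoe_betas[["e4"]]
}

# Inverse-CDF draw from the Gompertz hazard lambda*exp(gamma*(t-60))*exp(s).
gompertz_onset <- function(n, s, lambda, gamma) {
  e <- stats::rexp(n)
  60 + log(1 + gamma * e / (lambda * exp(s))) / gamma
}

#' Simulate ages of onset and censoring
#'
#' Event times are drawn from the proportional-hazards Gompertz model
#' \eqn{h(t\mid s) = \lambda e^{\gamma(t-60)} e^{s}}, where the polygenic
#' score \eqn{s = \sum_j \beta_j g_{ij}} (SNP and APOE terms) is centered at
#' its population mean, so \eqn{\lambda} is the baseline hazard at the mean
#' genetic profile. Last-visit ages are uniform over the follow-up window,
#' independent of genotype.
#'
#' @param genotypes a [simulate_genotypes()] result.
#' @param config the matching [sim_config()].
#' @return object of class `phs_cohort`: a data frame with `iid`, `sex`,
#'   `apoe_e2`, `apoe_e4`, `pc1`..`pc5`, `entry_age`, `exit_age`, `event`,
#'   the true score `s_true`, the latent `onset_age`, and one dosage column
#'   per variant.
#' @export
simulate_onset <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "phs_genotypes"),
            inherits(config, "phs_sim_config"))
  if (config$lambda <= 0 || config$gamma <= 0) stop("lambda and gamma must be > 0")
  set.seed(config$seed + 1L)
  n <- nrow(genotypes$dosage)
  s_raw <- drop(genotypes$dosage %*% config$variants$beta) +
    config$apoe_betas[["e2"]] * genotypes$apoe_e2 +
    config$apoe_betas[["e4"]] * genotypes$apoe_e4
  s <- s_raw - population_score_mean(config)
  sex <- stats::rbinom(n, 1L, 0.5)
  eta <- s + config$sex_beta * sex
  onset <- gompertz_onset(n, eta, config$lambda, config$gamma)
  visit <- stats::runif(n, config$followup[1], config$followup[2])
  event <- as.integer(onset <= visit)
  cohort <- data.frame(iid = genotypes$individuals,
                       sex = sex,
                       apoe_e2 = genotypes$apoe_e2,
                       apoe_e4 = genotypes$apoe_e4,
                       matrix(stats::rnorm(5 * n), ncol = 5,
                              dimnames = list(NULL, paste0("pc", 1:5))),
                       entry_age = 60,
                       exit_age = ifelse(event == 1, onset, visit),
                       event = event,
                       s_true = s,
                       onset_age = onset,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(genotypes$dosage))
  class(cohort) <- c("phs_cohort", "data.frame")
  cohort
}

#' Simulate onset from externally supplied scores
#'
#' Same event-time model as [simulate_onset()] but with a user-supplied
#' vector of (already centered) log relative hazards, e.g. Gaussian scores
#' for analytic checks.
#'
#' @param s numeric vector of log relative hazards.
#' @param config a [sim_config()] (its `n_individuals` is ignored).
#' @return `phs_cohort` data frame without dosage columns.
#' @export
simulate_onset_from_scores <- function(s, config) {
  stopifnot(inherits(config, "phs_sim_config"))
  set.seed(config$seed + 1L)
  n <- length(s)
  onset <- gompertz_onset(n, s, config$lambda, config$gamma)
  visit <- stats::runif(n, config$followup[1], config$followup[2])
  event <- as.integer(onset <= visit)
  cohort <- data.frame(iid = sprintf("id_%06d", seq_len(n)),
                       entry_age = 60,
                       exit_age = ifelse(event == 1, onset, visit),
                       event = event, s_true = s, onset_age = onset)
  class(cohort) <- c("phs_cohort", "data.frame")
  cohort
}

#' Ascertain a study sample from a simulated pool
#'
#' Applies the minimum-onset-age exclusion (events with onset before 60 are
#' removed) and, under the case-control design, samples the requested
#' numbers of cases and controls from the pool.
#'
#' @param cohort a `phs_cohort`.
#' @param config the matching [sim_config()].
#' @return the ascertained `phs_cohort`.
#' @export
ascertain <- function(cohort, config) {
  stopifnot(inherits(config, "phs_sim_config"))
  keep <- !(cohort$event == 1 & cohort$exit_age < 60)
  cohort <- cohort[keep, , drop = FALSE]
  if (!nrow(cohort)) stop("ascertainment removed every record")
  if (config$study_design == "cohort") return(cohort)
  set.seed(config$seed + 2L)
  cases <- which(cohort$event == 1)
  controls <- which(cohort$event == 0)
  if (length(cases) < config$n_cases || length(controls) < config$n_controls) {
    stop("requested ", config$n_cases, " cases / ", config$n_controls,
         " controls but pool has ", length(cases), " / ", length(controls))
  }
  idx <- c(sample(cases, config$n_cases), sample(controls, config$n_controls))
  cohort[sort(idx), , drop = FALSE]
}

#' Population incidence implied by a simulation configuration
#'
#' The age-specific hazard of the generated population among survivors,
#' \eqn{h_{pop}(t) = \lambda e^{\gamma(t-60)} E[e^s \mid T \ge t]}, computed
#' by marching the exact (or Monte Carlo) score distribution over an age
#' grid. Returned as an annualized-rate table usable as a calibration
#' baseline.
#'
#' @param config a [sim_config()].
#' @param ages knot ages for the returned table.
#' @param dt marching step in years.
#' @return data frame `age`, `rate_per_100py` (class `phs_baseline`).
#' @export
population_incidence <- function(config, ages = seq(60, 95, by = 5),
                                 dt = 0.25) {
  betas <- data.frame(id = config$variants$id, beta = config$variants$beta)
  dist <- reference_distribution(
    betas, freqs = stats::setNames(config$variants$freq, config$variants$id),
    apoe_freqs = config$apoe_freqs, apoe_betas = config$apoe_betas,
    method = if (nrow(betas) <= 12) "exact" else "monte_carlo",
    n_mc = 2e5, seed = config$seed)
  grid <- seq(60, max(ages) + 1, by = dt)
  S <- rep(1, length(dist$s))
  es <- exp(dist$s)
  hpop <- numeric(length(grid))
  for (k in seq_along(grid)) {
    w <- dist$w * S
    hpop[k] <- config$lambda * exp(config$gamma * (grid[k] - 60)) *
      sum(w * es) / sum(w)
    S <- S * exp(-config$lambda * exp(config$gamma * (grid[k] - 60)) * es * dt)
  }
  h_at <- stats::approx(grid, hpop, xout = ages)$y
  baseline_incidence(ages, 100 * (1 - exp(-h_at)))
}
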