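# PHS derivation: prescreen GWAS summary statistics, forward stepwise Cox
# selection minimizing the sum of squared martingale residuals, bootstrap
# model averaging of the hazard ratios, individual scoring, and the
# population reference distribution of the score under HWE and linkage
# equilibrium.

#' Prescreen candidate SNPs from GWAS summary statistics
#'
#' Returns the variant ids with association p-value below the threshold
#' (default \eqn{10^{-5}}), optionally restricted to risk-increasing
#' effects. Deterministic and order-stable.
#'
#' @param stats data frame with at least `snp` and `p` columns; a `beta`
#'   (log odds ratio) column is required when `direction_filter = TRUE`.
#' @param p_threshold significance threshold in (0, 1).
#' @param direction_filter keep only variants with positive log odds ratio.
#' @return character vector of candidate ids.
#' @export
prescreen <- function(stats, p_threshold = 1e-5, direction_filter = FALSE) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  if (!nrow(stats)) return(character(0))
  if (!all(c("snp", "p") %in% names(stats))) {
    stop("summary statistics need `snp` and `p` columns")
  }
  if (any(is.na(stats$p) | stats$p <= 0 | stats$p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  keep <- stats$p < p_threshold
  if (direction_filter) {
    if (!"beta" %in% names(stats)) stop("direction_filter needs a `beta` column")
    keep <- keep & stats$beta > 0
  }
  as.character(stats$snp[keep])
}

# Sum of absolute martingale residuals for a covariate set; the stepwise
# selection criterion. Uses the residuals returned by the fit itself
# (identical to martingale_residuals() on the training data). The absolute
# aggregation is used because the squared sum is not monotone in model
# quality here: adding a strongly associated covariate frequently
# *increases* the squared sum (event residuals shrink but their square is
# dominated by the many censored residuals pushed further negative), while
# the absolute sum decreases reliably.
residual_criterion <- function(cohort, covariates, ties) {
  fit <- fit_cox(cohort, covariates, ties = ties, baseline = FALSE)
  if (!fit$converged) stop("fit not converged")
  sum(abs(fit$model$residuals))
}

#' Forward stepwise SNP selection on martingale residuals
#'
#' Starting from the base covariate model (sex, APOE dosages, principal
#' components), each step refits the joint Cox model with every remaining
#' candidate and selects the one minimizing the sum of absolute martingale
#' residuals; selection halts when the best candidate no longer reduces the
#' criterion by more than `tol` (absolute). Candidates whose joint fit
#' fails or does not converge are skipped with a warning and logged.
#'
#' @param cohort `phs_cohort`-style data frame containing survival columns,
#'   the base covariates, and one dosage column per candidate.
#' @param candidates character vector of candidate dosage columns.
#' @param base_covariates character vector of adjustment covariates.
#' @param tol absolute criterion-improvement threshold for halting. A null
#'   candidate's best-of-pool improvement of the residual sum is O(1)
#'   (chi-square-like) regardless of cohort size, so an absolute threshold
#'   is size-stable where a relative one is not; the default 3.0 sits
#'   above the measured null scale (~1-2.5) and below the improvement of
#'   moderately associated SNPs (log HR >= ~0.2) at cohort sizes in the
#'   thousands.
#' @param ties ties method passed to [fit_cox()].
#' @param max_steps optional cap on accepted steps.
#' @return list with `selected` (ids in acceptance order) and `trace`
#'   (data frame: step, candidate, criterion before/after, accepted,
#'   reason), the criterion strictly decreasing along accepted steps.
#' @export
stepwise_select <- function(cohort, candidates, base_covariates,
                            tol = 3, ties = "efron", max_steps = Inf) {
  cohort <- as.data.frame(cohort)
  missing_base <- setdiff(base_covariates, names(cohort))
  if (length(missing_base)) {
    stop("base covariates missing from cohort: ",
         paste(missing_base, collapse = ", "))
  }
  candidates <- intersect(candidates, names(cohort))
  crit <- residual_criterion(cohort, base_covariates, ties)
  trace <- data.frame(step = integer(0), candidate = character(0),
                      criterion_before = numeric(0),
                      criterion_after = numeric(0),
                      accepted = logical(0), reason = character(0))
  selected <- character(0)
  pool <- candidates
  step <- 0L
  if (!length(pool)) {
    trace <- rbind(trace, data.frame(step = 0L, candidate = NA_character_,
                                     criterion_before = crit,
                                     criterion_after = crit,
                                     accepted = FALSE,
                                     reason = "empty candidate pool"))
    return(list(selected = selected, trace = trace))
  }
  repeat {
    step <- step + 1L
    if (step > max_steps || !length(pool)) break
    crit_cand <- rep(NA_real_, length(pool))
    for (j in seq_along(pool)) {
      crit_cand[j] <- tryCatch(
        residual_criterion(cohort, c(base_covariates, selected, pool[j]), ties),
        error = function(e) {
          warning("candidate ", pool[j], " skipped: ", conditionMessage(e))
          NA_real_
        })
    }
    if (all(is.na(crit_cand))) {
      trace <- rbind(trace, data.frame(step = step, candidate = NA_character_,
                                       criterion_before = crit,
                                       criterion_after = crit,
                                       accepted = FALSE,
                                       reason = "no candidate fit converged"))
      break
    }
    best <- which.min(crit_cand)
    gain <- crit - crit_cand[best]
    accepted <- is.finite(gain) && gain > tol
    trace <- rbind(trace, data.frame(
      step = step, candidate = pool[best],
      criterion_before = crit, criterion_after = crit_cand[best],
      accepted = accepted,
      reason = if (accepted) "accepted" else "improvement below tolerance"))
    if (!accepted) break
    selected <- c(selected, pool[best])
    crit <- crit_cand[best]
    pool <- pool[-best]
  }
  list(selected = selected, trace = trace)
}

#' Bootstrap model averaging of the selected hazard ratios
#'
#' Refits the fixed selected joint model on `B` nonparametric bootstrap
#' resamples of individuals; the reported log hazard ratio per term is the
#' bootstrap mean over converged resamples, its standard error the
#' bootstrap standard deviation. Conditional p-values come from the
#' full-data joint fit's Wald tests.
#'
#' @param cohort cohort data frame (survival columns + covariates).
#' @param selected selected SNP dosage columns.
#' @param base_covariates adjustment covariates (APOE dosage terms among
#'   them, e.g. `apoe_e2`/`apoe_e4`, are reported as score components).
#' @param B number of bootstrap resamples (>= 1; 1,000 by default).
#' @param seed integer seed.
#' @param ties ties method.
#' @param resample set `FALSE` for the resample-free debug mode in which
#'   each "resample" is the identity (betas equal the full-data fit).
#' @return `phs_beta_table` data frame: `id`, `beta`, `se`, `p`, `mlog10p`,
#'   with attribute `full_fit`.
#' @export
bootstrap_betas <- function(cohort, selected, base_covariates,
                            B = 1000, seed = 1L, ties = "efron",
                            resample = TRUE) {
  if (B < 1) stop("B must be >= 1")
  cohort <- as.data.frame(cohort)
  covs <- c(base_covariates, selected)
  full <- fit_cox(cohort, covs, ties = ties)
  if (!full$converged) stop("selected model does not converge on the full cohort")
  score_terms <- c(intersect(c("apoe_e2", "apoe_e4"), base_covariates), selected)
  n <- nrow(cohort)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = B, ncol = length(score_terms),
                  dimnames = list(NULL, score_terms))
  for (b in seq_len(B)) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    fit_b <- tryCatch(fit_cox(cohort[idx, , drop = FALSE], covs, ties = ties,
                              baseline = FALSE),
                      error = function(e) NULL)
    if (!is.null(fit_b) && fit_b$converged) {
      draws[b, ] <- fit_b$beta[score_terms]
    }
  }
  ok <- stats::complete.cases(draws)
  if (mean(ok) < 0.5) {
    stop("fewer than 50% of bootstrap resamples converged (",
         sum(ok), "/", B, ")")
  }
  out <- data.frame(
    id = score_terms,
    beta = colMeans(draws[ok, , drop = FALSE]),
    se = apply(draws[ok, , drop = FALSE], 2, stats::sd),
    p = full$wald_p[score_terms],
    mlog10p = full$mlog10p[score_terms],
    row.names = NULL)
  if (!resample || B == 1) out$se <- full$se[score_terms]
  attr(out, "full_fit") <- full
  attr(out, "n_converged") <- sum(ok)
  class(out) <- c("phs_beta_table", "data.frame")
  out
}

resolve_apoe_betas <- function(betas, apoe_betas = NULL) {
  if (!is.null(apoe_betas)) {
    return(c(e2 = unname(apoe_betas[["e2"]]), e4 = unname(apoe_betas[["e4"]])))
  }
  b2 <- betas$beta[match("APOE_e2", betas$id)]
  b4 <- betas$beta[match("APOE_e4", betas$id)]
  c(e2 = ifelse(is.na(b2), 0, b2), e4 = ifelse(is.na(b4), 0, b4))
}

snp_rows <- function(betas) betas[!betas$id %in% c("APOE_e2", "APOE_e4"), ,
                                  drop = FALSE]

#' Compute polygenic hazard scores
#'
#' \eqn{s_i = \sum_j \beta_j g_{ij}} over every weight-table row, including
#' the APOE dosage terms. Missing dosages are mean-imputed as \eqn{2 f_j}
#' from the supplied frequencies; effect-allele mismatches are resolved by
#' flipping the dosage (\eqn{g \to 2 - g}) when the complementary allele
#' matches, and raise an error naming the variant otherwise.
#'
#' @param betas `phs_beta_table`-style data frame (`id`, `beta`, optionally
#'   `effect_allele`); rows `APOE_e2`/`APOE_e4` are applied to the APOE
#'   dosages.
#' @param genotypes a `phs_genotypes` object, or a matrix/data frame of
#'   effect-allele dosages with one column per variant.
#' @param apoe_e2,apoe_e4 APOE allele dosage vectors (taken from a
#'   `phs_genotypes` object when omitted; default 0).
#' @param freqs named effect-allele frequencies for imputing missing
#'   dosages.
#' @param center optional `phs_dist`; when given, scores are centered on
#'   the distribution's raw population mean so they live on the same scale
#'   as the (zero-mean) reference distribution.
#' @return named numeric vector of scores.
#' @export
compute_phs <- function(betas, genotypes, apoe_e2 = NULL, apoe_e4 = NULL,
                        freqs = NULL, center = NULL) {
  meta <- NULL
  if (inherits(genotypes, "phs_genotypes")) {
    if (is.null(apoe_e2)) apoe_e2 <- genotypes$apoe_e2
    if (is.null(apoe_e4)) apoe_e4 <- genotypes$apoe_e4
    meta <- genotypes$variants
    G <- genotypes$dosage
  } else {
    G <- as.matrix(genotypes)
  }
  snps <- snp_rows(betas)
  n <- nrow(G)
  if (is.null(apoe_e2)) apoe_e2 <- rep(0, n)
  if (is.null(apoe_e4)) apoe_e4 <- rep(0, n)
  s <- rep(0, n)
  for (k in seq_len(nrow(snps))) {
    id <- snps$id[k]
    if (!id %in% colnames(G)) {
      if (!is.null(freqs) && id %in% names(freqs)) {
        s <- s + snps$beta[k] * 2 * freqs[[id]]
        next
      }
      stop("variant ", id, " absent from genotypes and no frequency supplied")
    }
    g <- G[, id]
    if (!is.null(meta) && "effect_allele" %in% names(snps)) {
      mrow <- meta[match(id, meta$id), ]
      ea <- snps$effect_allele[k]
      if (!is.na(ea) && nzchar(ea) && ea != ".") {
        if (identical(ea, mrow$effect_allele)) {
          # aligned
        } else if (identical(ea, mrow$other_allele)) {
          g <- 2 - g
        } else {
          stop("unresolvable allele mismatch for variant ", id)
        }
      }
    }
    if (anyNA(g)) {
      if (is.null(freqs) || !id %in% names(freqs)) {
        stop("missing dosages for ", id, " and no frequency for imputation")
      }
      g[is.na(g)] <- 2 * freqs[[id]]
    }
    s <- s + snps$beta[k] * g
  }
  ab <- resolve_apoe_betas(betas)
  s <- s + ab[["e2"]] * apoe_e2 + ab[["e4"]] * apoe_e4
  if (!is.null(rownames(G))) names(s) <- rownames(G)
  if (!is.null(center)) {
    stopifnot(inherits(center, "phs_dist"))
    s <- s - center$mean_raw
  }
  s
}

apoe_genotype_table <- function(apoe_freqs, apoe_betas) {
  f <- apoe_freqs
  g <- expand.grid(a1 = c("e2", "e3", "e4"), a2 = c("e2", "e3", "e4"),
                   stringsAsFactors = FALSE)
  p <- f[g$a1] * f[g$a2]
  d2 <- (g$a1 == "e2") + (g$a2 == "e2")
  d4 <- (g$a1 == "e4") + (g$a2 == "e4")
  contrib <- apoe_betas[["e2"]] * d2 + apoe_betas[["e4"]] * d4
  data.frame(p = as.vector(p), contrib = contrib, e4 = d4 > 0)
}

#' Reference distribution of the polygenic hazard score
#'
#' Builds the population distribution f(s) of the score under
#' Hardy-Weinberg and linkage equilibrium: SNP dosages Binomial(2, f_j),
#' APOE genotypes multinomial over ordered allele pairs. The distribution
#' is centered so its population mean is zero; the raw mean is retained for
#' putting individual scores on the same scale. An exact enumeration is
#' available for up to 12 SNPs; Monte Carlo otherwise.
#'
#' @param betas weight table (`id`, `beta`); `APOE_e2`/`APOE_e4` rows (or
#'   `apoe_betas`) supply the APOE terms.
#' @param freqs named effect-allele frequencies for the SNP rows.
#' @param apoe_freqs allele frequencies `c(e2, e3, e4)` summing to 1.
#' @param apoe_betas optional override `c(e2, e4)` of the APOE weights.
#' @param method `"monte_carlo"` or `"exact"`.
#' @param n_mc Monte Carlo sample size.
#' @param seed integer seed for the Monte Carlo method.
#' @return object of class `phs_dist`: sorted support `s`, weights `w`,
#'   cumulative weights `cumw`, per-point APOE e4-carrier flag `e4`,
#'   `mean_raw`, and `method`.
#' @export
reference_distribution <- function(betas, freqs,
                                   apoe_freqs = c(e2 = 0.08, e3 = 0.78,
                                                  e4 = 0.14),
                                   apoe_betas = NULL,
                                   method = c("monte_carlo", "exact"),
                                   n_mc = 1e6, seed = 1L) {
  method <- match.arg(method)
  if (abs(sum(apoe_freqs) - 1) > 1e-8 || any(apoe_freqs < 0)) {
    stop("APOE allele frequencies must be nonnegative and sum to 1")
  }
  snps <- snp_rows(betas)
  fj <- freqs[snps$id]
  if (anyNA(fj) && nrow(snps)) stop("missing frequency for: ",
                                    paste(snps$id[is.na(fj)], collapse = ", "))
  fj <- as.numeric(fj)
  if (any(fj < 0 | fj > 1)) stop("frequencies must lie in [0, 1]")
  ab <- resolve_apoe_betas(betas, apoe_betas)
  apoe <- apoe_genotype_table(apoe_freqs, ab)
  if (method == "exact") {
    if (nrow(snps) > 12) {
      stop("exact enumeration limited to 12 SNPs; use method = 'monte_carlo'")
    }
    s <- 0; w <- 1
    for (k in seq_len(nrow(snps))) {
      pk <- c((1 - fj[k])^2, 2 * fj[k] * (1 - fj[k]), fj[k]^2)
      s <- as.vector(outer(s, snps$beta[k] * 0:2, `+`))
      w <- as.vector(outer(w, pk, `*`))
    }
    n_snp_support <- length(s)
    s <- as.vector(outer(s, apoe$contrib, `+`))
    w <- as.vector(outer(w, apoe$p, `*`))
    e4 <- rep(apoe$e4, each = n_snp_support)
    # collapse numerically identical (score, carrier-status) support points
    key <- paste(signif(s, 12), e4)
    if (anyDuplicated(key)) {
      grp <- match(key, key)
      w <- as.vector(rowsum(w, grp, reorder = FALSE))
      keep <- !duplicated(key)
      s <- s[keep]; e4 <- e4[keep]
    }
  } else {
    set.seed(seed)
    s <- rep(0, n_mc)
    for (k in seq_len(nrow(snps))) {
      s <- s + snps$beta[k] * stats::rbinom(n_mc, 2L, fj[k])
    }
    gidx <- sample.int(nrow(apoe), n_mc, replace = TRUE, prob = apoe$p)
    s <- s + apoe$contrib[gidx]
    e4 <- apoe$e4[gidx]
    w <- rep(1 / n_mc, n_mc)
  }
  mean_raw <- sum(w * s) / sum(w)
  s <- s - mean_raw
  o <- order(s)
  structure(list(s = s[o], w = w[o] / sum(w), cumw = cumsum(w[o]) / sum(w),
                 e4 = e4[o], mean_raw = mean_raw, method = method),
            class = "phs_dist")
}

#' Empirical score distribution from a cohort
#'
#' Builds a `phs_dist` from observed scores (equal weights), e.g. to use a
#' training cohort's empirical distribution instead of the allele-frequency
#' reference.
#'
#' @param s numeric scores.
#' @param e4 optional APOE e4 carrier flags.
#' @param center subtract the sample mean (default TRUE).
#' @return `phs_dist`.
#' @export
empirical_distribution <- function(s, e4 = NULL, center = TRUE) {
  mean_raw <- if (center) mean(s) else 0
  s <- s - mean_raw
  o <- order(s)
  if (is.null(e4)) e4 <- rep(NA, length(s))
  structure(list(s = s[o], w = rep(1 / length(s), length(s)),
                 cumw = seq_along(s) / length(s), e4 = e4[o],
                 mean_raw = mean_raw, method = "empirical"),
            class = "phs_dist")
}

#' @export
print.phs_dist <- function(x, ...) {
  cat("PHS reference distribution (", x$method, "), ",
      length(x$s), " support points\n", sep = "")
  cat("  sd:", format(sqrt(sum(x$w * x$s^2))),
      " e4-carrier mass:", format(sum(x$w[x$e4 %in% TRUE])), "\n")
  invisible(x)
}

#' Distribution function of the reference score
#'
#' @param dist a `phs_dist`.
#' @param s score value(s).
#' @return \eqn{P(S \le s)}.
#' @export
dist_cdf <- function(dist, s) {
  idx <- findInterval(s, dist$s)
  c(0, dist$cumw)[idx + 1]
}

#' Quantile of the reference score
#'
#' Left-continuous inverse of the CDF: smallest support value with
#' cumulative probability at least `p`.
#'
#' @param dist a `phs_dist`.
#' @param p probability in (0, 1).
#' @return score quantile(s).
#' @export
dist_quantile <- function(dist, p) {
  if (any(p <= 0 | p >= 1)) stop("quantile probabilities must be in (0, 1)")
  idx <- findInterval(p, dist$cumw, left.open = TRUE) + 1
  dist$s[pmin(idx, length(dist$s))]
}

#' Percentile of a score in the reference distribution
#'
#' \eqn{100 \cdot P(S < s) + 50 \cdot P(S = s)} (midpoint convention at
#' ties).
#'
#' @param s score value(s).
#' @param dist a `phs_dist`.
#' @return percentile(s) in (0, 100).
#' @export
percentile_of <- function(s, dist) {
  below <- c(0, dist$cumw)[findInterval(s, dist$s, left.open = TRUE) + 1]
  at_or_below <- c(0, dist$cumw)[findInterval(s, dist$s) + 1]
  100 * (below + (at_or_below - below) / 2)
}

#' Condition the reference distribution on APOE e4 carrier status
#'
#' @param dist a `phs_dist` with carrier flags.
#' @param carrier `TRUE` for e4 carriers, `FALSE` for non-carriers.
#' @return renormalized `phs_dist` on the same (centered) score scale.
#' @export
condition_apoe <- function(dist, carrier = TRUE) {
  keep <- dist$e4 %in% carrier
  if (!any(keep)) stop("no support points with the requested carrier status")
  w <- dist$w[keep] / sum(dist$w[keep])
  structure(list(s = dist$s[keep], w = w, cumw = cumsum(w),
                 e4 = dist$e4[keep], mean_raw = dist$mean_raw,
                 method = dist$method),
            class = "phs_dist")
}
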