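# Replication analyses for a frozen, externally trained PHS: percentile
# risk stratification with Kaplan-Meier curves, predicted-versus-empirical
# onset-age correlation, longitudinal progression trend, and the decile
# hazard ratio. None of these refit the score weights.

#' Percentile risk stratification with Kaplan-Meier curves
#'
#' Assigns each individual to a percentile bin of the reference
#' distribution via [percentile_of()], estimates a Kaplan-Meier curve per
#' bin, and runs a log-rank test between the extreme bins.
#'
#' @param cohort survival records (`entry_age`, `exit_age`, `event`).
#' @param scores per-individual scores on the distribution's scale.
#' @param dist the `phs_dist` reference distribution.
#' @param bin_edges percentile bin edges (default quartiles).
#' @return list of class `phs_strat_curves`: per-bin label, n, KM curve;
#'   and the extreme-bin `logrank` result (`NULL`, with a warning, when
#'   fewer than two bins are occupied).
#' @export
stratify_km <- function(cohort, scores, dist,
                        bin_edges = c(0, 25, 50, 75, 100)) {
  cohort <- as.data.frame(cohort)
  stopifnot(length(scores) == nrow(cohort))
  pct <- percentile_of(scores, dist)
  bins <- cut(pct, breaks = bin_edges, include.lowest = TRUE)
  curves <- list()
  for (lev in levels(bins)) {
    idx <- which(bins == lev)
    if (!length(idx)) {
      warning("empty percentile bin ", lev, " dropped")
      next
    }
    curves[[lev]] <- list(label = lev, n = length(idx),
                          n_events = sum(cohort$event[idx]),
                          km = kaplan_meier(cohort[idx, , drop = FALSE]))
  }
  occupied <- names(curves)
  logrank <- NULL
  if (length(occupied) >= 2) {
    lo <- which(bins == occupied[1])
    hi <- which(bins == occupied[length(occupied)])
    logrank <- logrank_test(cohort[lo, , drop = FALSE],
                            cohort[hi, , drop = FALSE])
  } else {
    warning("only one occupied stratum; log-rank test skipped")
  }
  structure(list(curves = curves, logrank = logrank, bin_edges = bin_edges),
            class = "phs_strat_curves")
}

#' Predicted versus empirical age of onset
#'
#' Bins cases by score percentile; the empirical value per bin is the mean
#' observed onset age, the predicted value is the model onset age (risk
#' level `q`, via [expected_onset_age()]) at the bin's median score.
#' Reports the Pearson correlation over bins with a two-sided p-value.
#' Bins with fewer than `min_cases` cases are merged with their neighbor.
#'
#' @param cases cohort rows with `event == 1` (onset age in `exit_age`).
#' @param scores case scores (calibration scale).
#' @param cal a `phs_calibration`.
#' @param n_bins number of percentile bins (>= 3).
#' @param q cumulative risk level defining the predicted onset age.
#' @param from_age conditioning age for the prediction.
#' @param min_cases minimum cases per bin before merging.
#' @return list of class `phs_onset_calibration`: per-bin table
#'   (`empirical`, `predicted`, `n`), `r`, `p`, `n_bins`.
#' @export
onset_correlation <- function(cases, scores, cal, n_bins = 20, q = 0.5,
                              from_age = 60, min_cases = 5) {
  cases <- as.data.frame(cases)
  if (n_bins < 3) stop("n_bins must be >= 3")
  if (any(cases$event != 1)) stop("`cases` must contain only event rows")
  stopifnot(length(scores) == nrow(cases))
  edges <- stats::quantile(scores, probs = seq(0, 1, length.out = n_bins + 1))
  edges <- unique(edges)
  bins <- cut(scores, breaks = edges, include.lowest = TRUE)
  tab <- data.frame(bin = levels(bins),
                    n = as.vector(table(bins)),
                    empirical = as.vector(tapply(cases$exit_age, bins, mean)),
                    median_score = as.vector(tapply(scores, bins, stats::median)))
  # merge undersized bins into their left neighbor
  merged <- 0L
  while (any(tab$n < min_cases) && nrow(tab) > 3) {
    i <- which(tab$n < min_cases)[1]
    j <- if (i == 1) 2L else i - 1L
    wsum <- tab$n[i] + tab$n[j]
    tab$empirical[j] <- (tab$empirical[j] * tab$n[j] +
                           tab$empirical[i] * tab$n[i]) / wsum
    tab$median_score[j] <- (tab$median_score[j] * tab$n[j] +
                              tab$median_score[i] * tab$n[i]) / wsum
    tab$n[j] <- wsum
    tab <- tab[-i, , drop = FALSE]
    merged <- merged + 1L
  }
  if (merged) message(merged, " undersized percentile bins merged")
  tab$predicted <- vapply(tab$median_score, function(sc)
    expected_onset_age(cal, sc, q = q, from_age = from_age), numeric(1))
  usable <- is.finite(tab$predicted)
  ct <- stats::cor.test(tab$empirical[usable], tab$predicted[usable])
  structure(list(bins = tab, r = unname(ct$estimate), p = ct$p.value,
                 n_bins = sum(usable), q = q),
            class = "phs_onset_calibration")
}

#' Progression-rate trend against predicted incidence
#'
#' For cognitively normal individuals followed at least `min_followup`
#' years, bins by the model-predicted annualized incidence at baseline age
#' and tests whether the empirical progression proportion trends with the
#' predicted incidence (Cochran-Armitage, bin scores = mean predicted
#' incidence per bin). Per-bin observed proportions carry Wilson 95%
#' confidence intervals.
#'
#' @param baseline_age baseline age per individual.
#' @param followup_years follow-up duration (all >= `min_followup`).
#' @param progressed 0/1 progression indicator.
#' @param scores individual scores (calibration scale).
#' @param cal a `phs_calibration`.
#' @param n_bins number of predicted-incidence bins.
#' @param min_followup minimum required follow-up (years).
#' @return list of class `phs_progression_trend`: `z`, `p`, per-bin table
#'   (`predicted` annualized incidence, `predicted_prob` model progression
#'   probability over the subjects' own follow-up, `observed`, `lower`,
#'   `upper`, `n`).
#' @export
progression_trend <- function(baseline_age, followup_years, progressed,
                              scores, cal, n_bins = 5, min_followup = 2) {
  n <- length(baseline_age)
  stopifnot(length(followup_years) == n, length(progressed) == n,
            length(scores) == n)
  if (any(followup_years < min_followup)) {
    stop("all records need at least ", min_followup, " years of follow-up")
  }
  if (n_bins < 2) stop("need at least 2 bins")
  pred <- annualized_incidence(cal, scores, baseline_age)
  edges <- unique(stats::quantile(pred, probs = seq(0, 1,
                                                    length.out = n_bins + 1)))
  if (length(edges) < 3) stop("predicted incidence too concentrated to bin")
  bins <- cut(pred, breaks = edges, include.lowest = TRUE)
  tot <- as.vector(table(bins))
  prog <- as.vector(tapply(progressed, bins, sum))
  keep <- tot > 0
  tot <- tot[keep]; prog <- prog[keep]
  bin_score <- as.vector(tapply(pred, bins, mean))[keep]
  if (length(tot) < 2) stop("fewer than 2 occupied bins")
  if (sum(prog) == 0 || sum(prog) == sum(tot)) {
    stop("degenerate table: all or none progressed")
  }
  trend <- cochran_armitage_trend(prog, tot, bin_score)
  ci <- t(vapply(seq_along(tot), function(i) {
    pt <- stats::prop.test(prog[i], tot[i], correct = FALSE)
    pt$conf.int
  }, numeric(2)))
  # model-implied progression probability over each subject's own follow-up
  pp <- 1 - exp(-exp(scores) *
                  (H0_at(cal, baseline_age + followup_years, extrapolate = TRUE) -
                     H0_at(cal, baseline_age)))
  pred_prob <- as.vector(tapply(pp, bins, mean))[keep]
  structure(list(z = trend$z, p = trend$p,
                 bins = data.frame(predicted = bin_score,
                                   predicted_prob = pred_prob,
                                   observed = prog / tot,
                                   lower = ci[, 1], upper = ci[, 2],
                                   progressed = prog, n = tot)),
            class = "phs_progression_trend")
}

#' Decile hazard ratio
#'
#' Restricts to the top and bottom score deciles and fits a Cox model with
#' the top-decile indicator (plus optional adjusters), reporting the hazard
#' ratio with its Wald 95% confidence interval and the log-rank test
#' between the deciles.
#'
#' @param cohort survival records.
#' @param scores per-individual scores.
#' @param adjust optional covariate columns to adjust for.
#' @return list of class `phs_decile_hr`: `hr`, `ci`, `logrank_p`, `fit`.
#' @export
decile_hr <- function(cohort, scores, adjust = NULL) {
  cohort <- as.data.frame(cohort)
  stopifnot(length(scores) == nrow(cohort))
  qs <- stats::quantile(scores, c(0.1, 0.9))
  lo <- scores <= qs[1]
  hi <- scores >= qs[2]
  sub <- cohort[lo | hi, , drop = FALSE]
  sub$top_decile <- as.integer(hi[lo | hi])
  if (stats::sd(sub$top_decile) == 0) {
    # indistinguishable deciles (e.g. constant scores): HR is 1 by definition
    return(structure(list(hr = 1, ci = c(1, 1), logrank_p = 1, fit = NULL),
                     class = "phs_decile_hr"))
  }
  if (sum(sub$event[sub$top_decile == 1]) == 0 ||
      sum(sub$event[sub$top_decile == 0]) == 0) {
    stop("a decile has no events")
  }
  fit <- fit_cox(sub, c("top_decile", adjust))
  b <- fit$beta[["top_decile"]]; se <- fit$se[["top_decile"]]
  lr <- logrank_test(sub[sub$top_decile == 0, , drop = FALSE],
                     sub[sub$top_decile == 1, , drop = FALSE])
  structure(list(hr = exp(b), ci = exp(b + c(-1, 1) * 1.96 * se),
                 logrank_p = lr$p, fit = fit),
            class = "phs_decile_hr")
}

#' @export
print.phs_decile_hr <- function(x, ...) {
  cat(sprintf("Decile hazard ratio: %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g\n",
              x$hr, x$ci[1], x$ci[2], x$logrank_p))
  invisible(x)
}
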