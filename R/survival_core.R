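# Survival engine: Cox partial-likelihood fitting on the age scale with
# optional left truncation, baseline cumulative hazard (Breslow/Efron),
# martingale residuals, Kaplan-Meier with Greenwood variance, log-rank and
# Cochran-Armitage trend tests, and a graphical proportional-hazards
# diagnostic.

#' Assemble survival records
#'
#' Validates and standardizes a data frame of survival records with age as
#' the time axis: one row per participant with entry age (study entry /
#' delayed entry), exit age (age of onset for events, age of last visit for
#' censored rows), an event indicator, and covariate columns.
#'
#' @param data data frame containing at least `exit_age` and `event`
#'   columns; `entry_age` is optional (defaults to 0, i.e. no truncation).
#' @return the validated data frame (invisibly classed `phs_records`).
#' @export
surv_records <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("exit_age", "event") %in% names(data))) {
    stop("records need `exit_age` and `event` columns")
  }
  if (!"entry_age" %in% names(data)) data$entry_age <- 0
  if (!all(data$event %in% c(0, 1))) stop("`event` must be 0/1")
  if (any(data$exit_age <= data$entry_age)) {
    stop("all records must have exit_age > entry_age")
  }
  class(data) <- unique(c("phs_records", class(data)))
  data
}

use_truncation <- function(data, truncation = NULL) {
  if (!is.null(truncation)) return(isTRUE(truncation))
  "entry_age" %in% names(data) && any(data$entry_age > 0)
}

cox_surv <- function(data, truncation) {
  if (truncation) {
    survival::Surv(data$entry_age, data$exit_age, data$event)
  } else {
    survival::Surv(data$exit_age, data$event)
  }
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood for the named covariates with age as
#' the time axis. Left truncation at `entry_age` is used by default whenever
#' entry ages are present and positive; otherwise subjects are at risk from
#' age 0. Ties are handled by the Efron correction by default.
#'
#' @param data survival records (see [surv_records()]): `entry_age`
#'   (optional), `exit_age`, `event`, and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param truncation logical; override the automatic left-truncation rule.
#' @param baseline compute the baseline cumulative hazard table (default
#'   TRUE; skipping it saves time in fit-only loops).
#' @return an object of class `phs_coxfit`: coefficients `beta`, standard
#'   errors `se`, Wald p-values `wald_p` (and `mlog10p`), partial
#'   log-likelihood `loglik`, baseline cumulative hazard step function
#'   `cumhaz` (at covariates = 0), event count `n_events`, and a
#'   `converged` flag. Non-convergence or monotone-likelihood problems are
#'   flagged, never silent.
#' @export
fit_cox <- function(data, covariates, ties = c("efron", "breslow"),
                    truncation = NULL, baseline = TRUE) {
  ties <- match.arg(ties)
  data <- surv_records(as.data.frame(data))
  if (sum(data$event) < 1) stop("cannot fit a Cox model with no events")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariates not found in records: ", paste(missing_cov, collapse = ", "))
  }
  trunc <- use_truncation(data, truncation)
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  y <- cox_surv(data, trunc)

  flagged <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(y ~ X, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- as.vector(stats::coef(fit))
  names(beta) <- covariates
  se <- sqrt(diag(fit$var))
  names(se) <- covariates
  converged <- !any(is.na(beta)) && !any(!is.finite(se)) &&
    !any(grepl("converge|infinite|out of iterations|beta may be infinite",
               flagged, ignore.case = TRUE))
  z <- beta / se
  wald_p <- 2 * stats::pnorm(-abs(z))
  cumhaz <- NULL
  if (baseline) {
    beta_safe <- ifelse(is.na(beta), 0, beta)
    eta <- drop(X %*% beta_safe)
    cumhaz <- baseline_hazard_table(data$entry_age, data$exit_age, data$event,
                                    eta, ties)
  }
  structure(list(
    beta = beta, se = se, loglik = fit$loglik[length(fit$loglik)],
    wald_p = wald_p, mlog10p = -log10(wald_p),
    cumhaz = cumhaz, n_events = sum(data$event),
    converged = converged, flags = flagged,
    covariates = covariates, ties = ties, truncation = trunc,
    model = fit
  ), class = "phs_coxfit")
}

#' @export
print.phs_coxfit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties, ",
      if (x$truncation) "left-truncated" else "no truncation", ")\n", sep = "")
  cat("  events:", x$n_events, " loglik:", format(x$loglik), "\n")
  print(data.frame(beta = x$beta, se = x$se, p = x$wald_p))
  if (!x$converged) cat("  WARNING: fit flagged as not converged\n")
  invisible(x)
}

# Risk-set weighted sums at each distinct event time, O(n log n).
# Risk set at t: entry < t <= exit. Returns per event time: d (deaths),
# risk_sum (sum of w over risk set), dead_sum (sum of w over deaths).
risk_set_sums <- function(entry, exit, event, w) {
  ut <- sort(unique(exit[event == 1]))
  tot <- sum(w)
  # sum of w with exit >= t: total - sum over exits strictly < t
  oe <- order(exit)
  cw_exit <- cumsum(w[oe])
  below_exit <- findInterval(ut, exit[oe], left.open = TRUE)
  A <- tot - c(0, cw_exit)[below_exit + 1]
  # minus sum of w with entry >= t (not yet entered: entry < t required)
  on <- order(entry)
  cw_entry <- cumsum(w[on])
  below_entry <- findInterval(ut, entry[on], left.open = TRUE)
  B <- tot - c(0, cw_entry)[below_entry + 1]
  risk_sum <- A - B
  d <- as.vector(tapply(event[event == 1], factor(exit[event == 1], levels = ut),
                        sum))
  dead_sum <- as.vector(tapply(w[event == 1], factor(exit[event == 1], levels = ut),
                               sum))
  data.frame(time = ut, d = d, risk_sum = risk_sum, dead_sum = dead_sum)
}

# Standard baseline hazard increments at event times (covariates = 0).
baseline_hazard_table <- function(entry, exit, event, eta, ties) {
  w <- exp(eta)
  if (!sum(event)) {
    return(data.frame(time = numeric(0), dhaz = numeric(0), cumhaz = numeric(0)))
  }
  rs <- risk_set_sums(entry, exit, event, w)
  dhaz <- if (ties == "breslow") {
    rs$d / rs$risk_sum
  } else {
    vapply(seq_len(nrow(rs)), function(k) {
      d <- rs$d[k]
      l <- seq_len(d) - 1
      sum(1 / (rs$risk_sum[k] - (l / d) * rs$dead_sum[k]))
    }, numeric(1))
  }
  data.frame(time = rs$time, d = rs$d, risk_sum = rs$risk_sum,
             dead_sum = rs$dead_sum, dhaz = dhaz, cumhaz = cumsum(dhaz))
}

#' Breslow/Efron baseline cumulative hazard
#'
#' Step function \eqn{H_0(t) = \sum_{t_k \le t} d_k / \sum_{R_k} e^{\beta x}}
#' (Breslow; the Efron variant adjusts tied risk sums), evaluated at the
#' fitted coefficients with covariates at zero.
#'
#' @param fit a [fit_cox()] result.
#' @param data the records to rebuild the risk sets from; defaults to the
#'   baseline table stored at fit time.
#' @return data frame with `time`, `dhaz` (increment), `cumhaz`.
#' @export
breslow_cumhaz <- function(fit, data = NULL) {
  if (is.null(data)) return(fit$cumhaz[, c("time", "dhaz", "cumhaz")])
  data <- surv_records(as.data.frame(data))
  X <- as.matrix(data[, fit$covariates, drop = FALSE])
  eta <- drop(X %*% ifelse(is.na(fit$beta), 0, fit$beta))
  entry <- if (fit$truncation) data$entry_age else rep(0, nrow(data))
  baseline_hazard_table(entry, data$exit_age, data$event, eta,
                        fit$ties)[, c("time", "dhaz", "cumhaz")]
}

step_cumhaz_at <- function(cumhaz_table, t) {
  if (!nrow(cumhaz_table)) return(rep(0, length(t)))
  idx <- findInterval(t, cumhaz_table$time)
  c(0, cumhaz_table$cumhaz)[idx + 1]
}

#' Martingale residuals
#'
#' \eqn{M_i = \delta_i - [H_0(exit_i) - H_0(entry_i)] e^{\beta x_i}}, the
#' event indicator minus the model-expected event count. Under Efron ties
#' the deceased at a tied time receive the reduced own-death increment, so
#' that the residuals sum to zero exactly at any coefficient value.
#'
#' @param data survival records with the fit's covariate columns.
#' @param fit a [fit_cox()] result.
#' @return numeric vector of residuals (each \eqn{\le 1}).
#' @export
martingale_residuals <- function(data, fit) {
  data <- surv_records(as.data.frame(data))
  X <- as.matrix(data[, fit$covariates, drop = FALSE])
  eta <- drop(X %*% ifelse(is.na(fit$beta), 0, fit$beta))
  w <- exp(eta)
  entry <- if (fit$truncation) data$entry_age else rep(0, nrow(data))
  bh <- baseline_hazard_table(entry, data$exit_age, data$event, eta, fit$ties)
  H_exit <- step_cumhaz_at(bh, data$exit_age)
  H_entry <- step_cumhaz_at(bh, entry)
  expected <- w * (H_exit - H_entry)
  if (fit$ties == "efron" && nrow(bh)) {
    tied <- bh[bh$d > 1, , drop = FALSE]
    if (nrow(tied)) {
      for (k in seq_len(nrow(tied))) {
        d <- tied$d[k]; R <- tied$risk_sum[k]; SD <- tied$dead_sum[k]
        l <- seq_len(d) - 1
        std_inc <- sum(1 / (R - (l / d) * SD))
        dead_inc <- sum((1 - l / d) / (R - (l / d) * SD))
        at <- which(data$event == 1 & data$exit_age == tied$time[k])
        expected[at] <- expected[at] + w[at] * (dead_inc - std_inc)
      }
    }
  }
  data$event - expected
}

#' Kaplan-Meier survivor curve
#'
#' Product-limit estimate with Greenwood variance and log-transformed 95%
#' confidence limits; supports left truncation when entry ages are present.
#'
#' @param data survival records.
#' @param truncation override the automatic left-truncation rule.
#' @return object of class `phs_stepsurv`: data frame `time`, `n_risk`,
#'   `n_event`, `surv`, `var`, `lower`, `upper`.
#' @export
kaplan_meier <- function(data, truncation = NULL) {
  data <- surv_records(as.data.frame(data))
  if (!nrow(data)) stop("no records")
  trunc <- use_truncation(data, truncation)
  sf <- survival::survfit(cox_surv(data, trunc) ~ 1, conf.type = "log")
  sm <- summary(sf, censored = TRUE)
  out <- data.frame(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                    surv = sm$surv, var = sm$std.err^2,
                    lower = sm$lower, upper = sm$upper)
  class(out) <- c("phs_stepsurv", "data.frame")
  out
}

stepsurv_at <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$time) + 1]
}

#' Log-rank test between two groups
#'
#' Standard one-degree-of-freedom log-rank statistic comparing two sets of
#' survival records, with a two-sided p-value.
#'
#' @param group_a,group_b survival records for the two groups.
#' @return list with `chisq`, `p`.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- as.data.frame(group_a); group_b <- as.data.frame(group_b)
  if (!nrow(group_a) || !nrow(group_b)) stop("both groups need at least one record")
  both <- surv_records(rbind(
    group_a[, intersect(names(group_a), c("entry_age", "exit_age", "event"))],
    group_b[, intersect(names(group_b), c("entry_age", "exit_age", "event"))]
  ))
  grp <- rep(c("a", "b"), c(nrow(group_a), nrow(group_b)))
  trunc <- use_truncation(both)
  if (trunc) {
    # with delayed entry the log-rank statistic is the Cox score test at 0
    fit <- survival::coxph(cox_surv(both, TRUE) ~ grp, ties = "breslow",
                           init = 0,
                           control = survival::coxph.control(iter.max = 0))
    chisq <- unname(fit$score)
  } else {
    sd <- survival::survdiff(cox_surv(both, FALSE) ~ grp)
    chisq <- unname(sd$chisq)
  }
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cochran-Armitage trend test
#'
#' Trend in proportions across ordered bins of a 2 x k table with
#' user-supplied bin scores. Two-sided p from the standard normal.
#'
#' @param progressed integer vector of event counts per bin.
#' @param totals integer vector of bin totals (> 0).
#' @param scores numeric bin scores.
#' @return list with `z`, `p`.
#' @export
cochran_armitage_trend <- function(progressed, totals, scores) {
  k <- length(totals)
  if (k < 2) stop("trend test needs at least 2 bins")
  if (length(progressed) != k || length(scores) != k) {
    stop("progressed, totals, scores must have equal length")
  }
  if (any(totals <= 0)) stop("all bin totals must be positive")
  if (any(progressed < 0 | progressed > totals)) stop("counts out of range")
  N <- sum(totals); R <- sum(progressed)
  pbar <- R / N
  if (pbar <= 0 || pbar >= 1) stop("degenerate table: all or no events")
  T_stat <- sum(scores * progressed) - pbar * sum(scores * totals)
  V <- pbar * (1 - pbar) * (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  if (V <= 0) stop("zero trend variance (constant scores?)")
  z <- T_stat / sqrt(V)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Graphical proportional-hazards diagnostic
#'
#' For each stratum, compares the Cox-implied survivor curve evaluated at
#' the stratum's mean covariates against the stratum's Kaplan-Meier
#' estimate, reporting the maximum vertical discrepancy and the fraction of
#' event times where the model curve lies inside the KM 95% band.
#'
#' @param data survival records with the fit's covariates.
#' @param fit a [fit_cox()] result.
#' @param strata factor/vector assigning each record to a stratum.
#' @return list with per-stratum results and `max_gap`.
#' @export
ph_diagnostic <- function(data, fit, strata) {
  data <- surv_records(as.data.frame(data))
  strata <- as.factor(strata)
  stopifnot(length(strata) == nrow(data))
  out <- list()
  for (lev in levels(strata)) {
    sub <- data[strata == lev, , drop = FALSE]
    if (sum(sub$event) == 0) {
      warning("stratum '", lev, "' has no events; skipped")
      next
    }
    km <- kaplan_meier(sub)
    xbar <- colMeans(as.matrix(sub[, fit$covariates, drop = FALSE]))
    eta_bar <- sum(ifelse(is.na(fit$beta), 0, fit$beta) * xbar)
    ev <- km[km$n_event > 0, , drop = FALSE]
    H <- step_cumhaz_at(fit$cumhaz, ev$time)
    model_surv <- exp(-H * exp(eta_bar))
    gap <- max(abs(model_surv - ev$surv))
    inside <- mean(model_surv >= ev$lower & model_surv <= ev$upper, na.rm = TRUE)
    out[[lev]] <- list(label = lev, km = km,
                       model = data.frame(time = ev$time, surv = model_surv),
                       max_gap = gap, ci_coverage = inside)
  }
  if (!length(out)) stop("no stratum with events")
  list(strata = out, max_gap = max(vapply(out, `[[`, numeric(1), "max_gap")))
}
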