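# Absolute-risk calibration: convert the PHS plus published population
# incidence into individualized hazards. The individual-level baseline
# hazard h0*(t) is solved so that the score-mixture population reproduces
# the published incidence exactly on the age grid, correcting the improper
# baseline of case-control samples.

#' Baseline incidence table
#'
#' Published population annualized incidence: ages (knots) and rates per
#' 100 person-years.
#'
#' @param age strictly increasing knot ages (years).
#' @param rate_per_100py positive annualized rates.
#' @return data frame of class `phs_baseline`.
#' @export
baseline_incidence <- function(age, rate_per_100py) {
  if (any(diff(age) <= 0)) stop("knot ages must be strictly increasing")
  if (any(rate_per_100py <= 0)) stop("rates must be positive")
  structure(data.frame(age = age, rate_per_100py = rate_per_100py),
            class = c("phs_baseline", "data.frame"))
}

#' Interpolated population hazard function
#'
#' Converts the published rates from percent per year to one-year
#' probabilities and then to hazards via \eqn{h = -\ln(1 - q)}, assigns the
#' hazard to the knot age, and interpolates log-linearly between knots.
#' Below the first knot the hazard is held flat; beyond the last knot it is
#' log-linearly extrapolated when `extrapolate = TRUE` and errors
#' otherwise.
#'
#' @param baseline a [baseline_incidence()] table.
#' @param extrapolate allow evaluation beyond the last knot.
#' @return function `h(t)` returning the per-year hazard, with the knot
#'   table attached as attributes.
#' @export
interpolate_baseline <- function(baseline, extrapolate = FALSE) {
  stopifnot(inherits(baseline, "phs_baseline") || is.data.frame(baseline))
  age <- baseline$age
  h <- -log(1 - baseline$rate_per_100py / 100)
  logh <- log(h)
  slope_hi <- (logh[length(h)] - logh[length(h) - 1]) /
    (age[length(age)] - age[length(age) - 1])
  fn <- function(t) {
    if (any(t > age[length(age)]) && !extrapolate) {
      stop("age beyond last knot (", age[length(age)],
           "); set extrapolate = TRUE")
    }
    out <- numeric(length(t))
    lo <- t <= age[1]
    out[lo] <- h[1]
    hi <- t > age[length(age)]
    out[hi] <- exp(logh[length(h)] + slope_hi * (t[hi] - age[length(age)]))
    mid <- !lo & !hi
    out[mid] <- exp(stats::approx(age, logh, xout = t[mid])$y)
    out
  }
  attr(fn, "knots") <- data.frame(age = age, hazard = h)
  attr(fn, "extrapolate") <- extrapolate
  fn
}

# Exact integral of the log-linearly interpolated hazard over [a, b]
# (log-mean of the endpoint hazards times the width, per sub-interval).
integrate_loglinear <- function(h_fn, a, b) {
  ha <- h_fn(a); hb <- h_fn(b)
  ifelse(abs(hb - ha) < 1e-15 * pmax(ha, hb),
         ha * (b - a),
         (hb - ha) / log(hb / ha) * (b - a))
}

#' Calibrate the individual-level baseline hazard to population incidence
#'
#' Marching in ascending age over a grid of step `dt`, maintains the
#' survivor function \eqn{S(t\mid s)} at every support point of the score
#' distribution and solves, per grid cell, for the baseline hazard
#' \eqn{h_0^*} such that the population mixture's survival drop over the
#' cell equals that of the published incidence curve exactly. Under the
#' resulting model the population hazard among survivors reproduces the
#' published incidence on the grid; with a degenerate distribution at
#' \eqn{s = 0}, \eqn{h_0^*} equals the (discretized) population hazard to
#' machine precision.
#'
#' @param baseline a [baseline_incidence()] table (or an
#'   [interpolate_baseline()] function).
#' @param dist the `phs_dist` score distribution.
#' @param dt grid step in years (default 0.25).
#' @param age_max upper end of the grid (default 100).
#' @param extrapolate allow the population hazard beyond its last knot.
#' @return object of class `phs_calibration`: grid node `ages`, per-cell
#'   baseline hazard `h0`, node cumulative baseline hazard `H0`, per-cell
#'   discretized population hazard `hpop`, the distribution, and the
#'   maximum reconstruction residual `max_residual`.
#' @export
calibrate_baseline <- function(baseline, dist, dt = 0.25, age_max = 100,
                               extrapolate = TRUE) {
  stopifnot(inherits(dist, "phs_dist"))
  h_fn <- if (is.function(baseline)) baseline else
    interpolate_baseline(baseline, extrapolate = extrapolate)
  knots <- attr(h_fn, "knots")
  a0 <- min(knots$age) - 5
  nodes <- seq(a0, age_max, by = dt)
  ncell <- length(nodes) - 1
  es <- exp(dist$s)
  if (!all(is.finite(es))) stop("score distribution has non-finite exp(s)")
  w <- dist$w
  S <- rep(1, length(es))
  h0 <- numeric(ncell)
  hpop <- numeric(ncell)
  resid <- numeric(ncell)
  for (k in seq_len(ncell)) {
    Hcell <- integrate_loglinear(h_fn, nodes[k], nodes[k + 1])
    hpop[k] <- Hcell / dt
    target <- -Hcell                      # log of the population drop
    wS <- w * S
    tot <- sum(wS)
    if (tot <= 0 || !is.finite(tot)) stop("score distribution fully depleted")
    mean_es <- sum(wS * es) / tot
    x <- Hcell / (dt * mean_es)           # Newton start
    for (it in 1:50) {
      decay <- exp(-x * es * dt)
      num <- sum(wS * decay)
      phi <- log(num / tot) - target
      dphi <- -dt * sum(wS * es * decay) / num
      step <- phi / dphi
      x <- x - step
      if (abs(phi) < 1e-14 && abs(step) < 1e-12 * max(x, 1e-30)) break
    }
    h0[k] <- x
    decay <- exp(-x * es * dt)
    resid[k] <- abs(sum(wS * decay) / tot - exp(target))
    S <- S * decay
  }
  structure(list(ages = nodes, h0 = h0, H0 = c(0, cumsum(h0 * dt)),
                 hpop = hpop, dt = dt, dist = dist,
                 max_residual = max(resid), knots = knots),
            class = "phs_calibration")
}

#' Construct a calibration object from a known baseline hazard
#'
#' Mainly for analytic checks: builds a `phs_calibration` directly from a
#' per-year baseline hazard (constant or a function of age) without
#' solving against a population table.
#'
#' @param h0 scalar hazard or function of age.
#' @param ages grid nodes.
#' @param dist optional `phs_dist` (default: point mass at 0).
#' @return `phs_calibration`.
#' @export
calibration_from_hazard <- function(h0, ages = seq(55, 100, by = 0.25),
                                    dist = NULL) {
  mid <- (ages[-1] + ages[-length(ages)]) / 2
  hz <- if (is.function(h0)) h0(mid) else rep(h0, length(mid))
  if (is.null(dist)) {
    dist <- structure(list(s = 0, w = 1, cumw = 1, e4 = NA, mean_raw = 0,
                           method = "degenerate"), class = "phs_dist")
  }
  dt <- diff(ages)
  structure(list(ages = ages, h0 = hz, H0 = c(0, cumsum(hz * dt)),
                 hpop = hz, dt = dt[1], dist = dist,
                 max_residual = 0, knots = NULL),
            class = "phs_calibration")
}

#' @export
print.phs_calibration <- function(x, ...) {
  cat("Calibrated baseline hazard: grid", min(x$ages), "-", max(x$ages),
      "y (dt =", x$dt, ")\n")
  cat("  reconstruction residual:", format(x$max_residual), "\n")
  invisible(x)
}

# Cumulative baseline hazard at arbitrary ages (piecewise-linear in t).
H0_at <- function(cal, t, extrapolate = FALSE) {
  rng <- range(cal$ages)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9)) {
    if (!extrapolate) stop("age outside the calibrated grid [",
                           rng[1], ", ", rng[2], "]")
    t <- pmin(pmax(t, rng[1]), rng[2])
  }
  stats::approx(cal$ages, cal$H0, xout = pmin(pmax(t, rng[1]), rng[2]))$y
}

#' Annualized incidence rate for a score
#'
#' One-year conditional onset probability, in percent:
#' \eqn{100 (1 - \exp(-\int_a^{a+1} h_0^*(u) e^{s} du))}.
#'
#' @param cal a `phs_calibration`.
#' @param s score value(s) on the distribution's centered scale.
#' @param age age(s); `age + 1` must lie inside the grid.
#' @return rate(s) per 100 person-years; vectorized over `s` or `age`.
#' @export
annualized_incidence <- function(cal, s, age) {
  dH <- H0_at(cal, age + 1) - H0_at(cal, age)
  100 * (1 - exp(-outer_or_vec(dH, exp(s))))
}

outer_or_vec <- function(a, b) {
  if (length(a) == 1 || length(b) == 1) a * b else {
    stopifnot(length(a) == length(b)); a * b
  }
}

#' Survivor curve for a score
#'
#' \eqn{S(t \mid s, \text{alive at } t_0) = \exp(-(H_0(t) - H_0(t_0))
#' e^{s})} on the calibration grid.
#'
#' @param cal a `phs_calibration`.
#' @param s score value.
#' @param from_age conditioning age (must lie on the grid range).
#' @return data frame `age`, `surv` from `from_age` to the grid end.
#' @export
survival_curve <- function(cal, s, from_age) {
  rng <- range(cal$ages)
  if (from_age < rng[1] || from_age >= rng[2]) {
    stop("from_age outside the calibrated grid")
  }
  ages <- c(from_age, cal$ages[cal$ages > from_age])
  H <- H0_at(cal, ages) - H0_at(cal, from_age)
  data.frame(age = ages, surv = exp(-H * exp(s)))
}

#' Expected age of onset at a cumulative risk level
#'
#' Smallest age at which the conditional cumulative risk
#' \eqn{1 - S(t \mid s, t_0)} reaches `q`, linearly interpolated between
#' grid nodes; `Inf` if the level is never reached on the grid.
#'
#' @param cal a `phs_calibration`.
#' @param s score value.
#' @param q cumulative risk level in (0, 1).
#' @param from_age conditioning age.
#' @return age in years (or `Inf`).
#' @export
expected_onset_age <- function(cal, s, q = 0.5, from_age = 60) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  sc <- survival_curve(cal, s, from_age)
  F <- 1 - sc$surv
  idx <- which(F >= q)
  if (!length(idx)) return(Inf)
  i <- idx[1]
  if (i == 1) return(sc$age[1])
  a1 <- sc$age[i - 1]; a2 <- sc$age[i]
  F1 <- F[i - 1]; F2 <- F[i]
  a1 + (q - F1) / (F2 - F1) * (a2 - a1)
}

#' Sample onset ages from a calibrated model
#'
#' Inverse-CDF draws from the hazard \eqn{h_0^*(t) e^{s}} for individuals
#' alive at `from_age`; ages beyond the grid end are returned as `Inf`
#' (no onset within the modelled range).
#'
#' @param cal a `phs_calibration`.
#' @param s vector of scores (one draw per element).
#' @param from_age conditioning age (default: grid start).
#' @param seed optional integer seed.
#' @return numeric vector of onset ages.
#' @export
sample_onset_ages <- function(cal, s, from_age = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(from_age)) from_age <- cal$ages[1]
  offset <- H0_at(cal, from_age)
  target <- offset + stats::rexp(length(s)) / exp(s)
  out <- stats::approx(cal$H0, cal$ages, xout = target, rule = 1)$y
  out[is.na(out)] <- Inf
  out
}

survivor_weights <- function(cal, dist, age) {
  dist$w * exp(-H0_at(cal, age) * exp(dist$s))
}

weighted_quantile <- function(s, w, p) {
  o <- order(s)
  cw <- cumsum(w[o]) / sum(w)
  s[o][findInterval(p, cw, left.open = TRUE) + 1]
}

#' Incidence table by PHS percentile and APOE stratum
#'
#' Builds the percentile-by-age grid of annualized incidence rates.
#' Percentile cells evaluate the rate at the quantile score of the
#' reference distribution (`mode = "quantile"`), or at the quantile of the
#' survivor-reweighted distribution at each age
#' (`mode = "survivor_quantile"`), under which the extreme-percentile
#' contrast shrinks with age as high-score individuals are depleted. APOE
#' columns are survivor-weighted mean rates within the carrier /
#' non-carrier conditioned distributions. A `baseline` column gives the
#' survivor-weighted population mean rate. Cells are capped at `cap`.
#'
#' @param cal a `phs_calibration` (carrying its `phs_dist`).
#' @param percentiles percentile columns, each in (0, 100).
#' @param ages row ages.
#' @param apoe_strata include e4 carrier / non-carrier columns (requires
#'   carrier flags in the distribution).
#' @param mode `"quantile"` or `"survivor_quantile"`.
#' @param cap cell cap per 100 person-years (default 100).
#' @param uncertainty optional list `(betas, freqs, apoe_freqs, B, seed)`:
#'   resamples the weight table from its bootstrap standard errors,
#'   rebuilds the distribution and calibration, and appends 95% interval
#'   columns for the percentile cells.
#' @return data frame of class `phs_incidence_table` (rows = ages).
#' @export
incidence_table <- function(cal, percentiles = c(1, 20, 80, 99),
                            ages = seq(60, 95, by = 5),
                            apoe_strata = FALSE,
                            mode = c("quantile", "survivor_quantile"),
                            cap = 100, uncertainty = NULL) {
  mode <- match.arg(mode)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie in (0, 100)")
  }
  dist <- cal$dist
  out <- data.frame(age = ages)
  # survivor-weighted population mean rate
  pop <- vapply(ages, function(a) {
    w <- survivor_weights(cal, dist, a)
    q <- annualized_incidence(cal, dist$s, a)
    sum(w * q) / sum(w)
  }, numeric(1))
  out$baseline <- pmin(cap, pop)
  for (p in percentiles) {
    cell <- vapply(ages, function(a) {
      sp <- if (mode == "quantile") dist_quantile(dist, p / 100) else
        weighted_quantile(dist$s, survivor_weights(cal, dist, a), p / 100)
      annualized_incidence(cal, sp, a)
    }, numeric(1))
    out[[sprintf("phs_p%02d", p)]] <- pmin(cap, cell)
  }
  if (apoe_strata) {
    if (all(is.na(dist$e4))) stop("distribution carries no APOE carrier flags")
    for (carrier in c(TRUE, FALSE)) {
      cond <- condition_apoe(dist, carrier)
      cell <- vapply(ages, function(a) {
        w <- cond$w * exp(-H0_at(cal, a) * exp(cond$s))
        q <- annualized_incidence(cal, cond$s, a)
        sum(w * q) / sum(w)
      }, numeric(1))
      out[[if (carrier) "apoe_e4_carrier" else "apoe_e4_noncarrier"]] <-
        pmin(cap, cell)
    }
  }
  if (!is.null(uncertainty)) {
    out <- add_incidence_intervals(out, cal, percentiles, ages, mode, cap,
                                   uncertainty)
  }
  structure(out, class = c("phs_incidence_table", "data.frame"), mode = mode)
}

add_incidence_intervals <- function(out, cal, percentiles, ages, mode, cap,
                                    unc) {
  B <- if (is.null(unc$B)) 50 else unc$B
  if (!is.null(unc$seed)) set.seed(unc$seed)
  betas <- unc$betas
  if (!"se" %in% names(betas)) stop("uncertainty needs a weight table with `se`")
  draws <- array(NA_real_, dim = c(B, length(ages), length(percentiles)))
  for (b in seq_len(B)) {
    bb <- betas
    bb$beta <- stats::rnorm(nrow(bb), betas$beta, betas$se)
    db <- reference_distribution(bb, unc$freqs, apoe_freqs = unc$apoe_freqs,
                                 method = "monte_carlo",
                                 n_mc = if (is.null(unc$n_mc)) 2e4 else unc$n_mc,
                                 seed = sample.int(.Machine$integer.max / 2, 1))
    calb <- calibrate_baseline(baseline_incidence(cal$knots$age,
                                                  100 * (1 - exp(-cal$knots$hazard))),
                               db, dt = cal$dt, age_max = max(cal$ages))
    for (j in seq_along(percentiles)) {
      p <- percentiles[j]
      draws[b, , j] <- vapply(ages, function(a) {
        sp <- if (mode == "quantile") dist_quantile(db, p / 100) else
          weighted_quantile(db$s, survivor_weights(calb, db, a), p / 100)
        min(cap, annualized_incidence(calb, sp, a))
      }, numeric(1))
    }
  }
  for (j in seq_along(percentiles)) {
    ci <- apply(draws[, , j, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975))
    out[[sprintf("phs_p%02d_lo", percentiles[j])]] <- ci[1, ]
    out[[sprintf("phs_p%02d_hi", percentiles[j])]] <- ci[2, ]
  }
  out
}
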