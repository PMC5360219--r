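# Cox engine, baseline hazard, residuals, KM, log-rank, trend test,
# proportional-hazards diagnostics.

test_that("fit_cox matches the brute-force partial-likelihood grid search", {
  d <- toy_records()
  grid <- seq(-5, 5, by = 1e-4)
  oracle <- grid[which.max(toy_partial_loglik(grid))]
  fit <- fit_cox(d, "x", ties = "breslow")
  expect_lt(abs(fit$beta[["x"]] - oracle), 1e-4)
  # 2-covariate agreement with a 2-d grid oracle
  set.seed(4)
  n <- 60
  d2 <- data.frame(exit_age = sort(runif(n, 1, 10)),
                   event = rbinom(n, 1, 0.7),
                   x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  pl2 <- function(b1, b2) {
    eta <- b1 * d2$x1 + b2 * d2$x2
    w <- exp(eta)
    sum(vapply(which(d2$event == 1), function(i) {
      eta[i] - log(sum(w[d2$exit_age >= d2$exit_age[i]]))
    }, numeric(1)))
  }
  fit2 <- fit_cox(d2, c("x1", "x2"), ties = "breslow")
  g <- as.matrix(expand.grid(b1 = seq(fit2$beta[1] - 0.01, fit2$beta[1] + 0.01,
                                      by = 1e-4),
                             b2 = seq(fit2$beta[2] - 0.01, fit2$beta[2] + 0.01,
                                      by = 1e-4)))
  ll <- mapply(pl2, g[, 1], g[, 2])
  best <- g[which.max(ll), ]
  expect_lt(abs(fit2$beta[["x1"]] - best[["b1"]]), 1.1e-4)
  expect_lt(abs(fit2$beta[["x2"]] - best[["b2"]]), 1.1e-4)
})

test_that("partial likelihood is invariant to monotone time transforms", {
  d <- toy_records()
  fit1 <- fit_cox(d, "x")
  d3 <- d; d3$exit_age <- d$exit_age^3
  fit3 <- fit_cox(d3, "x")
  expect_equal(fit1$beta, fit3$beta, tolerance = 1e-8)
})

test_that("fit_cox recovers a simulated log hazard ratio", {
  co <- single_snp_cohort(n = 2000, beta = 0.5, seed = 11)
  fit <- fit_cox(co, "snp1")
  expect_true(abs(fit$beta[["snp1"]] - 0.5) < 3 * fit$se[["snp1"]])
  expect_true(fit$converged)
})

test_that("fit_cox refuses event-free data and flags degenerate fits", {
  d <- toy_records(); d$event <- 0
  expect_error(fit_cox(d, "x"), "no events")
  # perfect separation: x orders the events monotonically
  sep <- data.frame(exit_age = 1:6, event = c(1, 1, 1, 0, 0, 0),
                    x = c(5, 4, 3, 0.2, 0.1, 0))
  fit <- fit_cox(sep, "x")
  expect_false(fit$converged)
})

test_that("baseline cumulative hazard reduces to Nelson-Aalen and matches hand sums", {
  # all beta = 0: H0 jumps 1/n, 1/(n-1), ...
  d <- data.frame(exit_age = 1:4, event = 1, z = 0)
  fit <- fit_cox(d, "z")
  expect_equal(fit$cumhaz$dhaz, 1 / (4:1), tolerance = 1e-12)
  # single subject, event at t = 5, x = 0: jump 1
  d1 <- data.frame(exit_age = 5, event = 1, z = 0)
  bh <- polyhaz:::baseline_hazard_table(0, 5, 1, 0, "breslow")
  expect_equal(bh$dhaz, 1)
  # toy example: hand-computed risk-set sums at the fitted beta
  toy <- toy_records()
  fitx <- fit_cox(toy, "x", ties = "breslow")
  b <- fitx$beta[["x"]]
  w <- exp(b * toy$x)
  hand <- c(1 / sum(w), 1 / sum(w[2:4]), 1 / sum(w[3:4]))
  expect_equal(fitx$cumhaz$dhaz, hand, tolerance = 1e-10)
})

test_that("martingale residuals match the defining formula and sum to zero", {
  toy <- toy_records()
  fit <- fit_cox(toy, "x", ties = "breslow")
  m <- martingale_residuals(toy, fit)
  H <- stats::stepfun(fit$cumhaz$time, c(0, fit$cumhaz$cumhaz))
  hand <- toy$event - H(toy$exit_age) * exp(fit$beta[["x"]] * toy$x)
  expect_equal(m, hand, tolerance = 1e-10)
  expect_lt(abs(sum(m)), 1e-6)
  expect_true(all(m <= 1))
  # censored before the first event time has residual exactly 0
  d <- rbind(toy, data.frame(exit_age = 0.5, event = 0, x = 1))
  fit2 <- fit_cox(d, "x")
  expect_equal(martingale_residuals(d, fit2)[5], 0)
})

test_that("martingale residuals agree with the survival package, ties included", {
  set.seed(21)
  d <- data.frame(exit_age = sample(1:6, 40, replace = TRUE),
                  event = rbinom(40, 1, 0.6), x = rnorm(40))
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(d, "x", ties = ties)
    ref <- survival::coxph(survival::Surv(exit_age, event) ~ x, data = d,
                           ties = ties)
    expect_equal(martingale_residuals(d, fit),
                 unname(residuals(ref, type = "martingale")),
                 tolerance = 1e-6)
    expect_lt(abs(sum(martingale_residuals(d, fit))), 1e-6)
  }
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kaplan_meier(data.frame(exit_age = c(1, 2, 3),
                                event = c(1, 0, 1)))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  # no events: S constant 1
  km0 <- kaplan_meier(data.frame(exit_age = c(1, 2), event = c(0, 0)))
  expect_true(all(km0$surv == 1))
  # all events, distinct times
  km4 <- kaplan_meier(data.frame(exit_age = 1:4, event = 1))
  expect_equal(km4$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(km4$surv) <= 0))
  expect_true(all(km4$lower <= km4$surv + 1e-12 &
                    km4$surv <= km4$upper + 1e-12, na.rm = TRUE))
})

test_that("Greenwood log-CI has near-nominal coverage on exponential data", {
  set.seed(31)
  t0 <- 0.5  # true S = exp(-0.5) ~ 0.607
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    d <- data.frame(exit_age = rexp(200), event = 1)
    km <- kaplan_meier(d)
    i <- findInterval(t0, km$time)
    if (i >= 1 && !is.na(km$lower[i]) &&
        km$lower[i] <= exp(-t0) && exp(-t0) <= km$upper[i]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.97)
})

test_that("log-rank test: identical groups, hand computation, null calibration", {
  d <- data.frame(exit_age = c(60.5, 70, 80), event = c(1, 0, 1),
                  entry_age = 60)
  res <- logrank_test(d, d)
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
  # hand-computed observed-minus-expected on a toy two-group layout
  a <- data.frame(exit_age = c(1, 3), event = 1)
  b <- data.frame(exit_age = c(2, 4), event = 1)
  # at times 1,2,3,4: O_a = 1,0,1,0; E_a = 2/4, 1/3, 1/2, 0; V = hypergeom
  O_E <- (1 - 2 / 4) + (0 - 1 / 3) + (1 - 1 / 2) + 0
  V <- (2 * 2) / (4 * 4) + (1 * 2) / (3 * 3) + (1 * 1) / (2 * 2) + 0
  res2 <- logrank_test(a, b)
  expect_equal(res2$chisq, O_E^2 / V, tolerance = 1e-8)
  expect_error(logrank_test(a, a[0, ]), "at least one record")
  # null calibration: p uniform over replicates
  set.seed(41)
  ps <- replicate(200, {
    d <- data.frame(exit_age = rexp(200), event = rbinom(200, 1, 0.8))
    g <- rep(1:2, each = 100)
    logrank_test(d[g == 1, ], d[g == 2, ])$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Cochran-Armitage trend matches the formula oracle", {
  # hand example: progressed (1,2,6) of (10,10,10), scores (1,2,3)
  res <- cochran_armitage_trend(c(1, 2, 6), c(10, 10, 10), 1:3)
  expect_equal(res$z, 5 / sqrt(4.2), tolerance = 1e-12)
  # cross-check chi-square against stats::prop.trend.test
  ptt <- stats::prop.trend.test(c(1, 2, 6), c(10, 10, 10), 1:3)
  expect_equal(res$z^2, unname(ptt$statistic), tolerance = 1e-10)
  # equal proportions: z = 0
  expect_equal(cochran_armitage_trend(c(3, 3, 3), c(10, 10, 10), 1:3)$z, 0)
  # reversing bin order flips the sign, p unchanged
  rev_res <- cochran_armitage_trend(c(6, 2, 1), c(10, 10, 10), 1:3)
  expect_equal(rev_res$z, -res$z, tolerance = 1e-12)
  expect_equal(rev_res$p, res$p, tolerance = 1e-12)
  expect_error(cochran_armitage_trend(1, 10, 1), "at least 2 bins")
  expect_error(cochran_armitage_trend(c(1, 2), c(10, 0), 1:2), "positive")
  expect_error(cochran_armitage_trend(c(0, 0), c(10, 10), 1:2), "degenerate")
})

test_that("PH diagnostic separates proportional from crossing hazards", {
  set.seed(51)
  n <- 500
  # proportional hazards: group doubles the hazard
  g <- rbinom(n, 1, 0.5)
  t_ph <- rexp(n, 0.1 * exp(log(2) * g))
  d_ph <- data.frame(exit_age = t_ph, event = 1, x = g)
  fit <- fit_cox(d_ph, "x")
  diag_ph <- ph_diagnostic(d_ph, fit, strata = g)
  cov_ph <- vapply(diag_ph$strata, `[[`, numeric(1), "ci_coverage")
  expect_true(all(cov_ph >= 0.9))
  # stratum identical to whole sample under the null model: gap ~ 0
  d0 <- data.frame(exit_age = rexp(300, 0.1), event = 1, z = 0)
  f0 <- fit_cox(d0, "z")
  diag0 <- ph_diagnostic(d0, f0, strata = rep("all", 300))
  expect_lt(diag0$max_gap, 0.08)
  # crossing hazards: Weibull shapes on either side of 1
  t_a <- rweibull(n / 2, shape = 0.5, scale = 8)
  t_b <- rweibull(n / 2, shape = 3, scale = 8)
  d_x <- data.frame(exit_age = c(t_a, t_b), event = 1,
                    x = rep(0:1, each = n / 2))
  fx <- fit_cox(d_x, "x")
  diag_x <- ph_diagnostic(d_x, fx, strata = d_x$x)
  # reference distribution of the gap under PH at the same size
  ref_gaps <- replicate(20, {
    g2 <- rep(0:1, each = n / 2)
    tt <- rexp(n, 0.1 * exp(0.3 * g2))
    dd <- data.frame(exit_age = tt, event = 1, x = g2)
    ph_diagnostic(dd, fit_cox(dd, "x"), strata = g2)$max_gap
  })
  expect_gt(diag_x$max_gap, max(ref_gaps))
  # stratum with no events is skipped with a warning
  d_ne <- d_ph; d_ne$event[d_ne$x == 1] <- 0
  fit_ne <- fit_cox(d_ne, "x")
  expect_warning(ph_diagnostic(d_ne, fit_ne, strata = d_ne$x), "no events")
})
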