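---
title: "Polygenic hazard scores: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic hazard scores: model, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhaz)
```

## The model

`polyhaz` treats disease onset as a survival process on the age scale. An
individual's genetic liability enters a proportional-hazards model as a
polygenic hazard score (PHS),

$$ s_i \;=\; \sum_j \beta_j \, g_{ij}, $$

the dosage-weighted sum of per-allele log hazard ratios over a set of risk
SNPs plus the two APOE allele terms (one weight per ε2 and ε4 copy; ε3 is
the reference). The instantaneous risk at age $t$ is

$$ h(t \mid s) \;=\; h_0^*(t)\, e^{\,s}, $$

where $h_0^*(t)$ is the baseline hazard of a score-zero individual. Scores
are centered so that zero is the population mean genetic profile.

Three stages produce a usable risk model:

1. **Candidate definition.** GWAS summary statistics are prescreened at
   $p < 10^{-5}$ (`prescreen()`; a direction filter restricting to
   risk-increasing effects is available but off by default, since either
   reading of "associated with increased risk" is defensible).
2. **Weight estimation.** Candidates are entered by forward stepwise
   selection into a joint Cox model on age of onset, controlling for sex,
   the APOE dosages, and five genetic principal components
   (`stepwise_select()`), and the selected model's hazard ratios are
   bootstrap-averaged (`bootstrap_betas()`).
3. **Absolute-risk calibration.** Because case–control sampling distorts
   the baseline hazard, the score distribution is combined with published
   population incidence to solve for $h_0^*(t)$ (`calibrate_baseline()`),
   from which annualized incidence rates, survivor curves, and expected
   onset ages follow.

## The stepwise criterion

The selection loss is the **sum of absolute martingale residuals** of the
refitted joint model, $\sum_i |\delta_i - \hat H(t_i) e^{\beta x_i}|$. We
initially evaluated the sum of squared residuals and found it unreliable as
a model-quality criterion in this setting: adding a covariate with a Wald
$z$ of 9–10 frequently *increased* the squared sum (the many censored
records' residuals are pushed further negative and dominate the square),
while the absolute sum decreased consistently and ranks a truly associated
SNP first essentially always at moderate effect sizes.

Halting uses an **absolute improvement threshold** (default `tol = 3`): a
step is accepted only if it lowers the criterion by more than 3. The best
improvement offered by a pool of null SNPs is an extreme value of
$O(1)$ chi-square-like quantities and is empirically ~1–2.5 across cohort
sizes from 1,500 to 8,000, whereas a SNP with $|\log HR| \gtrsim 0.2$ at a
few thousand events improves the criterion by 4 or more. A *relative*
tolerance cannot be size-stable, because the criterion itself scales with
the number of events while the null improvement does not. The threshold is
deterministic, so selection is exactly reproducible; the full path is
recorded in a selection trace whose criterion is strictly decreasing along
accepted steps.

Bootstrap averaging refits the **fixed** selected model on each resample
(selection is not re-run; the reported weight is the mean over converged
resamples and the uncertainty is the bootstrap standard deviation).
Conditional p-values come from the full-data joint fit's Wald tests and are
reported both raw and as $-\log_{10} p$.

## The reference score distribution

Population percentiles and calibration require the distribution $f(s)$ of
the score in the general population. It is built from per-variant
effect-allele frequencies under Hardy–Weinberg equilibrium (dosage
$\sim \mathrm{Binomial}(2, f_j)$) and linkage equilibrium (independence
across variants), with the APOE genotype drawn as an ordered pair of
ε2/ε3/ε4 alleles so that the ε2 + ε4 dosage can never exceed two. LD is
deliberately not modelled: per-SNP frequencies are combined exactly as the
weights were estimated, and the package's scope excludes LD-aware
selection. An exact enumeration is available up to 12 SNPs; beyond that a
Monte Carlo sample (default $10^6$, configurable) represents the
distribution, and a DKW-type check in the test suite confirms the two
agree. Each support point retains its ε4-carrier flag so the distribution
can be conditioned on carrier status for APOE-stratified tables.
Percentiles use the midpoint convention at ties.

## Calibration to population incidence

Published incidence tables give annualized rates $q_a$ (percent per year)
at knot ages. Rates are converted to hazards by $h = -\ln(1 - q)$,
attached to their knot ages, and interpolated log-linearly (incidence for
this disease is close to exponential in age); below the first knot the
hazard is held flat, beyond the last knot log-linear extrapolation is
optional. The calibration marches an age grid (default $\Delta t$ = 0.25 y
from 5 y before the first knot to 100 y) and, per grid cell, solves by
Newton iteration (tolerance $10^{-13}$) for the baseline hazard $h_0^*$
that makes the *score-mixture* survival drop match the population curve
exactly:

$$ \frac{\sum_k w_k S_k(t)\, e^{-h_0^* e^{s_k} \Delta t}}{\sum_k w_k S_k(t)}
   \;=\; e^{-\int_t^{t+\Delta t} h_{pop}(u)\,du}, $$

with $S_k$ the survivor function at support point $s_k$. Consequently the
population hazard among survivors reproduces the published curve to
machine precision on the grid (the reconstruction residual is stored as a
diagnostic), a degenerate distribution returns the discretized population
hazard itself, and a forward simulation from the calibrated model matches
the published column within Monte Carlo error. With a heterogeneous score
distribution $h_0^*$ sits *below* the population hazard at young ages and
drifts upward relative to it as high-score individuals are depleted.

One ambiguity deserves note: the published rate is defined as a one-year
conditional proportion, and we read its knot value as the hazard *at* the
knot age. Under this reading the model's forward one-year probability at a
knot differs from the printed value by the within-year hazard growth
(about 7% at growth rate ~0.143/y). The empirical counterpart used in the
round-trip checks is therefore an events/person-time hazard in a ±0.5 y
window centred on the knot, which is the estimator consistent with the
pointwise reading.

## Incidence tables and the depletion effect

Percentile columns evaluate the annualized incidence
$100(1 - e^{-\int_a^{a+1} h_0^* e^s})$ at the quantile score of the
reference distribution — a single $s$ per column, matching the
single-percentile column heads of published tables — and are capped at 100.
Two modes are offered: the default holds the percentile's score fixed
across ages, so the ratio of extreme columns is exactly $e^{s_{99}-s_1}$ on
the hazard scale at every age; the `survivor_quantile` mode re-draws the
quantile from the survivor-reweighted distribution at each age, under
which the extreme-percentile contrast shrinks with age as high-score
individuals are depleted. APOE carrier and non-carrier columns are
survivor-weighted mean rates within the conditioned distributions.
Optional uncertainty intervals resample the weight table from its
bootstrap standard errors and rebuild the distribution and calibration;
the published tables' interval construction is not described, so these
intervals are a stated convention, not a reproduction.

## The synthetic-cohort generator

Every stage is testable offline because the generator reproduces the
statistical structure the framework assumes:

- **Genotypes** under HWE and LE at configurable frequencies; APOE as a
  three-allele genotype with default allele frequencies (ε2, ε3, ε4) =
  (0.08, 0.78, 0.14), typical of European-ancestry populations.
- **Onset ages** from a Gompertz baseline
  $h(t) = \lambda e^{\gamma (t-60)}$ with proportional score effects. The
  defaults $\lambda = 8\times10^{-4}$/y and $\gamma = \ln(12.10/0.08)/35
  \approx 0.1434$/y anchor the baseline to the published US incidence
  endpoints at ages 60 and 95, giving a median onset near 94 y for a
  mean-profile individual.
- **Effect sizes**: the default 15-SNP panel is scaled so the SNP score has
  population standard deviation 0.35 — the scale implied by a
  top-versus-bottom-decile hazard ratio near 3.3 within a fixed APOE
  stratum — with the APOE weights at their published values (−0.47 per ε2,
  1.03 per ε4).
- **Censoring**: last-visit ages uniform on 65–95 y (clinic-cohort
  assessment ages), independent of genotype; entry at age 60.
- **Ascertainment**: cohort mode, or case–control sampling of requested
  counts; events with onset before 60 are excluded, mirroring standard
  late-onset inclusion criteria.

The generator does **not** emulate LD between variants, genotyping or
imputation error, family-based sampling, competing mortality, secular
trends in diagnosis, or covariate-dependent censoring. Passing tests
therefore demonstrate internal statistical correctness of the machinery
under the model's own assumptions, not robustness to the ways real cohort
data violate them.

The paper-scale analyses shrink to desk scale in the tests and the
acceptance script: training cohorts of 5,000–8,000 with 15–30 candidates,
20,000 ascertained validation cases in 20 percentile bins, $10^6$
forward-simulated individuals for the calibration round trip, and
bootstrap sizes of 60–200 (the user-facing default remains 1,000). These
sizes were chosen so every property under test retains comfortable
statistical resolution.

## Numerical choices

- Cox fitting uses the Efron tie correction by default (Breslow by flag)
  and left truncation at entry age whenever positive entry ages are
  present; with age as the time axis and entry at 60, truncation is
  the safe default.
- Under Efron ties the martingale residuals give the deceased their
  reduced own-death increments, so the residuals sum to zero exactly at
  any coefficient value.
- Log-rank comparisons fall back to the Cox score test at $\beta = 0$
  (identical statistic) when records carry delayed entry.
- Non-convergence, infinite coefficients, and monotone-likelihood
  separation are flagged on the fit object and skipped-with-warning inside
  the stepwise loop, never silent.
- Degenerate inputs are errors with named causes: empty risk sets,
  all-or-none progression tables, percentiles outside (0, 100), quantile
  levels outside (0, 1), ages off the calibrated grid.

## Limitations

The score model is strictly additive on the log-hazard scale, with no
interactions, no rare-variant terms, and no environmental covariates. The
reference distribution inherits whatever frequency panel it is given; the
package ships a clearly labelled *synthetic* panel for exercising the
pipeline, and real analyses must supply ancestry-matched frequencies.
Published incidence is not sex-stratified here, and competing mortality is
not modelled, so late-age absolute risks are risks of onset in the absence
of competing death.
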