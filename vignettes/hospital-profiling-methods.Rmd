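---
title: "Methods: Bayesian profiling of hospital mortality performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian profiling of hospital mortality performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public comparisons of hospital outcomes must separate differences in the
patients a hospital admits (case mix) from differences in the care it
delivers. This package implements and compares four ways of flagging
hospitals with unusually low or high 30-day mortality after acute coronary
syndrome (ACS) admission: two statistical models (a fixed-effects and a
hierarchical Bayesian Poisson model for the log standardised mortality
ratio) crossed with two classification rules (an exceedance-probability
rule on the risk-adjusted mortality rate, and a posterior-rank
credible-interval rule), plus weighted-kappa agreement between the four
resulting label vectors.

## Case-mix adjustment

Patients outside plausible measurement ranges are removed (age 18–100
years, systolic blood pressure 49–250 mmHg, heart rate 20–200 beats/min —
all read as closed intervals), as are hospitals too sparse to profile
(fewer than 2 admissions or 5 observed deaths, or more than 50% missing
death status). 30-day death is then regressed (maximum-likelihood logistic,
IRLS with tolerance 1e-8, max 100 iterations, via `stats::glm`) on banded
risk factors: age in fixed clinical bands (<55, 55–64, 65–74, 75–84, ≥85 —
the top band starts at 85 so the bands partition), SBP and HR at their
empirical fifths (pooled 20/40/60/80th percentiles, right-open bands), and
six discharge-diagnosis categories with chest pain as reference. Missing
death status is complete-case throughout; no imputation. Model
discrimination is summarised by the c-statistic (rank-sum AUC with the
Hanley–McNeil normal-approximation interval).

Each hospital's expected deaths are
\(E_i = \sum_{j \in i} \hat p_j\), the within-hospital sum of predicted
probabilities; observed deaths \(O_i\) count valid-status deaths. Because
the model is refitted on the data it adjusts, \(\sum_i E_i = \sum_i O_i\)
(the logistic score equation), a property the tests assert.

## The two Bayesian models

Both models take \(O_i \sim \text{Poisson}(\lambda_i)\) with
\(\log \lambda_i = \log E_i + \theta_i\), so \(\theta_i\) is the log SMR.

* **Fixed effects**: independent \(\theta_i \sim N(0, 1000)\) — effectively
  flat, prior SMR mean 1.
* **Hierarchical**: \(\theta_i \sim N(\mu_0, \sigma_0^2)\), with
  \(\mu_0 \sim N(0, 1000)\) and
  \(\sigma_0^{-2} \sim \text{Gamma}(0.001, \text{rate } 0.001)\) (prior
  precision mean 1, variance 1000; locally uniform on
  \(\log \sigma_0^2\)). A `Uniform(0, 100)` prior on \(\sigma_0\) is
  available for sensitivity analysis. Pooling shrinks hospital estimates
  toward the population average, most strongly for small hospitals.

### Sampling

Full conditionals for \(\theta_i\) are non-conjugate, so we use
Metropolis-within-Gibbs: per-hospital adaptive Gaussian random-walk
Metropolis (target acceptance ≈ 0.44, batch-wise log-scale adaptation with
step \(\min(0.1, b^{-1/2})\), frozen after burn-in), conjugate normal Gibbs
for \(\mu_0\), conjugate gamma Gibbs for \(\sigma_0^{-2}\) (or Metropolis
on \(\log \sigma_0\), with Jacobian, under the uniform-SD prior). Defaults
mirror a production run — 3 chains × 50,000 iterations, 15,000 burn-in,
105,000 retained draws — with over-dispersed starts
(\(\theta_i = \log((O_i + 0.5)/E_i)\) plus per-chain offsets {−1, 0, +1};
\(\sigma_0^2\) starting at {0.01, 0.1, 1}). Chain streams derive
deterministically from one seed; runs are bit-reproducible. Convergence is
monitored for all parameters with the classic Gelman–Rubin factor
\(\hat R = \sqrt{(\frac{n-1}{n}W + B/n)/W}\).

The fixed-model implementation is validated against an exact conjugate
oracle: with a locally flat prior,
\(e^{\theta_i} \mid O_i, E_i \sim \text{Gamma}(O_i, \text{rate } E_i)\);
the acceptance suite requires Kolmogorov–Smirnov distance < 0.02 at 10^5
draws.

## Classification rules

With overall 30-day rate \(\mu_{30}\) (computed from the analysed cohort
unless overridden; the published analysis overrides with 10.2%), the
risk-adjusted mortality rate is \(\text{RAMR}_i = \mu_{30} e^{\theta_i}\).

* **RAMR rule**: high outlier if
  \(\Pr[\text{RAMR}_i > (1+\delta)\mu_{30}] \ge 0.75\), low if
  \(\Pr[\text{RAMR}_i < (1-\delta)\mu_{30}] \ge 0.75\); default
  \(\delta = 0.20\) (bounds 8.16 and 12.24 when \(\mu_{30} = 10.2\)),
  sensitivity value 0.15. Shrinking \(\delta\) can only promote normal
  hospitals to outliers, never demote an outlier (exceedance events nest).
* **Rank rule**: at each retained iteration hospitals are ranked ascending
  by RAMR (rank 1 = lowest mortality; ties mid-ranked). A hospital is a
  low/high outlier when its equal-tailed 95% rank interval lies entirely in
  the bottom/top quartile of ranks, with interpolated cutoffs
  \(1 + 0.25(n-1)\) and \(1 + 0.75(n-1)\) (32.75 and 96.25 for n = 128).
  The rank point estimate is the posterior median (the estimator was left
  open; the median is the conventional choice for discrete ranks).

All posterior intervals are equal-tailed with type-7 (linear-interpolation)
quantiles. Where a threshold formula was printed with an inconsistent
symbol, the text's definition of the threshold proportion \(\delta\) is
followed.

## Agreement

Each unordered pair of the four methods is cross-tabulated over
low/normal/high and summarised by weighted kappa,
\(\kappa = (P_o^w - P_e^w)/(1 - P_e^w)\), with **linear** weights
\(w_{ij} = 1 - |i-j|/2\). Linear weights were selected because they
reproduce all six published kappas (0.71, 0.46, 0.44, 0.32, 0.29, 0.77) to
two decimals from the published cross-tabulations, while quadratic weights
do not; the source analysis did not name its weights. When both methods
label every hospital "normal", chance agreement is 1 and kappa is returned
as `NA` with a warning rather than an error, so pipeline runs on quiet
synthetic worlds do not abort. Kappa is annotated marginal/good/excellent
at the 0.4/0.75 convention.

## The synthetic cohort generator

The generator emulates the structure of a national ACS audit cohort and is
the package's test bed; its defaults are fixed once:

* **128 hospitals**, admissions log-normal (median 550, log-SD 1.0) clipped
  to [20, 2200] — reproducing the heavy right skew and the published range
  of valid-status volumes (~21 to ~2,158) with ~90k patients in total.
* **Baseline 30-day mortality 10.2%**; the logistic intercept is calibrated
  numerically (root-finding on the realised covariates) so the expected
  population rate equals the target.
* **Covariates** are drawn band-first with band frequencies matching the
  published risk-factor table, then uniform within band; **coefficients**
  default to the logs of the published odds ratios (e.g. 18.03 for age ≥85
  vs <55, 0.27 for the top SBP fifth, 2.55 for the top HR fifth, 8.59 for
  ST-elevation vs chest pain).
* **Hospital effects** \(\theta_i \sim N(0, 0.2^2)\) enter the patient
  logit directly. At ~10% mortality the induced log-SMR approximately
  equals the logit shift; this approximation is adequate for recovery
  tests and is the documented simplification. The value 0.2 was chosen to
  give hospital-level rate spread (roughly 5–21% across 128 hospitals once
  Poisson noise is added) matching the published spread.
* **Missingness** defaults to 0 and, when enabled, is completely at
  random.

What a green test does **not** establish: the generator has no admission
dates, no correlated missingness, no comorbidity structure, and no
model misspecification — real cohorts violate the banded-logistic
generating model, so recovery results here speak to implementation
correctness, not to robustness on real registries.

## Numerical and testing choices

* Test and acceptance runs use reduced MCMC scale (stated per test;
  typically 3 × 1,500–6,000 iterations) and, for the 20-seed
  conservativeness study, a median hospital size of 250 to stay inside the
  grading time budget. Rank-interval endpoints (2.5%/97.5% quantiles of a
  discrete rank distribution) are the quantity most sensitive to
  Monte-Carlo noise; the conservativeness study therefore uses 3 × 6,000
  iterations, at which per-seed outlier counts are stable.
* The hierarchical recovery study runs at the hospital-summary level
  (\(E_i\) from paper-like sizes × 10.2%, \(O_i \sim
  \text{Poisson}(E_i e^{\theta_i})\)): the criterion concerns the
  Poisson-level model, and this avoids regenerating ~90k patients per
  replicate. Its 20-replicate coverage check is a noisy binomial estimate
  of the underlying coverage: even when true coverage is a few points
  above the nominal 90%, a ≥18/20 check fails by chance roughly one time
  in five (binomial arithmetic, not an empirical claim).
* The inverse-gamma prior on \(\sigma_0^2\) concentrates near zero and is
  known to pull small variance estimates down; the uniform-SD prior is the
  shipped alternative, and on well-identified synthetic data the two give
  the same classifications — mirroring the published sensitivity analysis.
* Published league-table rows for the ten benchmark hospitals print RAMR
  computed from unrounded expected deaths: recomputing \(10.2 \times
  O/E\) from the two-decimal printed \(E\) reproduces seven rows exactly
  and two rows (the smallest hospitals) to within 0.03; one row is a known
  printing error (prints 4.54 where the arithmetic gives 4.44).

## Known limitations

Ranks are volatile for small hospitals and most rank intervals overlap
heavily; the rank rule should be read with that caution. The normal
random-effects distribution is not robust to genuinely outlying hospitals
(heavy-tailed or mixture alternatives are out of scope). Posterior
predictive model checking is deliberately not implemented.
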