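# hospprofile

Bayesian profiling of hospital performance on risk-adjusted 30-day
mortality after acute coronary syndrome (ACS) admission.

Public "league tables" of hospital mortality must separate case mix (who a
hospital admits) from care quality (what it does for them), and must not
flag small hospitals as outliers on noise alone. This package implements
and compares the four standard Bayesian profiling methods — a
**fixed-effects** and a **hierarchical** Poisson model for each hospital's
log standardised mortality ratio, each combined with an
**exceedance-probability rule** on the risk-adjusted mortality rate (RAMR)
and a **posterior-rank credible-interval rule** — plus weighted-kappa
agreement between the four resulting classifications. It is aimed at
biostatisticians and health-services researchers studying provider
profiling methodology.

## The model

For hospital *i* with observed 30-day deaths *O<sub>i</sub>* and case-mix
expected deaths *E<sub>i</sub>* (the within-hospital sum of predicted
probabilities from a banded logistic risk model):

* *O<sub>i</sub>* ~ Poisson(*λ<sub>i</sub>*), log *λ<sub>i</sub>* =
  log *E<sub>i</sub>* + *θ<sub>i</sub>*, so *θ<sub>i</sub>* = log SMR.
* Fixed effects: *θ<sub>i</sub>* ~ N(0, 1000) independently.
* Hierarchical: *θ<sub>i</sub>* ~ N(*μ₀*, *σ₀*²), *μ₀* ~ N(0, 1000),
  *σ₀*⁻² ~ Gamma(0.001, rate 0.001) (uniform(0, 100) on *σ₀* available
  for sensitivity analysis).
* RAMR<sub>i</sub> = *μ₃₀* · exp(*θ<sub>i</sub>*) with *μ₃₀* the overall
  30-day rate in percent (10.2 in the published benchmark).
* High outlier if Pr[RAMR > (1+δ)·*μ₃₀*] ≥ 0.75 (δ = 0.20 → bound 12.24),
  low if Pr[RAMR < (1−δ)·*μ₃₀*] ≥ 0.75 (bound 8.16); or, by rank, if the
  95% credible interval of the hospital's rank lies entirely in the
  bottom/top quartile (cutoffs 32.75 / 96.25 for 128 hospitals).
* Pairwise agreement: linear-weighted kappa over the 3×3
  low/normal/high cross-tabulation.

Posteriors are sampled by adaptive Metropolis-within-Gibbs MCMC (3 chains,
over-dispersed starts, Gelman–Rubin diagnostics), bit-reproducible from a
seed. A synthetic patient-level cohort generator with known ground truth
(128 hospitals, volumes 20–2,200, 10.2% baseline mortality, published-scale
covariate effects) drives all testing. See
`vignettes/hospital-profiling-methods.Rmd` for the full account.

## Worked example

```r
library(hospprofile)
cfg <- run_config(
  cohort = cohort_config(n_hospitals = 128, seed = 1),
  mcmc = mcmc_config(n_chains = 3, n_iterations = 3000, burn_in = 1000,
                     seed = 2),
  mu30_override = 10.2)
run <- run_pipeline(cfg)
print(run)
print(run$agreement)
```

```
[generate] 102667 patients in 128 hospitals
[adjust] 102667 patients retained, 128 hospitals, c = 0.792
[fit] 6000 draws kept per model, max r_hat = 1.006
[profile] outliers: fixed ramr 22, fixed rank 9, hier ramr 4, hier rank 3
[agree] kappa range 0.22-0.85
Profiling run: 128 hospitals, mu30 = 10.20%, delta = 0.20
  outliers: fixed_ramr = 22, fixed_rank = 9, hier_ramr = 4, hier_rank = 3
  max r_hat = 1.006
fixed_ramr.vs.fixed_rank     kappa 0.56 (good), weighted agreement 94.9%
fixed_ramr.vs.hier_ramr      kappa 0.29 (marginal), weighted agreement 93.0%
fixed_ramr.vs.hier_rank      kappa 0.22 (marginal), weighted agreement 92.6%
fixed_rank.vs.hier_ramr      kappa 0.61 (good), weighted agreement 98.0%
fixed_rank.vs.hier_rank      kappa 0.49 (good), weighted agreement 97.7%
hier_ramr.vs.hier_rank       kappa 0.85 (excellent), weighted agreement 99.6%
```

Reading this: the case-mix model discriminates well (c-statistic 0.79);
chains mixed (all Gelman–Rubin factors ≤ 1.006). The fixed-effects methods
flag 22 and 9 outliers where the hierarchical methods — which shrink noisy
small-hospital estimates toward the average — flag only 4 and 3: the
hierarchical methods are markedly more conservative. Observed agreement
between classifications is high everywhere (93–99.6%), but chance-corrected
agreement is only good-to-excellent *within* a model (0.56 fixed, 0.85
hierarchical) and marginal *between* the hierarchical rank method and
either fixed method (0.22–0.29): the choice of statistical model matters
more than the choice of outlier definition.

The ten-hospital published league-table benchmark and the six published
cross-classifications ship as plain-text data
(`benchmark_hospitals()`, `benchmark_crosstabs()`); for example
`plug_in_ramr(19, 9.97)` returns 19.44, the worst hospital's published
RAMR, and linear-weighted kappa reproduces all six published agreement
values to two decimals.

A sensitivity rerun (`sensitivity_rerun(run, list(delta = 0.15))`) tightens
the RAMR thresholds; by construction it can only promote previously-normal
hospitals, never demote an outlier. A command-line interface with verbs
`generate`, `adjust`, `fit`, `profile`, `agree`, `run`, `sensitivity` is
available via `inst/cli/hospprofile` or `hospprofile_cli()`.

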