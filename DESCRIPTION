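Package: hospprofile
Title: Bayesian Profiling of Hospital Mortality Performance
Version: 0.1.0
Authors@R:
    person("MINAP", "Profiling Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing hospital performance on risk-adjusted 30-day
    mortality after acute coronary syndrome admission. Provides a synthetic
    patient-level cohort generator with known ground truth; case-mix
    adjustment via banded logistic regression yielding per-hospital observed
    and expected deaths; fixed-effects and hierarchical Bayesian Poisson
    models for the log standardised mortality ratio, sampled by adaptive
    Metropolis-within-Gibbs MCMC with Gelman-Rubin diagnostics; outlier
    classification by risk-adjusted mortality rate exceedance probabilities
    and by posterior rank credible intervals; and pairwise agreement between
    the four resulting profiling methods using weighted kappa statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
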