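# Shared fixtures: everything is generated in code at test time.

small_mcmc <- function(seed = 11, iters = 1500, burn = 500, chains = 3) {
  mcmc_config(n_chains = chains, n_iterations = iters, burn_in = burn,
              seed = seed)
}

toy_summaries <- function(O, E, ids = seq_along(O)) {
  structure(data.frame(hospital_id = ids,
                       n_admissions = pmax(1L, as.integer(round(E * 10))),
                       observed = O, expected = E),
            class = c("hospital_summary", "data.frame"))
}

# Hospital-summary-level world matching the patient-level generator's
# assumptions: sizes log-normal clipped to [20, 2200], E_i = size x 10.2%,
# theta_i ~ N(mu0, sigma0^2), O_i ~ Poisson(E_i e^theta_i).
simulate_summaries <- function(n_hosp = 128, mu0 = 0, sigma0 = 0.2,
                               seed = 1, median_size = 550) {
  set.seed(seed)
  sizes <- pmin(pmax(stats::rlnorm(n_hosp, log(median_size), 1), 20), 2200)
  E <- sizes * 0.102
  theta <- stats::rnorm(n_hosp, mu0, sigma0)
  O <- stats::rpois(n_hosp, E * exp(theta))
  list(summaries = toy_summaries(O, E), theta = theta,
       mu0 = mu0, sigma0 = sigma0)
}

# hand-built patient rows for exclusion/banding tests (args recycle)
mk_patients <- function(hospital_id = 1L, age = 60, sbp = 140,
                        hr = 80, diagnosis = "chest_pain", died = 0L) {
  data.frame(hospital_id = hospital_id, age = age, sbp = sbp,
             heart_rate = hr, diagnosis = diagnosis, died_30d = died,
             stringsAsFactors = FALSE)
}
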