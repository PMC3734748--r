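#' Bayesian model specification for hospital effects
#'
#' Both models treat observed deaths as `O_i ~ Poisson(lambda_i)` with
#' `log lambda_i = log E_i + theta_i`, so `theta_i` is the hospital's
#' log standardised mortality ratio (log SMR).
#'
#' * `fixed`: independent `theta_i ~ Normal(0, fixed_prior_variance)`; the
#'   default variance 1000 is effectively flat and implies a prior SMR mean
#'   of 1.
#' * `hierarchical`: `theta_i ~ Normal(mu0, sigma0^2)` with
#'   `mu0 ~ Normal(0, hyper_mean_prior_variance)` and either
#'   `sigma0^-2 ~ Gamma(0.001, rate = 0.001)` (prior mean 1, variance 1000
#'   for the precision; locally uniform on log sigma0^2) or, for sensitivity
#'   analysis, `sigma0 ~ Uniform(0, 100)`.
#'
#' @param kind `"fixed"` or `"hierarchical"`.
#' @param fixed_prior_variance Prior variance of theta in the fixed model.
#' @param hyper_mean_prior_variance Prior variance of mu0.
#' @param sigma_prior `"gamma"` (conjugate, default) or `"uniform"`.
#' @param gamma_shape,gamma_rate Parameters of the gamma prior on the
#'   hyper-precision.
#' @param uniform_upper Upper bound of the uniform prior on sigma0.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("fixed", "hierarchical"),
                       fixed_prior_variance = 1000,
                       hyper_mean_prior_variance = 1000,
                       sigma_prior = c("gamma", "uniform"),
                       gamma_shape = 0.001, gamma_rate = 0.001,
                       uniform_upper = 100) {
  kind <- match.arg(kind)
  sigma_prior <- match.arg(sigma_prior)
  stopifnot(fixed_prior_variance > 0, hyper_mean_prior_variance > 0,
            gamma_shape > 0, gamma_rate > 0, uniform_upper > 0)
  out <- list(kind = kind, fixed_prior_variance = fixed_prior_variance,
              hyper_mean_prior_variance = hyper_mean_prior_variance,
              sigma_prior = sigma_prior, gamma_shape = gamma_shape,
              gamma_rate = gamma_rate, uniform_upper = uniform_upper)
  class(out) <- "model_spec"
  out
}

#' MCMC run configuration
#'
#' Defaults mirror a production run: three parallel chains of 50,000
#' iterations each, the first 15,000 discarded as burn-in, leaving a
#' combined posterior sample of 105,000 draws. Proposal-scale adaptation
#' happens only inside the burn-in window.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iterations Iterations per chain.
#' @param burn_in Iterations discarded per chain.
#' @param seed Integer seed; chain streams are derived from it.
#' @param adapt_window Iterations of proposal adaptation, capped at
#'   `burn_in`.
#' @param adapt_batch Batch length for acceptance-rate adaptation.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iterations = 50000L,
                        burn_in = 15000L, seed = 1L,
                        adapt_window = burn_in, adapt_batch = 50L) {
  stopifnot(n_chains >= 1, burn_in < n_iterations, burn_in >= 0,
            adapt_batch >= 1)
  out <- list(n_chains = as.integer(n_chains),
              n_iterations = as.integer(n_iterations),
              burn_in = as.integer(burn_in), seed = as.integer(seed),
              adapt_window = as.integer(min(adapt_window, burn_in)),
              adapt_batch = as.integer(adapt_batch))
  class(out) <- "mcmc_config"
  out
}

# Robbins-Monro-style log-scale step targeting acceptance 0.44
.adapt_step <- function(batch_number) min(0.1, batch_number^-0.5)

# One chain of the fixed-effects sampler: independent adaptive random-walk
# Metropolis on each theta_i (all hospitals updated in one vectorised sweep).
.run_chain_fixed <- function(O, E, v0, mcmc, start, chain_seed) {
  set.seed(chain_seed)
  n <- length(O)
  theta <- start
  log_sd <- rep(log(0.5), n)
  logE <- log(E)
  lp <- O * theta - E * exp(theta) - theta^2 / (2 * v0)
  if (any(!is.finite(lp))) stop("non-finite log-posterior at initial state")
  keep <- mcmc$n_iterations - mcmc$burn_in
  draws <- matrix(NA_real_, keep, n)
  acc_batch <- numeric(n)
  n_acc <- 0
  for (it in seq_len(mcmc$n_iterations)) {
    prop <- theta + stats::rnorm(n) * exp(log_sd)
    lpp <- O * prop - E * exp(prop) - prop^2 / (2 * v0)
    acc <- log(stats::runif(n)) < lpp - lp
    theta[acc] <- prop[acc]
    lp[acc] <- lpp[acc]
    if (it <= mcmc$adapt_window) {
      acc_batch <- acc_batch + acc
      if (it %% mcmc$adapt_batch == 0) {
        d <- .adapt_step(it %/% mcmc$adapt_batch)
        log_sd <- log_sd + ifelse(acc_batch / mcmc$adapt_batch > 0.44, d, -d)
        acc_batch[] <- 0
      }
    }
    if (it > mcmc$burn_in) {
      draws[it - mcmc$burn_in, ] <- theta
      n_acc <- n_acc + sum(acc)
    }
  }
  list(theta = draws, accept = n_acc / (keep * n))
}

# One chain of the hierarchical sampler: Metropolis on each theta_i, Gibbs
# on mu0, and either conjugate-gamma Gibbs on the precision or Metropolis on
# log sigma0 under the uniform-SD prior.
.run_chain_hier <- function(O, E, spec, mcmc, start, chain_seed) {
  set.seed(chain_seed)
  n <- length(O)
  theta <- start$theta
  mu0 <- start$mu0
  s2 <- start$sigma0_sq
  log_sd <- rep(log(0.5), n)
  log_sd_sig <- log(0.5)
  v_mu <- spec$hyper_mean_prior_variance
  lp <- O * theta - E * exp(theta) - (theta - mu0)^2 / (2 * s2)
  if (any(!is.finite(lp))) stop("non-finite log-posterior at initial state")
  keep <- mcmc$n_iterations - mcmc$burn_in
  draws <- matrix(NA_real_, keep, n)
  mu0_d <- numeric(keep)
  s2_d <- numeric(keep)
  acc_batch <- numeric(n)
  acc_sig <- 0
  zero_flag <- FALSE
  for (it in seq_len(mcmc$n_iterations)) {
    prop <- theta + stats::rnorm(n) * exp(log_sd)
    lpp <- O * prop - E * exp(prop) - (prop - mu0)^2 / (2 * s2)
    acc <- log(stats::runif(n)) < lpp - lp
    theta[acc] <- prop[acc]
    lp[acc] <- lpp[acc]

    # mu0 | theta, sigma0^2 : normal conjugate
    prec <- n / s2 + 1 / v_mu
    mu0 <- stats::rnorm(1, (sum(theta) / s2) / prec, sqrt(1 / prec))

    ss <- sum((theta - mu0)^2)
    if (spec$sigma_prior == "gamma") {
      # sigma0^-2 | theta, mu0 : gamma conjugate (rate parameterisation)
      s2 <- 1 / stats::rgamma(1, spec$gamma_shape + n / 2,
                              rate = spec$gamma_rate + ss / 2)
    } else {
      # uniform(0, upper) prior on sigma0: Metropolis on log sigma0 with the
      # Jacobian term; target log-density -n log(sigma) - ss/(2 sigma^2)
      lsig <- log(sqrt(s2))
      lsig_p <- lsig + stats::rnorm(1) * exp(log_sd_sig)
      if (exp(lsig_p) < spec$uniform_upper) {
        ld <- function(l) -n * l - ss / (2 * exp(2 * l)) + l
        if (log(stats::runif(1)) < ld(lsig_p) - ld(lsig)) {
          lsig <- lsig_p
          acc_sig <- acc_sig + 1
        }
      }
      s2 <- exp(2 * lsig)
    }
    if (s2 < 1e-12) zero_flag <- TRUE
    # hyper-parameters moved: refresh the cached theta log-posterior
    lp <- O * theta - E * exp(theta) - (theta - mu0)^2 / (2 * s2)

    if (it <= mcmc$adapt_window) {
      acc_batch <- acc_batch + acc
      if (it %% mcmc$adapt_batch == 0) {
        b <- it %/% mcmc$adapt_batch
        d <- .adapt_step(b)
        log_sd <- log_sd + ifelse(acc_batch / mcmc$adapt_batch > 0.44, d, -d)
        if (spec$sigma_prior == "uniform") {
          log_sd_sig <- log_sd_sig +
            if (acc_sig / mcmc$adapt_batch > 0.44) d else -d
          acc_sig <- 0
        }
        acc_batch[] <- 0
      }
    }
    if (it > mcmc$burn_in) {
      k <- it - mcmc$burn_in
      draws[k, ] <- theta
      mu0_d[k] <- mu0
      s2_d[k] <- s2
    }
  }
  if (zero_flag)
    warning("sigma0 chain touched ~0; posterior may be absorbing at zero")
  list(theta = draws, mu0 = mu0_d, sigma0_sq = s2_d)
}

.check_summaries <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("hospital_id", "observed", "expected") %in%
                  names(summaries)))
  if (any(summaries$expected <= 0))
    stop("expected deaths must be positive for every hospital")
}

.chain_seeds <- function(mcmc) {
  set.seed(mcmc$seed)
  sample.int(.Machine$integer.max, mcmc$n_chains)
}

.assemble_draws <- function(chains, mcmc, hospital_id, model, spec) {
  keep <- mcmc$n_iterations - mcmc$burn_in
  theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  out <- list(theta = theta,
              mu0 = if (!is.null(chains[[1]]$mu0))
                unlist(lapply(chains, `[[`, "mu0")),
              sigma0_sq = if (!is.null(chains[[1]]$sigma0_sq))
                unlist(lapply(chains, `[[`, "sigma0_sq")),
              chain = rep(seq_along(chains), each = keep),
              iteration = rep(seq_len(keep) + mcmc$burn_in,
                              times = length(chains)),
              hospital_id = hospital_id, model = model, spec = spec,
              mcmc = mcmc)
  class(out) <- "posterior_draws"
  out
}

#' Sample the fixed-effects posterior
#'
#' Each hospital's log SMR `theta_i` has an independent posterior
#' proportional to `Poisson(O_i | E_i e^theta) x Normal(theta | 0, v0)`,
#' sampled by adaptive random-walk Metropolis (target acceptance ~0.44;
#' adaptation frozen after burn-in). Chains start over-dispersed at
#' `log((O_i + 0.5)/E_i)` plus chain-specific offsets `{-1, 0, +1}`.
#'
#' @param summaries A [expected_deaths()] hospital summary table.
#' @param spec A `"fixed"` [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_draws` object: `theta` is a matrix with one column
#'   per hospital and one row per retained draw (chains stacked), with
#'   `chain` and `iteration` provenance vectors.
#' @export
fit_fixed_model <- function(summaries, spec = model_spec("fixed"),
                            mcmc = mcmc_config()) {
  .check_summaries(summaries)
  stopifnot(spec$kind == "fixed")
  O <- summaries$observed
  E <- summaries$expected
  seeds <- .chain_seeds(mcmc)
  offsets <- rep(c(-1, 0, 1), length.out = mcmc$n_chains)
  chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
    start <- log(O + 0.5) - log(E) + offsets[ch]
    .run_chain_fixed(O, E, spec$fixed_prior_variance, mcmc, start, seeds[ch])
  })
  .assemble_draws(chains, mcmc, summaries$hospital_id, "fixed", spec)
}

#' Sample the hierarchical (random-effects) posterior
#'
#' `theta_i ~ Normal(mu0, sigma0^2)` pools information across hospitals and
#' shrinks each hospital's estimate towards the population average, most
#' strongly for small hospitals. Sampling is Metropolis-within-Gibbs:
#' adaptive random-walk Metropolis for each `theta_i`, a normal conjugate
#' Gibbs draw for `mu0`, and a gamma conjugate Gibbs draw for the precision
#' `sigma0^-2` (or Metropolis on `log sigma0` under the uniform-SD prior).
#' Chains start over-dispersed: theta as in [fit_fixed_model()], `mu0 = 0`,
#' `sigma0^2` cycling through `{0.01, 0.1, 1}`.
#'
#' @inheritParams fit_fixed_model
#' @param spec A `"hierarchical"` [model_spec()].
#' @return A `posterior_draws` object, additionally carrying `mu0` and
#'   `sigma0_sq` draw vectors.
#' @export
fit_hierarchical_model <- function(summaries,
                                   spec = model_spec("hierarchical"),
                                   mcmc = mcmc_config()) {
  .check_summaries(summaries)
  stopifnot(spec$kind == "hierarchical", nrow(summaries) >= 3)
  O <- summaries$observed
  E <- summaries$expected
  seeds <- .chain_seeds(mcmc)
  offsets <- rep(c(-1, 0, 1), length.out = mcmc$n_chains)
  s2_starts <- rep(c(0.01, 0.1, 1), length.out = mcmc$n_chains)
  chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
    start <- list(theta = log(O + 0.5) - log(E) + offsets[ch],
                  mu0 = 0, sigma0_sq = s2_starts[ch])
    .run_chain_hier(O, E, spec, mcmc, start, seeds[ch])
  })
  .assemble_draws(chains, mcmc, summaries$hospital_id, "hierarchical", spec)
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Classic between/within-chain variance decomposition: with `m` chains of
#' length `n`, `W` the mean within-chain variance and `B/n` the variance of
#' the chain means, the factor is `sqrt(((n-1)/n W + B/n) / W)`. Values near
#' 1 indicate the chains have mixed into a common distribution.
#'
#' @param draws A `posterior_draws` object (all hospital effects plus any
#'   hyper-parameters are monitored), or a numeric matrix with one column
#'   per chain.
#' @param ... Unused.
#' @return data.frame of class `convergence_report` with columns
#'   `parameter`, `r_hat`.
#' @export
gelman_rubin <- function(draws, ...) UseMethod("gelman_rubin")

#' @rdname gelman_rubin
#' @export
gelman_rubin.matrix <- function(draws, ...) {
  if (ncol(draws) < 2) stop("need at least 2 chains")
  if (nrow(draws) < 10) stop("chain length must be at least 10")
  n <- nrow(draws)
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, stats::var))
  B_over_n <- stats::var(means)
  r_hat <- sqrt(((n - 1) / n * W + B_over_n) / W)
  structure(data.frame(parameter = "x", r_hat = r_hat),
            class = c("convergence_report", "data.frame"))
}

#' @rdname gelman_rubin
#' @export
gelman_rubin.posterior_draws <- function(draws, ...) {
  split_mat <- function(x) {
    do.call(cbind, lapply(split(x, draws$chain), identity))
  }
  one <- function(x) gelman_rubin(split_mat(x))$r_hat
  pars <- paste0("theta[", draws$hospital_id, "]")
  rh <- apply(draws$theta, 2, one)
  if (!is.null(draws$mu0)) {
    pars <- c(pars, "mu0", "sigma0_sq")
    rh <- c(rh, one(draws$mu0), one(draws$sigma0_sq))
  }
  structure(data.frame(parameter = pars, r_hat = unname(rh)),
            class = c("convergence_report", "data.frame"))
}

#' Posterior summaries
#'
#' Mean, median and an equal-tailed credible interval (type-7 quantiles).
#'
#' @param draws Numeric vector or matrix (columns = parameters), or a
#'   `posterior_draws` object (summarises theta plus hyper-parameters).
#' @param level Credibility level, default 0.95.
#' @return data.frame with `parameter`, `mean`, `median`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  if (inherits(draws, "posterior_draws")) {
    m <- draws$theta
    colnames(m) <- paste0("theta[", draws$hospital_id, "]")
    if (!is.null(draws$mu0))
      m <- cbind(m, mu0 = draws$mu0, sigma0_sq = draws$sigma0_sq)
    return(posterior_summary(m, level))
  }
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0) stop("no draws to summarise")
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(
    parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    mean = colMeans(draws),
    median = apply(draws, 2, stats::median),
    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws (%s model): %d hospitals, %d draws (%d chains)\n",
              x$model, ncol(x$theta), nrow(x$theta), x$mcmc$n_chains))
  invisible(x)
}
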