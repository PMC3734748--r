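#' Profiling configuration
#'
#' Parameters of the two outlier-classification rules.
#'
#' @param mu30 Overall 30-day mortality rate, in percent (default 10.2).
#' @param delta Relative threshold for the RAMR rule (default 0.20; 0.15 in
#'   sensitivity analysis). A hospital is a high outlier when the posterior
#'   probability that its RAMR exceeds `(1 + delta) * mu30` is at least
#'   `prob_cutoff`, a low outlier symmetrically below `(1 - delta) * mu30`.
#' @param prob_cutoff Posterior probability required to flag (default 0.75).
#' @param rank_level Credibility of the posterior rank intervals (0.95).
#' @param rank_quantiles Bottom/top rank quantile levels defining the
#'   outlying quartiles (0.25, 0.75).
#' @return A list of class `profiling_config`.
#' @export
profiling_config <- function(mu30 = 10.2, delta = 0.20, prob_cutoff = 0.75,
                             rank_level = 0.95,
                             rank_quantiles = c(0.25, 0.75)) {
  stopifnot(mu30 > 0, delta >= 0, prob_cutoff > 0.5, prob_cutoff <= 1,
            length(rank_quantiles) == 2,
            rank_quantiles[1] < rank_quantiles[2])
  out <- list(mu30 = mu30, delta = delta, prob_cutoff = prob_cutoff,
              rank_level = rank_level, rank_quantiles = rank_quantiles)
  class(out) <- "profiling_config"
  out
}

.label_levels <- c("low", "normal", "high")

#' Plug-in risk-adjusted mortality rate
#'
#' `RAMR = mu30 x O/E`: the overall rate scaled by the hospital's plug-in
#' standardised mortality ratio, interpretable as the hospital's expected
#' 30-day mortality had it admitted the population case mix.
#'
#' @param observed Observed deaths O (vectorised).
#' @param expected Expected deaths E (> 0).
#' @param mu30 Overall rate in percent.
#' @return RAMR in percent.
#' @export
plug_in_ramr <- function(observed, expected, mu30 = 10.2) {
  if (any(expected <= 0)) stop("expected deaths must be positive")
  mu30 * observed / expected
}

#' RAMR posterior draws
#'
#' Elementwise `mu30 * exp(theta)`; strictly monotone in theta, so draw-wise
#' ranks of RAMR equal draw-wise ranks of theta.
#'
#' @param theta Log-SMR draws (vector or draws-by-hospitals matrix).
#' @param mu30 Overall rate in percent.
#' @return RAMR draws, same shape, in percent.
#' @export
ramr_draws <- function(theta, mu30 = 10.2) mu30 * exp(theta)

#' Classify hospitals by RAMR exceedance probability
#'
#' @param ramr RAMR draws: vector (one hospital) or draws-by-hospitals
#'   matrix.
#' @param config A [profiling_config()].
#' @return data.frame with `p_high`, `p_low` (exceedance probabilities) and
#'   `label` in `low < normal < high`.
#' @export
classify_ramr <- function(ramr, config = profiling_config()) {
  if (is.null(dim(ramr))) ramr <- matrix(ramr, ncol = 1)
  hi <- (1 + config$delta) * config$mu30
  lo <- (1 - config$delta) * config$mu30
  p_high <- colMeans(ramr > hi)
  p_low <- colMeans(ramr < lo)
  label <- ifelse(p_high >= config$prob_cutoff, "high",
                  ifelse(p_low >= config$prob_cutoff, "low", "normal"))
  data.frame(p_high = p_high, p_low = p_low,
             label = factor(label, levels = .label_levels))
}

#' Posterior rank draws
#'
#' At each retained iteration, hospitals are ranked ascending by RAMR
#' (rank 1 = lowest mortality = best); ties receive mid-ranks. Because
#' RAMR is monotone in theta, ranking theta draws gives the same result.
#'
#' @param theta Draws-by-hospitals matrix (columns aligned across hospitals
#'   within each iteration).
#' @return Matrix of the same shape holding per-iteration ranks.
#' @export
rank_draws <- function(theta) {
  if (is.null(dim(theta)) || ncol(theta) < 1)
    stop("theta must be a draws-by-hospitals matrix")
  if (ncol(theta) == 1) return(matrix(1, nrow(theta), 1))
  t(apply(theta, 1, rank, ties.method = "average"))
}

#' Rank quartile cut points
#'
#' Linear-interpolation quantiles of the integer ranks 1..n:
#' `low = 1 + q1 (n - 1)`, `high = 1 + q2 (n - 1)`. For n = 128 and the
#' default quartiles these are 32.75 and 96.25.
#'
#' @param n_hospitals Number of hospitals (>= 2).
#' @param rank_quantiles Quantile levels, default `c(0.25, 0.75)`.
#' @return Named numeric `c(low_cut, high_cut)`.
#' @export
rank_quartile_cutoffs <- function(n_hospitals,
                                  rank_quantiles = c(0.25, 0.75)) {
  if (n_hospitals < 2) stop("need at least 2 hospitals to rank")
  c(low_cut = 1 + rank_quantiles[1] * (n_hospitals - 1),
    high_cut = 1 + rank_quantiles[2] * (n_hospitals - 1))
}

#' Classify a hospital by its rank credible interval
#'
#' Low outlier if the interval lies entirely in the bottom quartile of ranks
#' (upper endpoint <= low cut), high outlier if entirely in the top quartile
#' (lower endpoint >= high cut), otherwise normal.
#'
#' @param rank_interval Length-2 interval, or a 2-column matrix of
#'   intervals.
#' @param cutoffs From [rank_quartile_cutoffs()].
#' @return Factor label(s) in `low < normal < high`.
#' @export
classify_rank <- function(rank_interval, cutoffs) {
  if (is.null(dim(rank_interval)))
    rank_interval <- matrix(rank_interval, ncol = 2)
  if (any(rank_interval[, 1] > rank_interval[, 2]))
    stop("inverted rank interval")
  label <- ifelse(rank_interval[, 2] <= cutoffs[["low_cut"]], "low",
                  ifelse(rank_interval[, 1] >= cutoffs[["high_cut"]],
                         "high", "normal"))
  factor(label, levels = .label_levels)
}

#' Full hospital profiles from posterior draws
#'
#' Combines the plug-in SMR/RAMR, posterior RAMR summaries and exceedance
#' probabilities, posterior rank summaries, and both outlier labels into one
#' table.
#'
#' @param summaries Hospital summary table (O, E).
#' @param draws A `posterior_draws` object for the same hospitals.
#' @param config A [profiling_config()].
#' @return data.frame of class `hospital_profiles`, one row per hospital:
#'   O/E-based `smr` and `ramr_plugin`, posterior `ramr_mean`/`ramr_median`
#'   and equal-tailed interval, `p_high`/`p_low` and `ramr_label`, posterior
#'   `rank_median` and interval, and `rank_label`.
#' @export
profile_hospitals <- function(summaries, draws,
                              config = profiling_config()) {
  stopifnot(inherits(draws, "posterior_draws"),
            nrow(summaries) == ncol(draws$theta),
            all(summaries$hospital_id == draws$hospital_id))
  ramr <- ramr_draws(draws$theta, config$mu30)
  rs <- posterior_summary(ramr, level = config$rank_level)
  cls <- classify_ramr(ramr, config)

  rk <- rank_draws(draws$theta)
  rks <- posterior_summary(rk, level = config$rank_level)
  cuts <- rank_quartile_cutoffs(nrow(summaries), config$rank_quantiles)
  rlab <- classify_rank(cbind(rks$lower, rks$upper), cuts)

  out <- data.frame(
    hospital_id = summaries$hospital_id,
    n_admissions = summaries$n_admissions,
    observed = summaries$observed,
    expected = summaries$expected,
    smr = summaries$observed / summaries$expected,
    ramr_plugin = plug_in_ramr(summaries$observed, summaries$expected,
                               config$mu30),
    ramr_mean = rs$mean, ramr_median = rs$median,
    ramr_lower = rs$lower, ramr_upper = rs$upper,
    p_high = cls$p_high, p_low = cls$p_low, ramr_label = cls$label,
    rank_median = rks$median, rank_lower = rks$lower,
    rank_upper = rks$upper, rank_label = rlab)
  class(out) <- c("hospital_profiles", "data.frame")
  attr(out, "config") <- config
  attr(out, "model") <- draws$model
  out
}
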