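#' Cohort exclusion rules
#'
#' Range filters on admission covariates and hospital-level sparsity rules.
#' Defaults: age 18-100 years, SBP 49-250 mmHg, HR 20-200 beats/min (all
#' closed intervals), hospitals must have at least 2 admissions, at least 5
#' observed 30-day deaths, and at most 50% missing death status.
#'
#' @param age_range,sbp_range,hr_range Length-2 closed intervals.
#' @param min_admissions Minimum admissions per retained hospital.
#' @param min_deaths Minimum observed 30-day deaths per retained hospital.
#' @param max_missing Maximum tolerated proportion of missing death status.
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(age_range = c(18, 100),
                            sbp_range = c(49, 250),
                            hr_range = c(20, 200),
                            min_admissions = 2L,
                            min_deaths = 5L,
                            max_missing = 0.5) {
  for (r in list(age_range, sbp_range, hr_range))
    stopifnot(length(r) == 2, r[1] <= r[2])
  out <- list(age_range = age_range, sbp_range = sbp_range,
              hr_range = hr_range, min_admissions = as.integer(min_admissions),
              min_deaths = as.integer(min_deaths), max_missing = max_missing)
  class(out) <- "exclusion_rules"
  out
}

#' Apply cohort filters
#'
#' Removes patients whose age, SBP or HR fall outside the closed intervals in
#' `rules`, then removes entire hospitals that are too sparse to profile:
#' fewer than `min_admissions` admissions, fewer than `min_deaths` observed
#' deaths among valid-status patients, or more than `max_missing` missing
#' death status.
#'
#' @param patients Patient data.frame (see [generate_cohort()]).
#' @param rules An [exclusion_rules()] object.
#' @return List with `patients` (filtered) and `report`, a data.frame of
#'   removal counts by reason (patient rows for range filters, hospital
#'   counts for sparsity rules).
#' @export
apply_exclusions <- function(patients, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"))
  n0 <- nrow(patients)
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  ok_age <- in_range(patients$age, rules$age_range)
  ok_sbp <- in_range(patients$sbp, rules$sbp_range)
  ok_hr <- in_range(patients$heart_rate, rules$hr_range)
  keep <- ok_age & ok_sbp & ok_hr
  report <- data.frame(
    reason = c("age_out_of_range", "sbp_out_of_range", "hr_out_of_range"),
    unit = "patients",
    removed = c(sum(!ok_age), sum(!ok_sbp & ok_age),
                sum(!ok_hr & ok_age & ok_sbp)),
    stringsAsFactors = FALSE)
  patients <- patients[keep, , drop = FALSE]

  n_adm <- table(patients$hospital_id)
  deaths <- tapply(patients$died_30d, patients$hospital_id,
                   function(d) sum(d, na.rm = TRUE))
  miss <- tapply(patients$died_30d, patients$hospital_id,
                 function(d) mean(is.na(d)))
  ids <- names(n_adm)
  drop_adm <- as.vector(n_adm) < rules$min_admissions
  drop_dth <- !drop_adm & deaths[ids] < rules$min_deaths
  drop_mis <- !drop_adm & !drop_dth & miss[ids] > rules$max_missing
  dropped <- ids[drop_adm | drop_dth | drop_mis]
  report <- rbind(report, data.frame(
    reason = c("too_few_admissions", "too_few_deaths", "excess_missing"),
    unit = "hospitals",
    removed = c(sum(drop_adm), sum(drop_dth), sum(drop_mis)),
    stringsAsFactors = FALSE))
  patients <- patients[!(patients$hospital_id %in% dropped), , drop = FALSE]
  if (nrow(patients) == 0)
    stop("no patients survive the exclusion rules")
  report <- rbind(report, data.frame(
    reason = "retained", unit = "patients", removed = nrow(patients),
    stringsAsFactors = FALSE))
  attr(report, "n_input") <- n0
  list(patients = patients, report = report)
}

#' Derive covariate band edges
#'
#' Age bands are fixed at clinical cut points (<55, 55-64, 65-74, 75-84,
#' >=85). SBP and HR are banded at their empirical fifths: the 20/40/60/80th
#' percentiles of the pooled filtered cohort.
#'
#' @param patients Filtered patient data.frame.
#' @return List of class `band_edges` with numeric interior cut points
#'   `age`, `sbp`, `hr`; bands are right-open, `[edge_k, edge_{k+1})`.
#' @export
derive_bands <- function(patients) {
  for (v in c("sbp", "heart_rate"))
    if (length(unique(patients[[v]])) < 5)
      stop("need at least 5 distinct values of ", v, " to band into fifths")
  qs <- c(0.2, 0.4, 0.6, 0.8)
  out <- list(age = c(55, 65, 75, 85),
              sbp = unname(stats::quantile(patients$sbp, qs)),
              hr = unname(stats::quantile(patients$heart_rate, qs)))
  for (v in c("sbp", "hr"))
    if (any(diff(out[[v]]) <= 0))
      stop("band edges for ", v, " are not strictly increasing")
  class(out) <- "band_edges"
  out
}

.band_labels <- function(edges, digits = 0) {
  e <- round(edges, digits)
  c(paste0("<", e[1]),
    paste0("[", e[-length(e)], ",", e[-1], ")"),
    paste0(">=", e[length(e)]))
}

#' Attach banded factors to a patient table
#'
#' Adds `age_band`, `sbp_band`, `hr_band` (right-open bands from `edges`)
#' and a `diagnosis` factor with chest pain as the reference level.
#'
#' @param patients Patient data.frame.
#' @param edges A [derive_bands()] object.
#' @return The patient data.frame with four factor columns appended.
#' @export
band_patients <- function(patients, edges) {
  stopifnot(inherits(edges, "band_edges"))
  bandf <- function(x, e) {
    factor(.band_index(x, e), levels = seq_len(length(e) + 1L),
           labels = .band_labels(e))
  }
  patients$age_band <- bandf(patients$age, edges$age)
  patients$sbp_band <- bandf(patients$sbp, edges$sbp)
  patients$hr_band <- bandf(patients$heart_rate, edges$hr)
  patients$diagnosis <- factor(patients$diagnosis,
                               levels = diagnosis_levels())
  if (anyNA(patients$diagnosis))
    stop("unknown diagnosis category present")
  patients
}

#' Fit the case-mix logistic risk model
#'
#' Maximum-likelihood logistic regression of 30-day death on indicator-coded
#' age, SBP and HR bands and discharge diagnosis, fitted by iteratively
#' reweighted least squares (convergence tolerance 1e-8, at most 100
#' iterations). Patients with missing death status are dropped
#' (complete-case). The reference level of each factor is its first band
#' (age <55, lowest SBP fifth, lowest HR fifth, chest pain).
#'
#' @param patients Patient data.frame (banded or not; bands are applied from
#'   `band_edges` when absent).
#' @param band_edges A [derive_bands()] object.
#' @return List of class `risk_model`: `intercept`, `coefficients` (named
#'   log-odds for non-reference levels), `se`, `c_statistic` (estimate with
#'   95% CI), `band_edges`, `n_fit`, and the underlying `fit` used for
#'   prediction.
#' @export
fit_risk_model <- function(patients, band_edges) {
  patients <- band_patients(patients, band_edges)
  cc <- patients[!is.na(patients$died_30d), , drop = FALSE]
  for (f in c("age_band", "sbp_band", "hr_band", "diagnosis"))
    if (length(unique(cc[[f]])) < 2)
      stop("factor ", f, " has fewer than 2 observed levels")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(died_30d ~ age_band + sbp_band + hr_band + diagnosis,
               family = stats::binomial(), data = cc,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic fit did not converge; check factors: ",
         paste(names(which(abs(stats::coef(fit)) > 15)), collapse = ", "))
  if (sep_warn)
    warning("possible separation: ",
            paste(names(which(abs(stats::coef(fit)) > 15)), collapse = ", "))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  cs <- c_statistic(stats::fitted(fit), cc$died_30d)
  out <- list(intercept = unname(co[1]), coefficients = co[-1], se = se,
              c_statistic = cs, band_edges = band_edges,
              n_fit = nrow(cc), fit = fit)
  class(out) <- "risk_model"
  out
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Case-mix logistic model on %d complete-case patients\n",
              x$n_fit))
  cat(sprintf("  c-statistic %.3f (95%% CI %.3f-%.3f)\n",
              x$c_statistic$estimate, x$c_statistic$ci[1],
              x$c_statistic$ci[2]))
  tab <- data.frame(log_odds = round(x$coefficients, 3),
                    odds_ratio = round(exp(x$coefficients), 2))
  print(tab)
  invisible(x)
}

#' Concordance statistic (area under the ROC curve)
#'
#' The proportion of (death, survivor) pairs in which the death received the
#' higher predicted probability, ties counted one half; computed via the
#' rank-sum identity. The confidence interval uses the Hanley-McNeil normal
#' approximation for the AUC standard error.
#'
#' @param predicted Predicted probabilities.
#' @param outcomes Binary outcomes (1 = death).
#' @param level Confidence level, default 0.95.
#' @return List with `estimate`, `se`, `ci`.
#' @export
c_statistic <- function(predicted, outcomes, level = 0.95) {
  stopifnot(length(predicted) == length(outcomes))
  keep <- !is.na(outcomes) & !is.na(predicted)
  predicted <- predicted[keep]; outcomes <- outcomes[keep]
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(predicted)
  auc <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = auc, se = se,
       ci = c(max(0, auc - z * se), min(1, auc + z * se)))
}

#' Per-hospital observed and expected deaths
#'
#' Sums each retained hospital's observed 30-day deaths (O) and its patients'
#' model-predicted death probabilities (E). Patients with missing death
#' status contribute to neither sum (complete-case).
#'
#' @param patients Filtered patient data.frame.
#' @param model A fitted [fit_risk_model()].
#' @return data.frame of class `hospital_summary` with columns
#'   `hospital_id`, `n_admissions` (valid 30-day status), `observed`,
#'   `expected`.
#' @export
expected_deaths <- function(patients, model) {
  stopifnot(inherits(model, "risk_model"))
  patients <- band_patients(patients, model$band_edges)
  cc <- patients[!is.na(patients$died_30d), , drop = FALSE]
  ids <- sort(unique(patients$hospital_id))
  if (!all(ids %in% cc$hospital_id))
    stop("hospital(s) with zero valid-status patients: ",
         paste(setdiff(ids, unique(cc$hospital_id)), collapse = ", "))
  p <- stats::predict(model$fit, newdata = cc, type = "response")
  agg <- function(x) as.vector(tapply(x, factor(cc$hospital_id, levels = ids),
                                      sum))
  out <- data.frame(hospital_id = ids,
                    n_admissions = as.vector(table(
                      factor(cc$hospital_id, levels = ids))),
                    observed = agg(cc$died_30d),
                    expected = agg(p))
  class(out) <- c("hospital_summary", "data.frame")
  out
}
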