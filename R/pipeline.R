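#' End-to-end run configuration
#'
#' Bundles every stage's configuration: cohort generation (or a path to an
#' existing cohort file), exclusion rules, model and MCMC settings, and
#' profiling thresholds.
#'
#' @param cohort A [cohort_config()] or a path to a cohort file written by
#'   [write_cohort()].
#' @param exclusions An [exclusion_rules()].
#' @param fixed_spec,hier_spec [model_spec()] objects for the two models.
#' @param mcmc An [mcmc_config()].
#' @param profiling A [profiling_config()]; its `mu30` is replaced by the
#'   analysed cohort's overall 30-day rate unless `mu30_override` is set.
#' @param mu30_override Optional overall rate in percent (e.g. 10.2) used
#'   instead of the cohort's realised rate.
#' @param output_dir Directory for artifacts; created if missing. `NULL`
#'   keeps everything in memory.
#' @param save_draws Write the (large) long-format draws files.
#' @param seed Optional master seed; when given it re-seeds the cohort
#'   (`seed`) and MCMC (`seed + 1`) configurations.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       exclusions = exclusion_rules(),
                       fixed_spec = model_spec("fixed"),
                       hier_spec = model_spec("hierarchical"),
                       mcmc = mcmc_config(),
                       profiling = profiling_config(),
                       mu30_override = NULL,
                       output_dir = NULL,
                       save_draws = FALSE,
                       seed = NULL) {
  if (!is.null(seed)) {
    if (inherits(cohort, "cohort_config")) cohort$seed <- as.integer(seed)
    mcmc$seed <- as.integer(seed) + 1L
  }
  out <- list(cohort = cohort, exclusions = exclusions,
              fixed_spec = fixed_spec, hier_spec = hier_spec,
              mcmc = mcmc, profiling = profiling,
              mu30_override = mu30_override, output_dir = output_dir,
              save_draws = save_draws)
  class(out) <- "run_config"
  out
}

# rolling polynomial hash of the deparsed config; stable across runs of the
# same config (a fingerprint, not a cryptographic digest)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full profiling pipeline
#'
#' Stages: generate (or load) the cohort; apply exclusions; band covariates
#' and fit the case-mix logistic model; sum observed/expected deaths per
#' hospital; sample fixed and hierarchical posteriors; profile hospitals
#' under both classification rules; compute all six pairwise agreements and
#' Gelman-Rubin diagnostics; write delimited-text artifacts and a manifest.
#' Any stage failure aborts with the stage name; artifacts written so far
#' are preserved.
#'
#' @param config A [run_config()].
#' @return List of class `profiling_run`: `cohort`, `exclusion_report`,
#'   `risk_model`, `summaries`, `draws` (fixed, hierarchical), `profiles`
#'   (fixed, hierarchical), `labels` (four methods), `agreement`,
#'   `convergence`, `mu30`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  emit <- function(writer, obj, name) {
    if (!is.null(dir)) writer(obj, file.path(dir, name))
  }
  stage <- "generate"
  res <- tryCatch({
    cohort <- if (inherits(config$cohort, "cohort_config")) {
      generate_cohort(config$cohort)
    } else read_cohort(config$cohort)
    .stage_log(stage, "%d patients in %d hospitals",
               nrow(cohort$patients),
               length(unique(cohort$patients$hospital_id)))
    if (inherits(config$cohort, "cohort_config"))
      emit(write_cohort, cohort, "cohort.tsv")

    stage <- "adjust"
    excl <- apply_exclusions(cohort$patients, config$exclusions)
    edges <- derive_bands(excl$patients)
    model <- fit_risk_model(excl$patients, edges)
    summaries <- expected_deaths(excl$patients, model)
    .stage_log(stage, "%d patients retained, %d hospitals, c = %.3f",
               nrow(excl$patients), nrow(summaries),
               model$c_statistic$estimate)
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         excl$report, "exclusion_report.tsv")
    emit(write_summaries, summaries, "hospital_summaries.tsv")

    mu30 <- config$mu30_override %||%
      (100 * mean(excl$patients$died_30d, na.rm = TRUE))
    pcfg <- config$profiling
    pcfg$mu30 <- mu30

    stage <- "fit"
    draws_f <- fit_fixed_model(summaries, config$fixed_spec, config$mcmc)
    draws_h <- fit_hierarchical_model(summaries, config$hier_spec,
                                      config$mcmc)
    conv <- rbind(
      cbind(model = "fixed", gelman_rubin(draws_f)),
      cbind(model = "hierarchical", gelman_rubin(draws_h)))
    .stage_log(stage, "%d draws kept per model, max r_hat = %.3f",
               nrow(draws_f$theta), max(conv$r_hat))
    if (config$save_draws) {
      emit(write_draws, draws_f, "draws_fixed.tsv")
      emit(write_draws, draws_h, "draws_hierarchical.tsv")
    }
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         conv, "convergence.tsv")

    stage <- "profile"
    prof_f <- profile_hospitals(summaries, draws_f, pcfg)
    prof_h <- profile_hospitals(summaries, draws_h, pcfg)
    labels <- list(fixed_ramr = prof_f$ramr_label,
                   fixed_rank = prof_f$rank_label,
                   hier_ramr = prof_h$ramr_label,
                   hier_rank = prof_h$rank_label)
    .stage_log(stage, "outliers: fixed ramr %d, fixed rank %d, hier ramr %d, hier rank %d",
               sum(labels$fixed_ramr != "normal"),
               sum(labels$fixed_rank != "normal"),
               sum(labels$hier_ramr != "normal"),
               sum(labels$hier_rank != "normal"))
    emit(write_profiles, prof_f, "profiles_fixed.tsv")
    emit(write_profiles, prof_h, "profiles_hierarchical.tsv")
    scatter <- data.frame(hospital_id = summaries$hospital_id,
                          ramr_median_fixed = prof_f$ramr_median,
                          ramr_median_hier = prof_h$ramr_median,
                          rank_median_fixed = prof_f$rank_median,
                          rank_median_hier = prof_h$rank_median)
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         scatter, "scatter_fixed_vs_hier.tsv")

    stage <- "agree"
    agreement <- pairwise_comparisons(labels)
    agree_tab <- data.frame(
      pair = names(agreement),
      kappa = vapply(agreement, function(a) a$agreement$kappa, 1),
      weighted_agreement = vapply(agreement,
                                  function(a) a$agreement$weighted_agreement,
                                  1),
      strength = vapply(agreement, function(a) a$agreement$strength, ""))
    emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE),
         agree_tab, "agreement.tsv")
    kk <- agree_tab$kappa[!is.na(agree_tab$kappa)]
    if (length(kk))
      .stage_log(stage, "kappa range %.2f-%.2f", min(kk), max(kk))
    else .stage_log(stage, "all pairwise kappas undefined")

    manifest <- list(
      config_hash = .config_hash(config),
      cohort_seed = if (inherits(config$cohort, "cohort_config"))
        config$cohort$seed else NA_integer_,
      mcmc_seed = config$mcmc$seed,
      n_patients_input = nrow(cohort$patients),
      n_patients_retained = nrow(excl$patients),
      n_hospitals = nrow(summaries),
      draws_per_model = nrow(draws_f$theta),
      mu30 = mu30,
      delta = pcfg$delta,
      sigma_prior = config$hier_spec$sigma_prior)
    if (!is.null(dir)) {
      dcf <- as.data.frame(lapply(manifest, as.character))
      write.dcf(dcf, file.path(dir, "manifest.dcf"))
    }

    list(cohort = cohort, exclusion_report = excl$report,
         risk_model = model, summaries = summaries,
         draws = list(fixed = draws_f, hierarchical = draws_h),
         profiles = list(fixed = prof_f, hierarchical = prof_h),
         labels = labels, agreement = agreement, convergence = conv,
         mu30 = mu30, profiling = pcfg, config = config,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(res) <- "profiling_run"
  res
}

#' Sensitivity re-run
#'
#' Re-profiles a completed run under overridden settings and tabulates label
#' changes by hospital and method. Supported overrides: `delta` (RAMR
#' threshold, e.g. 0.15) and `sigma_prior` (`"gamma"` or `"uniform"`; a
#' prior change triggers a hierarchical refit with the same MCMC
#' configuration).
#'
#' @param run A `profiling_run` from [run_pipeline()].
#' @param overrides Named list; unknown keys are an error.
#' @return List of class `sensitivity_report`: `changes` (one row per
#'   hospital x method with base and new labels), `n_changed`, `labels`,
#'   and the overridden `profiling` config.
#' @export
sensitivity_rerun <- function(run, overrides = list()) {
  stopifnot(inherits(run, "profiling_run"))
  unknown <- setdiff(names(overrides), c("delta", "sigma_prior"))
  if (length(unknown))
    stop("unknown override key(s): ", paste(unknown, collapse = ", "))
  pcfg <- run$profiling
  if (!is.null(overrides$delta)) pcfg$delta <- overrides$delta
  draws_h <- run$draws$hierarchical
  if (!is.null(overrides$sigma_prior) &&
      !identical(overrides$sigma_prior, run$config$hier_spec$sigma_prior)) {
    spec <- run$config$hier_spec
    spec$sigma_prior <- overrides$sigma_prior
    draws_h <- fit_hierarchical_model(run$summaries, spec, run$config$mcmc)
  }
  prof_f <- profile_hospitals(run$summaries, run$draws$fixed, pcfg)
  prof_h <- profile_hospitals(run$summaries, draws_h, pcfg)
  labels <- list(fixed_ramr = prof_f$ramr_label,
                 fixed_rank = prof_f$rank_label,
                 hier_ramr = prof_h$ramr_label,
                 hier_rank = prof_h$rank_label)
  changes <- do.call(rbind, lapply(names(labels), function(m) {
    data.frame(hospital_id = run$summaries$hospital_id, method = m,
               base = run$labels[[m]], new = labels[[m]])
  }))
  changes$changed <- changes$base != changes$new
  out <- list(changes = changes, n_changed = sum(changes$changed),
              labels = labels, profiling = pcfg, overrides = overrides)
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.profiling_run <- function(x, ...) {
  cat(sprintf("Profiling run: %d hospitals, mu30 = %.2f%%, delta = %.2f\n",
              nrow(x$summaries), x$mu30, x$profiling$delta))
  outl <- vapply(x$labels, function(l) sum(l != "normal"), 1L)
  cat("  outliers:", paste(names(outl), outl, sep = " = ",
                           collapse = ", "), "\n")
  cat(sprintf("  max r_hat = %.3f\n", max(x$convergence$r_hat)))
  invisible(x)
}
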