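#' Write and read cohort artifacts
#'
#' The cohort is a headered tab-delimited file, one row per admission; the
#' ground truth (per-hospital theta) goes in a `*_truth.tsv` sidecar in the
#' same directory. Both carry the generating seed as a `# seed:` comment
#' line.
#'
#' @param cohort An `acs_cohort` from [generate_cohort()].
#' @param path Output path of the cohort file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "acs_cohort"))
  .write_commented_tsv(cohort$patients, path,
                       sprintf("# seed: %d", cohort$truth$seed))
  truth <- data.frame(hospital_id = seq_along(cohort$truth$theta_true),
                      theta_true = cohort$truth$theta_true)
  .write_commented_tsv(truth, .truth_path(path),
                       sprintf("# seed: %d", cohort$truth$seed))
  invisible(path)
}

.truth_path <- function(path) {
  sub("(\\.[^.]+)?$", "_truth.tsv", path)
}

.write_commented_tsv <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_commented_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  patients <- .read_commented_tsv(path)
  truth <- NULL
  tp <- .truth_path(path)
  if (file.exists(tp)) {
    td <- .read_commented_tsv(tp)
    truth <- list(theta_true = td$theta_true)
  }
  out <- list(patients = patients, truth = truth)
  class(out) <- "acs_cohort"
  out
}

#' Write hospital summaries as delimited text
#' @param summaries A `hospital_summary` data.frame.
#' @param path Output path.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  class(out) <- c("hospital_summary", "data.frame")
  out
}

#' Persist posterior draws in long columnar text
#'
#' One row per (parameter, chain, iteration, value). At production MCMC
#' scale this file is large; the pipeline writes it only on request.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output path.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  n_h <- ncol(draws$theta)
  pars <- paste0("theta[", draws$hospital_id, "]")
  long <- data.frame(
    parameter = rep(pars, each = nrow(draws$theta)),
    chain = rep(draws$chain, times = n_h),
    iteration = rep(draws$iteration, times = n_h),
    value = as.vector(draws$theta))
  if (!is.null(draws$mu0)) {
    hyp <- data.frame(
      parameter = rep(c("mu0", "sigma0_sq"), each = length(draws$mu0)),
      chain = rep(draws$chain, 2),
      iteration = rep(draws$iteration, 2),
      value = c(draws$mu0, draws$sigma0_sq))
    long <- rbind(long, hyp)
  }
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  th <- long[startsWith(long$parameter, "theta["), ]
  ids <- unique(sub("^theta\\[(.*)\\]$", "\\1", th$parameter))
  theta <- do.call(cbind, lapply(paste0("theta[", ids, "]"), function(p)
    th$value[th$parameter == p]))
  first <- th$parameter == paste0("theta[", ids[1], "]")
  out <- list(theta = theta,
              mu0 = if (any(long$parameter == "mu0"))
                long$value[long$parameter == "mu0"],
              sigma0_sq = if (any(long$parameter == "sigma0_sq"))
                long$value[long$parameter == "sigma0_sq"],
              chain = th$chain[first], iteration = th$iteration[first],
              hospital_id = utils::type.convert(ids, as.is = TRUE),
              model = if (any(long$parameter == "mu0")) "hierarchical"
              else "fixed",
              spec = NULL, mcmc = NULL)
  class(out) <- "posterior_draws"
  out
}

#' Write hospital profiles (league-table layout plus labels)
#' @param profiles A `hospital_profiles` data.frame.
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
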