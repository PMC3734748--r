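#' Published profiling benchmarks
#'
#' Two small reference tables from a published national-audit analysis of
#' 30-day ACS mortality across 128 English and Welsh hospitals, shipped as
#' plain text under `inst/extdata/` and used as worked-example oracles:
#'
#' * `benchmark_hospitals()` — the five best and five worst hospitals by
#'   risk-adjusted mortality rate, with admission counts (valid 30-day
#'   status), observed deaths O, case-mix expected deaths E, and the printed
#'   RAMR (percent) with its 95% credible interval. Note: the printed RAMR
#'   was computed from unrounded E, so recomputing 10.2 x O/E from the
#'   printed two-decimal E can differ by up to ~0.03 for the smallest
#'   hospitals, and hospital 1's printed 4.54 does not match the arithmetic
#'   at all (4.44; a known typo).
#' * `benchmark_crosstabs()` — the six pairwise 3x3 cross-classifications of
#'   outlier labels (low/normal/high) between the four profiling methods,
#'   with the published linear-weighted kappa for each pair.
#'
#' @return A data.frame (`benchmark_hospitals`) or a named list of 3x3
#'   `cross_tab` matrices with a `kappa_printed` attribute on each
#'   (`benchmark_crosstabs`).
#' @export
benchmark_hospitals <- function() {
  utils::read.csv(system.file("extdata", "benchmark_hospitals.csv",
                              package = "hospprofile"))
}

#' @rdname benchmark_hospitals
#' @export
benchmark_crosstabs <- function() {
  raw <- utils::read.csv(system.file("extdata", "benchmark_crosstabs.csv",
                                     package = "hospprofile"))
  keys <- unique(raw[, c("method_a", "method_b")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    blk <- raw[raw$method_a == keys$method_a[i] &
                 raw$method_b == keys$method_b[i], ]
    blk <- blk[match(.label_levels, blk$row_label), ]
    m <- as.matrix(blk[, c("low", "normal", "high")])
    dimnames(m) <- list(.label_levels, .label_levels)
    m <- matrix(as.integer(m), 3, 3,
                dimnames = list(.label_levels, .label_levels))
    class(m) <- c("cross_tab", class(m))
    attr(m, "kappa_printed") <- blk$kappa_printed[1]
    m
  })
  names(out) <- paste(keys$method_a, keys$method_b, sep = ".vs.")
  out
}
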