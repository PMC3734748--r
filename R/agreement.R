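#' Cross-tabulate two methods' outlier labels
#'
#' @param labels_a,labels_b Equal-length label vectors over
#'   `low`/`normal`/`high` (rows = method A, columns = method B).
#' @return 3x3 integer matrix of class `cross_tab`.
#' @export
cross_tabulate <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  to_f <- function(x) {
    f <- factor(as.character(x), levels = .label_levels)
    if (anyNA(f)) stop("unknown label: ",
                       paste(setdiff(unique(as.character(x)),
                                     .label_levels), collapse = ", "))
    f
  }
  tab <- table(to_f(labels_a), to_f(labels_b))
  out <- matrix(as.integer(tab), 3, 3,
                dimnames = list(.label_levels, .label_levels))
  class(out) <- c("cross_tab", class(out))
  out
}

.kappa_weights <- function(k, scheme) {
  i <- matrix(seq_len(k), k, k)
  j <- t(i)
  switch(scheme,
         linear = 1 - abs(i - j) / (k - 1),
         quadratic = 1 - (i - j)^2 / (k - 1)^2,
         unweighted = (i == j) * 1)
}

#' Weighted kappa agreement statistic
#'
#' Chance-corrected agreement for ordered categories. With weights `w_ij`
#' (linear: `1 - |i - j|/(k - 1)`), observed weighted agreement `Po_w` and
#' expected weighted agreement `Pe_w` from the products of the marginals,
#' `kappa = (Po_w - Pe_w) / (1 - Pe_w)`. Strength is annotated by the common
#' convention: marginal below 0.4, good 0.4-0.75, excellent above 0.75.
#'
#' @param tab A [cross_tabulate()] 3x3 table (or any square count matrix
#'   over ordered categories).
#' @param weight_scheme `"linear"` (default), `"quadratic"` or
#'   `"unweighted"`.
#' @return List of class `agreement_result`: `observed_agreement`
#'   (unweighted), `weighted_agreement`, `expected_weighted_agreement`,
#'   `kappa`, `weight_scheme`, `strength`, `n`.
#' @export
weighted_kappa <- function(tab, weight_scheme = c("linear", "quadratic",
                                                  "unweighted")) {
  weight_scheme <- match.arg(weight_scheme)
  tab <- unclass(tab)
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty table")
  w <- .kappa_weights(nrow(tab), weight_scheme)
  po_w <- sum(w * tab) / n
  pe_w <- sum(w * outer(rowSums(tab), colSums(tab))) / n^2
  if (1 - pe_w < 1e-12) {
    # e.g. both raters label every unit "normal": chance agreement is
    # already 1 and kappa carries no information
    warning("degenerate marginals: expected agreement is 1, kappa undefined")
    kappa <- NA_real_
  } else {
    kappa <- (po_w - pe_w) / (1 - pe_w)
  }
  out <- list(observed_agreement = sum(diag(tab)) / n,
              weighted_agreement = po_w,
              expected_weighted_agreement = pe_w,
              kappa = kappa, weight_scheme = weight_scheme,
              strength = if (is.na(kappa)) "undefined"
              else kappa_strength(kappa), n = n)
  class(out) <- "agreement_result"
  out
}

#' Qualitative kappa banding
#'
#' @param kappa Kappa value.
#' @return `"marginal"` (< 0.4), `"good"` (0.4-0.75) or `"excellent"`
#'   (> 0.75).
#' @export
kappa_strength <- function(kappa) {
  ifelse(kappa > 0.75, "excellent", ifelse(kappa >= 0.4, "good", "marginal"))
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Weighted kappa (%s weights, n = %d)\n  observed agreement %.3f, weighted %.3f, expected %.3f\n  kappa = %.3f (%s agreement)\n",
    x$weight_scheme, x$n, x$observed_agreement, x$weighted_agreement,
    x$expected_weighted_agreement, x$kappa, x$strength))
  invisible(x)
}

#' All pairwise agreement comparisons between profiling methods
#'
#' With two models (fixed, hierarchical) and two classification rules (RAMR
#' exceedance, rank interval) there are four methods and six unordered
#' pairs.
#'
#' @param labels Named list of four label vectors over the same hospitals,
#'   conventionally `fixed_ramr`, `fixed_rank`, `hier_ramr`, `hier_rank`.
#' @param weight_scheme Passed to [weighted_kappa()].
#' @return List of class `pairwise_agreement`; one element per pair with
#'   `pair`, `tab` and `agreement`.
#' @export
pairwise_comparisons <- function(labels, weight_scheme = "linear") {
  stopifnot(is.list(labels), length(labels) >= 2,
            !is.null(names(labels)))
  len <- vapply(labels, length, 1L)
  if (length(unique(len)) != 1)
    stop("all label vectors must cover the same hospitals")
  nms <- names(labels)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    tab <- cross_tabulate(labels[[pr[1]]], labels[[pr[2]]])
    list(pair = pr, tab = tab,
         agreement = weighted_kappa(tab, weight_scheme))
  })
  names(out) <- vapply(pairs, paste, "", collapse = ".vs.")
  class(out) <- "pairwise_agreement"
  out
}

#' @export
print.pairwise_agreement <- function(x, ...) {
  for (nm in names(x)) {
    a <- x[[nm]]$agreement
    cat(sprintf("%-28s kappa %.2f (%s), weighted agreement %.1f%%\n",
                nm, a$kappa, a$strength, 100 * a$weighted_agreement))
  }
  invisible(x)
}
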