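#' Center a quantitative phenotype
#'
#' Subtracts the sample mean from a vector of raw trait values. All kernel
#' statistics in this package assume the phenotype vector `y` satisfies
#' `sum(y) == 0`; centering is therefore performed once, up front, and the
#' centered vector is what every downstream function receives. Raw
#' phenotypes are never used directly in a statistic.
#'
#' @param raw_values Numeric vector of trait values, one per individual
#'   (e.g. serum urate in µg/dL). Length at least 2, all values finite.
#'   Names, if present, are preserved.
#'
#' @return A numeric vector of class `gvd_phenotype`: the input minus its
#'   mean, with mean zero to within 1e-12.
#'
#' @examples
#' center_phenotype(c(5, 7, 9))
#' @export
center_phenotype <- function(raw_values) {
  if (!is.numeric(raw_values)) {
    abort("`raw_values` must be numeric.")
  }
  if (length(raw_values) < 2L) {
    abort("`raw_values` must contain at least 2 individuals.")
  }
  if (!all(is.finite(raw_values))) {
    bad <- which(!is.finite(raw_values))[1L]
    abort(sprintf("`raw_values` contains a non-finite value at position %d.", bad))
  }
  y <- as.numeric(raw_values) - mean(as.numeric(raw_values))
  names(y) <- names(raw_values)
  structure(y, class = c("gvd_phenotype", "numeric"))
}

# Validate that y is usable as a centered phenotype of length n.
check_phenotype <- function(y, n = NULL) {
  if (!is.numeric(y) || length(y) < 2L || !all(is.finite(y))) {
    abort("`y` must be a finite numeric vector of length >= 2.")
  }
  if (!is.null(n) && length(y) != n) {
    abort(sprintf(
      "phenotype length (%d) does not match genotype sample size (%d).",
      length(y), n
    ))
  }
  if (abs(mean(y)) > 1e-8 * max(1, max(abs(y)))) {
    abort("`y` is not centered; run center_phenotype() first.")
  }
  invisible(y)
}

#' @export
print.gvd_phenotype <- function(x, ...) {
  cat(sprintf("<centered phenotype: n = %d, sd = %.4g>\n", length(x), sd(x)))
  print(unclass(x), ...)
  invisible(x)
}
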