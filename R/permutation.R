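## Permutation test for the aggregate kernel statistic.
##
## The phenotype labels are resampled without replacement; genotype vectors
## are never touched (permuting y is equivalent to permuting every site's
## indicator vectors, and cheaper). Each permuted statistic is recomputed
## through the same O(n) inner-product path as the observed one, so one
## permutation costs O(n * l).

#' Permutation test for a kernel statistic
#'
#' Estimates the p-value of the aggregate statistic `S` by resampling the
#' centered phenotype without replacement `B` times and recomputing `S`
#' for each permutation via the O(n) path. The estimator is the standard
#' add-one permutation p-value
#' `p = (count_ge + 1) / (B + 1)`, where `count_ge` counts permuted
#' statistics greater than or equal to the observed one (ties inclusive);
#' it is valid under the permutation null and can never be 0.
#'
#' Permutations are drawn sequentially from R's Mersenne-Twister stream
#' seeded with `seed`, so identical inputs and seed give a bit-identical
#' result; the seed used is always recorded in the output.
#'
#' @inheritParams kernel_statistic
#' @param B Number of permutations (>= 1).
#' @param seed Integer RNG seed; if `NULL` one is drawn from the current
#'   RNG stream and recorded.
#' @param keep_null If `TRUE` (default) the `B` permuted statistics are
#'   kept in the result (used by [autoplot()] and for auditing).
#' @param chunk_size Permutations are processed in blocks of this size so
#'   the permuted-phenotype matrix stays small; has no effect on results.
#' @return An object of class `gvd_perm` with elements `kernel`,
#'   `observed_S`, `B`, `count_ge`, `p_value`, `seed`, `n`, `n_sites`, and
#'   `null_S` (if kept). Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' y <- center_phenotype(rnorm(20))
#' sites <- simulate_genotypes(20, c(0.3, 0.4), seed = 1)
#' permutation_test(y, sites, kernel = "GRM", B = 99, seed = 7)
#' @export
permutation_test <- function(y, sites, kernel = c("GRM", "IBS"),
                             weights = weight_scheme("uniform"),
                             B = 999L, seed = NULL, keep_null = TRUE,
                             chunk_size = 1024L) {
  kernel <- match.arg(kernel)
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 1) {
    abort("`B` must be a single integer >= 1.")
  }
  B <- as.integer(B)
  check_sites(sites, n = length(y))
  if (nrow(sites) == 0L) abort("`sites` must contain at least one site.")
  check_phenotype(y)
  if (is.null(seed)) seed <- draw_seed()

  w <- resolve_weights(sites, weights)
  Bm <- site_matrix(sites, "b")
  Cm <- site_matrix(sites, "c")
  n <- length(y)
  stat_fun <- if (kernel == "GRM") q_from_inner else r_from_inner

  agg <- function(Y) {
    # Y: n x m matrix of (permuted) phenotypes -> length-m vector of S
    yb <- crossprod(Bm, Y)
    yc <- crossprod(Cm, Y)
    as.numeric(crossprod(stat_fun(yb, yc), w))
  }

  observed_S <- agg(matrix(as.numeric(y), ncol = 1L))

  null_S <- with_seed(seed, {
    out <- numeric(B)
    done <- 0L
    while (done < B) {
      m <- min(chunk_size, B - done)
      Y <- vapply(seq_len(m), function(j) y[sample.int(n)], numeric(n))
      out[done + seq_len(m)] <- agg(Y)
      done <- done + m
    }
    out
  })

  count_ge <- sum(null_S >= observed_S)
  structure(
    list(kernel = kernel, observed_S = observed_S, B = B,
         count_ge = count_ge, p_value = (count_ge + 1) / (B + 1),
         seed = as.integer(seed), n = n, n_sites = nrow(sites),
         null_S = if (keep_null) null_S else NULL),
    class = "gvd_perm"
  )
}

#' Decide a permutation test at level alpha
#'
#' Rejects the null hypothesis when the permutation p-value is at most
#' `alpha` (boundary inclusive). `alpha = 1` is permitted as a degenerate
#' always-reject level for calibration exercises.
#'
#' @param result A `gvd_perm` object.
#' @param alpha Significance level in `(0, 1]`.
#' @return `TRUE` or `FALSE`.
#' @export
reject_null <- function(result, alpha) {
  if (!inherits(result, "gvd_perm")) abort("`result` must be a gvd_perm object.")
  stopifnot_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  result$p_value <= alpha
}

#' @export
print.gvd_perm <- function(x, ...) {
  cat(sprintf(
    "%s kernel permutation test\n  S = %.6g, B = %d, count_ge = %d\n  p = %.6g  (seed %d, n = %d, sites = %d)\n",
    x$kernel, x$observed_S, x$B, x$count_ge, x$p_value, x$seed, x$n, x$n_sites
  ))
  invisible(x)
}

#' @rdname permutation_test
#' @param x,object A `gvd_perm` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.gvd_perm <- function(x, ...) {
  tibble(kernel = x$kernel, S = x$observed_S, B = x$B,
         count_ge = x$count_ge, p_value = x$p_value,
         seed = x$seed, n = x$n, n_sites = x$n_sites)
}

#' @rdname permutation_test
#' @exportS3Method generics::tidy
#' @export
tidy.gvd_perm <- function(x, ...) glance.gvd_perm(x)

#' @rdname permutation_test
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.gvd_perm <- function(object, ...) {
  if (is.null(object$null_S)) {
    abort("result was built with keep_null = FALSE; nothing to plot.")
  }
  d <- tibble(S = object$null_S)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$S)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(xintercept = object$observed_S, linetype = "dashed") +
    ggplot2::labs(
      x = "permuted statistic S", y = "count",
      title = sprintf("%s kernel permutation null (B = %d), p = %.3g",
                      object$kernel, object$B, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
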