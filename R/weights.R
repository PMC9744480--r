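#' Per-site weight schemes
#'
#' SKAT-style statistics aggregate per-site quadratic forms as
#' `S = sum_k w_k Q_k` (GRM) or `S = sum_k w_k R_k` (IBS). Three schemes are
#' supported: `"uniform"` (all weights 1, the default, matching an
#' unweighted analysis), `"beta"` (the Beta density evaluated at each
#' site's minor-allele frequency; `shape1 = 1, shape2 = 25` is the
#' conventional rare-variant up-weighting but is not applied silently —
#' shapes must be given), and `"custom"` (explicit nonnegative weights, one
#' per site).
#'
#' @param kind One of `"uniform"`, `"beta"`, `"custom"`.
#' @param shape1,shape2 Beta density shapes (required for `kind = "beta"`).
#' @param weights Numeric vector of explicit weights (for `kind = "custom"`).
#' @return An object of class `gvd_weights`.
#' @examples
#' weight_scheme("beta", shape1 = 1, shape2 = 25)
#' @export
weight_scheme <- function(kind = c("uniform", "beta", "custom"),
                          shape1 = NULL, shape2 = NULL, weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "beta") {
    stopifnot_scalar_number(shape1, "shape1")
    stopifnot_scalar_number(shape2, "shape2")
    if (shape1 <= 0 || shape2 <= 0) abort("Beta shapes must be positive.")
  }
  if (kind == "custom") {
    if (is.null(weights) || !is.numeric(weights)) {
      abort("`weights` must be supplied for a custom scheme.")
    }
    if (any(!is.finite(weights)) || any(weights < 0)) {
      abort("custom weights must be finite and nonnegative.")
    }
  }
  structure(
    list(kind = kind, shape1 = shape1, shape2 = shape2, weights = weights),
    class = "gvd_weights"
  )
}

#' Resolve a weight scheme against a site table
#'
#' @param sites A `gvd_sites` tibble (nonempty).
#' @param scheme A [weight_scheme()] object; a bare string such as
#'   `"uniform"` is promoted for convenience.
#' @return Numeric vector of nonnegative weights, one per site. For the
#'   Beta scheme the density is evaluated at the minor-allele frequency
#'   `min(p, 1 - p)`.
#' @export
resolve_weights <- function(sites, scheme = weight_scheme("uniform")) {
  check_sites(sites)
  if (nrow(sites) == 0L) abort("`sites` must contain at least one site.")
  if (is.character(scheme)) scheme <- weight_scheme(scheme)
  if (!inherits(scheme, "gvd_weights")) {
    abort("`scheme` must be a weight_scheme() object.")
  }
  w <- switch(scheme$kind,
    uniform = rep(1, nrow(sites)),
    beta = {
      maf <- pmin(sites$p, 1 - sites$p)
      dbeta(maf, scheme$shape1, scheme$shape2)
    },
    custom = {
      if (length(scheme$weights) != nrow(sites)) {
        abort(sprintf("custom scheme has %d weights for %d sites.",
                      length(scheme$weights), nrow(sites)))
      }
      as.numeric(scheme$weights)
    }
  )
  if (any(!is.finite(w)) || any(w < 0)) {
    abort("resolved weights must be finite and nonnegative.")
  }
  w
}

#' @export
print.gvd_weights <- function(x, ...) {
  cat(switch(x$kind,
    uniform = "<weights: uniform>\n",
    beta = sprintf("<weights: Beta(%g, %g) density at MAF>\n", x$shape1, x$shape2),
    custom = sprintf("<weights: custom, %d value(s)>\n", length(x$weights))
  ))
  invisible(x)
}
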