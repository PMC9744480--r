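## O(n) kernel statistics.
##
## For a centered phenotype y and a site with indicator vectors a, b, c:
##
##   Q = (y'b + 2 y'c)^2          (GRM quadratic form  y' X y = y' g g' y)
##   R = 2 (y'a)^2 + 2 (y'c)^2    (IBS quadratic form  y' IBS y)
##
## with y'a = -(y'b + y'c), which holds exactly because a + b + c = 1 and
## y'1 = 0. Each statistic is a couple of inner products: one pass over the
## individuals, no n-by-n matrix is ever formed.

# Extract the n x l numeric matrix of one indicator column across sites.
site_matrix <- function(sites, which = c("b", "c", "a", "g")) {
  which <- match.arg(which)
  n <- sites$n[1L]
  matrix(as.numeric(unlist(sites[[which]], use.names = FALSE)),
         nrow = n, ncol = nrow(sites))
}

# Vectorized inner products y'b and y'c for every site; the workhorse of
# both the per-site statistics and the permutation engine.
site_inner_products <- function(y, sites) {
  Bm <- site_matrix(sites, "b")
  Cm <- site_matrix(sites, "c")
  list(yb = as.numeric(crossprod(Bm, y)), yc = as.numeric(crossprod(Cm, y)))
}

q_from_inner <- function(yb, yc) (yb + 2 * yc)^2
r_from_inner <- function(yb, yc) 2 * (yb + yc)^2 + 2 * yc^2

#' Per-site GRM statistic, computed in O(n)
#'
#' Computes `Q = (y'b + 2 y'c)^2` for each site, the quadratic form of the
#' centered phenotype against the site's genetic-relationship matrix
#' `X[i,j] = (g(i) - mu)(g(j) - mu)`, without constructing that matrix.
#' For centered `y` the mean term vanishes, so `y' X y = (y' g)^2`.
#'
#' @param y Centered phenotype vector (see [center_phenotype()]).
#' @param sites A `gvd_sites` tibble; sample size must match `length(y)`.
#' @return Numeric vector of nonnegative statistics, one per site.
#' @seealso [grm_matrix()] and [quadratic_form()] for the brute-force
#'   equivalent.
#' @examples
#' y <- center_phenotype(c(1, -1))
#' q_statistic(y, genotype_site(c("0/1", "0/0")))
#' @export
q_statistic <- function(y, sites) {
  check_sites(sites, n = length(y))
  check_phenotype(y)
  if (nrow(sites) == 0L) return(numeric())
  ip <- site_inner_products(y, sites)
  q_from_inner(ip$yb, ip$yc)
}

#' Per-site IBS statistic, computed in O(n)
#'
#' Computes `R = 2 (y'a)^2 + 2 (y'c)^2` for each site, the quadratic form
#' of the centered phenotype against the site's identity-by-state matrix
#' (shared-allele counts), without constructing that matrix. The
#' heterozygote rank-one terms `1 b' + b 1'` contribute nothing because
#' `y'1 = 0`, and `y'a` is obtained as `-(y'b + y'c)`.
#'
#' @inheritParams q_statistic
#' @return Numeric vector of nonnegative statistics, one per site.
#' @seealso [ibs_matrix()] and [quadratic_form()] for the brute-force
#'   equivalent.
#' @examples
#' y <- center_phenotype(c(1, -1))
#' r_statistic(y, genotype_site(c("0/1", "0/0")))
#' @export
r_statistic <- function(y, sites) {
  check_sites(sites, n = length(y))
  check_phenotype(y)
  if (nrow(sites) == 0L) return(numeric())
  ip <- site_inner_products(y, sites)
  r_from_inner(ip$yb, ip$yc)
}

#' Aggregate kernel statistic over a set of sites
#'
#' The multi-site SKAT-style statistic `S = sum_k w_k Q_k` (GRM kernel) or
#' `S = sum_k w_k R_k` (IBS kernel), with per-site statistics computed via
#' the O(n) inner-product path. Monomorphic sites contribute exactly 0.
#'
#' @inheritParams q_statistic
#' @param kernel `"GRM"` or `"IBS"`.
#' @param weights A [weight_scheme()] (or its name as a string).
#' @return An object of class `gvd_kernel` with elements `kernel`, `S`,
#'   `per_site` (tibble of per-site statistics, weights and contributions),
#'   `weights`, `n_sites` and `n`. Has [tidy()] and [glance()] methods.
#' @examples
#' y <- center_phenotype(c(1, -1))
#' sites <- genotype_sites(cbind(c("0/1", "0/0"), c("1/1", "0/0")))
#' kernel_statistic(y, sites, kernel = "GRM")
#' @export
kernel_statistic <- function(y, sites, kernel = c("GRM", "IBS"),
                             weights = weight_scheme("uniform")) {
  kernel <- match.arg(kernel)
  check_sites(sites, n = length(y))
  if (nrow(sites) == 0L) abort("`sites` must contain at least one site.")
  check_phenotype(y)
  w <- resolve_weights(sites, weights)
  ip <- site_inner_products(y, sites)
  stat <- if (kernel == "GRM") q_from_inner(ip$yb, ip$yc) else r_from_inner(ip$yb, ip$yc)
  per_site <- tibble(
    chrom = sites$chrom, pos = sites$pos, rsid = sites$rsid, p = sites$p,
    statistic = stat, weight = w, contribution = w * stat
  )
  structure(
    list(kernel = kernel, S = sum(per_site$contribution), per_site = per_site,
         weights = w, n_sites = nrow(sites), n = length(y)),
    class = "gvd_kernel"
  )
}

#' @export
print.gvd_kernel <- function(x, ...) {
  cat(sprintf("%s kernel statistic: S = %.6g  (n = %d, sites = %d)\n",
              x$kernel, x$S, x$n, x$n_sites))
  invisible(x)
}

#' @rdname kernel_statistic
#' @param x A `gvd_kernel` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.gvd_kernel <- function(x, ...) x$per_site

#' @rdname kernel_statistic
#' @exportS3Method generics::glance
#' @export
glance.gvd_kernel <- function(x, ...) {
  tibble(kernel = x$kernel, S = x$S, n = x$n, n_sites = x$n_sites)
}

#' @rdname kernel_statistic
#' @param object A `gvd_kernel` object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.gvd_kernel <- function(object, ...) {
  d <- object$per_site
  d$site <- factor(paste0(d$chrom, ":", d$pos), levels = paste0(d$chrom, ":", d$pos))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = expression(w[k] %.% statistic),
      title = sprintf("%s kernel: per-site contributions to S = %.4g",
                      object$kernel, object$S)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
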