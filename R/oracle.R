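## Brute-force kernel-matrix oracle.
##
## These functions build the explicit n x n per-site matrices and evaluate
## y'Ky with naive double loops. They are deliberately free of the
## algebraic shortcuts used by the O(n) path, so they serve as an
## independent ground truth in tests (and as a pedagogical export), not as
## a refactoring of the fast code.

#' Explicit per-site GRM
#'
#' Builds the n-by-n genetic-relationship matrix of one site,
#' `X[i,j] = (g(i) - mu)(g(j) - mu)`, entry by entry. Every row sums to
#' zero because the genotype values are mean-centered.
#'
#' @param site One row of a `gvd_sites` tibble.
#' @return A symmetric n-by-n numeric matrix.
#' @export
grm_matrix <- function(site) {
  check_sites(site)
  if (nrow(site) != 1L) abort("`site` must be a single site (one row).")
  g <- as.numeric(site$g[[1L]])
  mu <- site$mu
  n <- length(g)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- (g[i] - mu) * (g[j] - mu)
    }
  }
  K
}

#' Explicit per-site uncentered genotype cross-product matrix
#'
#' Builds `G[i,j] = g(i) g(j)`. For a centered phenotype,
#' `y' G y == y' X y` (the mean terms are annihilated by `y'1 = 0`), which
#' is the identity the O(n) GRM statistic rests on.
#'
#' @inheritParams grm_matrix
#' @return A symmetric n-by-n numeric matrix.
#' @export
g_matrix <- function(site) {
  check_sites(site)
  if (nrow(site) != 1L) abort("`site` must be a single site (one row).")
  g <- as.numeric(site$g[[1L]])
  n <- length(g)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- g[i] * g[j]
    }
  }
  K
}

#' Shared-allele count of a genotype pair
#'
#' The identity-by-state (IBS) value of two individuals at a biallelic
#' site: the number of alleles (0, 1 or 2) their genotypes share,
#' `2 a_i a_j + b_i + b_j + 2 c_i c_j` in indicator form. Symmetric in its
#' arguments. Vectorized over pairs.
#'
#' @param call_i,call_j Genotype-call strings.
#' @return Integer vector of shared-allele counts in `{0, 1, 2}`.
#' @examples
#' ibs_pair("0/1", "1/1")
#' @export
ibs_pair <- function(call_i, call_j) {
  gi <- genotype_value(call_i)
  gj <- genotype_value(call_j)
  ai <- as.integer(gi == 0L); bi <- as.integer(gi == 1L); ci <- as.integer(gi == 2L)
  aj <- as.integer(gj == 0L); bj <- as.integer(gj == 1L); cj <- as.integer(gj == 2L)
  2L * ai * aj + bi + bj + 2L * ci * cj
}

#' Explicit per-site IBS matrix
#'
#' Builds the n-by-n matrix of pairwise shared-allele counts, either by
#' pairwise lookup (`method = "pairwise"`, the default: [ibs_pair()] on
#' every pair) or from the rank-structured identity
#' `IBS = 2 a a' + 1 b' + b 1' + 2 c c'` (`method = "rank"`). The two
#' constructions agree entry for entry.
#'
#' @inheritParams grm_matrix
#' @param method `"pairwise"` or `"rank"`.
#' @return A symmetric integer-valued n-by-n matrix with diagonal 2.
#' @export
ibs_matrix <- function(site, method = c("pairwise", "rank")) {
  method <- match.arg(method)
  check_sites(site)
  if (nrow(site) != 1L) abort("`site` must be a single site (one row).")
  if (method == "pairwise") {
    calls <- site_calls(site)
    n <- length(calls)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        K[i, j] <- ibs_pair(calls[i], calls[j])
      }
    }
    K
  } else {
    a <- as.numeric(site$a[[1L]])
    b <- as.numeric(site$b[[1L]])
    c <- as.numeric(site$c[[1L]])
    one <- rep(1, length(a))
    2 * outer(a, a) + outer(one, b) + outer(b, one) + 2 * outer(c, c)
  }
}

#' Quadratic form y'Ky by direct summation
#'
#' Evaluates `sum_i sum_j y(i) K(i,j) y(j)` with an explicit O(n^2) double
#' loop — intentionally naive, so that it is an independent check of the
#' O(n) statistics rather than a rearrangement of them.
#'
#' @param y Numeric phenotype vector.
#' @param K An n-by-n numeric matrix.
#' @return A single number.
#' @examples
#' quadratic_form(c(1, -1), matrix(c(2, 1, 1, 2), 2))
#' @export
quadratic_form <- function(y, K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) abort("`K` must be a square matrix.")
  n <- length(y)
  if (nrow(K) != n) {
    abort(sprintf("dimension mismatch: length(y) = %d, K is %d x %d.",
                  n, nrow(K), ncol(K)))
  }
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- s + y[i] * K[i, j] * y[j]
    }
  }
  s
}

#' Export a kernel matrix as TSV
#'
#' Writes an n-by-n kernel matrix row-major with a header of individual
#' IDs, for inspection.
#'
#' @param K Square numeric matrix.
#' @param path Output file path.
#' @param ids Individual IDs (default `ind1..indn`).
#' @return `path`, invisibly.
#' @export
write_kernel_matrix <- function(K, path, ids = paste0("ind", seq_len(nrow(K)))) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) abort("`K` must be a square matrix.")
  if (length(ids) != nrow(K)) abort("`ids` length must match the matrix order.")
  dimnames(K) <- list(NULL, ids)
  write.table(K, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
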