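## Genotype value vectors.
##
## A biallelic site over n individuals is represented by three binary
## indicator vectors: a (homozygous reference, 0/0), b (heterozygous) and
## c (homozygous alternative, 1/1). They satisfy a + b + c = 1 elementwise,
## and the genotype value (alternative-allele count) is g = b + 2c. A set
## of sites is a tibble of class `gvd_sites` with one row per site and
## list-columns holding the per-individual vectors.

# Map genotype-call strings to alt-allele counts. Returns list(g, missing,
# invalid): g has NA where the call is missing or unrecognized; `missing`
# flags ./., half-calls and "."; `invalid` flags everything else that is
# not a plain biallelic diploid call (e.g. allele index >= 2).
parse_calls <- function(calls) {
  x <- chartr("|", "/", trimws(as.character(calls)))
  g <- rep(NA_integer_, length(x))
  g[x == "0/0"] <- 0L
  g[x == "0/1" | x == "1/0"] <- 1L
  g[x == "1/1"] <- 2L
  missing <- x %in% c("./.", ".", "./0", "0/.", "./1", "1/.")
  list(g = g, missing = missing, invalid = is.na(g) & !missing)
}

#' Genotype value of a biallelic call
#'
#' The genotype value of an individual at a biallelic site is the number of
#' alternative alleles carried: 0 for `0/0`, 1 for a heterozygote, 2 for
#' `1/1`. Both `/` and `|` separators are accepted and `1/0` is treated the
#' same as `0/1`.
#'
#' @param calls Character vector of genotype calls.
#' @return Integer vector of alternative-allele counts.
#' @examples
#' genotype_value(c("0/0", "0/1", "1/1", "1|0"))
#' @export
genotype_value <- function(calls) {
  p <- parse_calls(calls)
  if (any(p$missing | p$invalid)) {
    bad <- which(p$missing | p$invalid)[1L]
    abort(sprintf("invalid genotype call \"%s\" at position %d.", calls[bad], bad))
  }
  p$g
}

new_sites <- function(chrom, pos, rsid, a, b, c, g) {
  n <- if (length(g)) lengths(g) else integer()
  alt <- vapply(g, function(v) sum(v), numeric(1))
  p <- if (length(g)) alt / (2 * n) else numeric()
  out <- tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    rsid = as.character(rsid),
    n = as.integer(n),
    p = p,
    mu = 2 * p,
    a = a, b = b, c = c, g = g
  )
  class(out) <- c("gvd_sites", class(out))
  out
}

empty_sites <- function() {
  new_sites(character(), integer(), character(),
            list(), list(), list(), list())
}

#' Build a genotype site from calls
#'
#' Converts a vector of per-individual genotype calls at one biallelic site
#' into the indicator representation used by all statistics: binary vectors
#' `a` (0/0), `b` (heterozygote), `c` (1/1), the genotype values
#' `g = b + 2c`, the alternative-allele frequency `p` and the mean genotype
#' value `mu = 2p`.
#'
#' @param calls Character vector of genotype calls (`0/0`, `0/1`, `1/0`,
#'   `1/1`; `/` or `|` separators), one per individual, at least 2.
#' @param chrom,pos,rsid Site identifiers (chromosome, 1-based position,
#'   optional rsID).
#' @param missing Policy for missing calls (`./.`, half-calls): `"error"`
#'   (default) aborts naming the site and individual; `"drop_site"` returns
#'   a zero-row site table with a warning; `"ref_impute"` treats missing
#'   calls as `0/0`.
#'
#' @return A one-row (or, under `"drop_site"`, zero-row) tibble of class
#'   `gvd_sites` with columns `chrom`, `pos`, `rsid`, `n`, `p`, `mu` and
#'   list-columns `a`, `b`, `c`, `g`.
#'
#' @examples
#' genotype_site(c("0/0", "0/1", "1/1"), chrom = "11", pos = 64360996)
#' @export
genotype_site <- function(calls, chrom = "1", pos = 1L, rsid = NA_character_,
                          missing = c("error", "drop_site", "ref_impute")) {
  missing <- match.arg(missing)
  if (length(calls) < 2L) {
    abort("a site needs calls for at least 2 individuals.")
  }
  pc <- parse_calls(calls)
  if (any(pc$invalid)) {
    bad <- which(pc$invalid)[1L]
    abort(sprintf(
      "unrecognized (non-biallelic?) call \"%s\" for individual %d at %s:%s.",
      calls[bad], bad, chrom, pos
    ))
  }
  if (any(pc$missing)) {
    if (missing == "error") {
      bad <- which(pc$missing)[1L]
      abort(sprintf(
        "missing genotype for individual %d at %s:%s (policy \"error\").",
        bad, chrom, pos
      ))
    } else if (missing == "drop_site") {
      warn(sprintf("dropping site %s:%s: %d missing genotype(s).",
                   chrom, pos, sum(pc$missing)))
      return(empty_sites())
    } else {
      pc$g[pc$missing] <- 0L
    }
  }
  g <- pc$g
  new_sites(chrom, pos, rsid,
            a = list(as.integer(g == 0L)),
            b = list(as.integer(g == 1L)),
            c = list(as.integer(g == 2L)),
            g = list(g))
}

#' Build a table of genotype sites
#'
#' Vectorized companion of [genotype_site()]: takes an n-by-l matrix of
#' calls (individuals in rows, sites in columns) and returns one `gvd_sites`
#' row per column.
#'
#' @param calls Character matrix, individuals x sites.
#' @param chrom,pos,rsid Per-site identifiers, recycled if length 1.
#' @inheritParams genotype_site
#' @return A `gvd_sites` tibble with one row per retained site.
#' @export
genotype_sites <- function(calls, chrom = "1", pos = seq_len(ncol(calls)),
                           rsid = NA_character_,
                           missing = c("error", "drop_site", "ref_impute")) {
  missing <- match.arg(missing)
  if (!is.matrix(calls)) abort("`calls` must be a matrix (individuals x sites).")
  l <- ncol(calls)
  chrom <- rep_len(as.character(chrom), l)
  pos <- rep_len(pos, l)
  rsid <- rep_len(as.character(rsid), l)
  rows <- purrr::map(seq_len(l), function(k) {
    genotype_site(calls[, k], chrom = chrom[k], pos = pos[k], rsid = rsid[k],
                  missing = missing)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gvd_sites", setdiff(class(out), "gvd_sites"))
  out
}

#' Is a site monomorphic?
#'
#' A site is monomorphic when every individual carries the same allele
#' (alternative-allele frequency 0 or 1). Monomorphic sites carry no
#' association signal and are excluded by the file-reading pipeline.
#'
#' @param sites A `gvd_sites` tibble.
#' @return Logical vector, one value per site.
#' @export
is_monomorphic <- function(sites) {
  check_sites(sites)
  sites$p == 0 | sites$p == 1
}

#' Reconstruct genotype calls from a site
#'
#' Inverse of [genotype_site()]: maps the stored genotype values back to
#' `0/0` / `0/1` / `1/1` strings (heterozygote phase is not recoverable and
#' is emitted as `0/1`).
#'
#' @param site One row of a `gvd_sites` tibble.
#' @return Character vector of calls, one per individual.
#' @export
site_calls <- function(site) {
  check_sites(site)
  if (nrow(site) != 1L) abort("`site` must be a single site (one row).")
  c("0/0", "0/1", "1/1")[site$g[[1L]] + 1L]
}

check_sites <- function(sites, n = NULL) {
  if (!inherits(sites, "gvd_sites") ||
      !all(c("chrom", "pos", "n", "p", "a", "b", "c", "g") %in% names(sites))) {
    abort("`sites` must be a `gvd_sites` tibble (see genotype_site()).")
  }
  if (!is.null(n) && nrow(sites) > 0 && any(sites$n != n)) {
    abort(sprintf(
      "sites have sample size(s) %s but expected %d.",
      paste(unique(sites$n), collapse = ", "), n
    ))
  }
  invisible(sites)
}

#' @export
print.gvd_sites <- function(x, ...) {
  cat(sprintf("<genotype sites: %d site(s), n = %s>\n",
              nrow(x),
              if (nrow(x)) paste(unique(x$n), collapse = "/") else "?"))
  NextMethod()
}
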