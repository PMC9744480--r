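## Synthetic genotype / phenotype generator.
##
## Genotypes are drawn under Hardy-Weinberg equilibrium: at a site with
## alternative-allele frequency p each individual's genotype value is an
## independent Binomial(2, p) draw, i.e. genotype probabilities
## (1-p)^2, 2p(1-p), p^2. Phenotypes follow a carrier-shift model: carriers
## of at least one alternative allele at at least one causal site are
## shifted by a fixed effect (default -1.0 trait units), and independent
## Normal(0, noise_sd) environmental noise (default SD 1.0) is added.

#' Default rare-site frequency profile
#'
#' Seven alternative-allele frequencies spanning the range typical of rare
#' coding variants in a cohort of a few thousand individuals (expected
#' minor-allele counts from ~1 to ~25 at n = 2504). This is the default
#' panel used by the power-study helpers.
#'
#' @return Numeric vector of 7 frequencies.
#' @export
default_site_freqs <- function() {
  c(0.0002, 0.0004, 0.0006, 0.001, 0.002, 0.003, 0.005)
}

#' Simulate genotype sites under Hardy-Weinberg equilibrium
#'
#' Draws, for each requested frequency `p`, `n` independent genotypes with
#' probabilities `(1-p)^2`, `2p(1-p)`, `p^2` for 0/0, 0/1, 1/1. Monomorphic
#' realizations (all individuals identical) carry no signal; by default
#' they are dropped from the returned table (mirroring the exclusion
#' applied to real data), or they can be redrawn.
#'
#' @param n Sample size (>= 2).
#' @param freqs Alternative-allele frequencies, all strictly in (0, 1).
#' @param seed Integer RNG seed; `NULL` uses the current stream.
#' @param monomorphic `"drop"` (default) or `"redraw"`.
#' @param chrom Chromosome label for the synthetic sites.
#' @return A `gvd_sites` tibble (possibly with fewer rows than
#'   `length(freqs)` under the drop policy, and possibly zero rows). The
#'   number of dropped sites is reported via a message and stored in the
#'   `"n_dropped"` attribute.
#' @examples
#' simulate_genotypes(100, c(0.05, 0.2), seed = 1)
#' @export
simulate_genotypes <- function(n, freqs, seed = NULL,
                               monomorphic = c("drop", "redraw"),
                               chrom = "1") {
  monomorphic <- match.arg(monomorphic)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    abort("`n` must be a single integer >= 2.")
  }
  n <- as.integer(n)
  if (!is.numeric(freqs) || length(freqs) == 0L ||
      any(!is.finite(freqs)) || any(freqs <= 0) || any(freqs >= 1)) {
    abort("`freqs` must all lie strictly in (0, 1).")
  }
  sites <- with_seed(seed, {
    rows <- purrr::map(seq_along(freqs), function(k) {
      g <- rbinom(n, 2L, freqs[k])
      if (monomorphic == "redraw") {
        tries <- 0L
        while (length(unique(g)) == 1L) {
          tries <- tries + 1L
          if (tries > 10000L) {
            abort(sprintf(
              "site %d (p = %g) stayed monomorphic after 10000 redraws.",
              k, freqs[k]
            ))
          }
          g <- rbinom(n, 2L, freqs[k])
        }
      }
      new_sites(chrom, k, sprintf("sim%d", k),
                a = list(as.integer(g == 0L)),
                b = list(as.integer(g == 1L)),
                c = list(as.integer(g == 2L)),
                g = list(as.integer(g)))
    })
    dplyr::bind_rows(rows)
  })
  class(sites) <- c("gvd_sites", setdiff(class(sites), "gvd_sites"))
  n_dropped <- 0L
  if (monomorphic == "drop" && nrow(sites) > 0L) {
    mono <- is_monomorphic(sites)
    n_dropped <- sum(mono)
    if (n_dropped > 0L) {
      inform(sprintf("dropped %d monomorphic site(s) of %d.",
                     n_dropped, nrow(sites)))
      sites <- sites[!mono, ]
      class(sites) <- c("gvd_sites", setdiff(class(sites), "gvd_sites"))
    }
  }
  attr(sites, "n_dropped") <- n_dropped
  sites
}

#' Simulate a quantitative phenotype with a carrier shift
#'
#' Generates raw (uncentered) trait values for the individuals of a site
#' panel. Under the default `"carrier"` model an individual's trait is
#' shifted by `carrier_effect` once if they carry at least one alternative
#' allele at at least one causal site (heterozygotes and alternative-allele
#' homozygotes are shifted equally); under the `"additive"` model the
#' shift is applied once per causal site carried. Independent
#' `Normal(0, noise_sd)` environmental noise is added to every individual.
#'
#' Centering is *not* performed here: pass the result through
#' [center_phenotype()] (the file readers and test helpers do this).
#'
#' @param sites A nonempty `gvd_sites` tibble of causal sites.
#' @param carrier_effect Trait shift for carriers, in trait units
#'   (default -1.0). `0` gives a pure-noise null phenotype.
#' @param noise_sd Environmental standard deviation (default 1.0); 0 is
#'   allowed as a noiseless limit.
#' @param seed Integer RNG seed; `NULL` uses the current stream.
#' @param effect_model `"carrier"` (default) or `"additive"`.
#' @return Numeric vector of raw trait values, one per individual.
#' @examples
#' sites <- simulate_genotypes(50, 0.2, seed = 1)
#' y <- center_phenotype(simulate_phenotype(sites, seed = 2))
#' @export
simulate_phenotype <- function(sites, carrier_effect = -1.0, noise_sd = 1.0,
                               seed = NULL,
                               effect_model = c("carrier", "additive")) {
  effect_model <- match.arg(effect_model)
  check_sites(sites)
  if (nrow(sites) == 0L) {
    abort("`sites` is empty: the carrier model needs at least one causal site.")
  }
  stopifnot_scalar_number(carrier_effect, "carrier_effect")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  n <- sites$n[1L]
  G <- site_matrix(sites, "g")
  shift <- switch(effect_model,
    carrier = carrier_effect * as.numeric(rowSums(G > 0) > 0),
    additive = carrier_effect * rowSums(G > 0)
  )
  noise <- with_seed(seed, rnorm(n, mean = 0, sd = noise_sd))
  shift + noise
}

#' Power / type-I-error experiment
#'
#' Repeats the full pipeline — simulate genotypes under Hardy-Weinberg
#' equilibrium, simulate a carrier-shift phenotype, center it, run the
#' permutation test, decide at level `alpha` — and counts rejections.
#' With `carrier_effect = 0` this measures the type-I error; otherwise,
#' power. All randomness is derived from `master_seed`: genotype, phenotype
#' and permutation seeds are drawn from it, so a rerun with the same master
#' seed reproduces the result exactly. By default the genotype panel is
#' simulated once and held fixed across replicates (only the phenotype is
#' redrawn); set `resimulate_genotypes = TRUE` to redraw it each replicate.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_phenotype
#' @param kernel `"GRM"` or `"IBS"`.
#' @param weights A [weight_scheme()].
#' @param B Permutations per test.
#' @param alpha Significance level in (0, 1].
#' @param replicates Number of replicate tests (>= 1).
#' @param master_seed Integer seed governing the whole experiment.
#' @param resimulate_genotypes Redraw the genotype panel each replicate?
#' @return An object of class `gvd_power` with elements `kernel`,
#'   `rejections`, `replicates`, `alpha`, `B`, `n`, `master_seed`,
#'   `p_values` and the simulation parameters. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @examples
#' power_experiment(n = 200, freqs = c(0.05, 0.1), replicates = 3,
#'                  B = 99, alpha = 0.05, master_seed = 1)
#' @export
power_experiment <- function(n = 2504, freqs = default_site_freqs(),
                             carrier_effect = -1.0, noise_sd = 1.0,
                             kernel = c("GRM", "IBS"),
                             weights = weight_scheme("uniform"),
                             B = 999L, alpha = 0.01, replicates = 10L,
                             master_seed = NULL,
                             resimulate_genotypes = FALSE,
                             effect_model = c("carrier", "additive"),
                             monomorphic = c("drop", "redraw")) {
  kernel <- match.arg(kernel)
  effect_model <- match.arg(effect_model)
  monomorphic <- match.arg(monomorphic)
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1) {
    abort("`replicates` must be a single integer >= 1.")
  }
  replicates <- as.integer(replicates)
  if (is.null(master_seed)) master_seed <- draw_seed()

  seeds <- with_seed(master_seed, {
    list(
      genotype = sample.int(2147483646L, replicates),
      phenotype = sample.int(2147483646L, replicates),
      permutation = sample.int(2147483646L, replicates)
    )
  })

  sites <- NULL
  if (!resimulate_genotypes) {
    sites <- simulate_genotypes(n, freqs, seed = seeds$genotype[1L],
                                monomorphic = monomorphic)
    if (nrow(sites) == 0L) {
      abort("all simulated sites were monomorphic; nothing to test.")
    }
  }

  p_values <- vapply(seq_len(replicates), function(r) {
    s <- if (resimulate_genotypes) {
      sim <- simulate_genotypes(n, freqs, seed = seeds$genotype[r],
                                monomorphic = monomorphic)
      if (nrow(sim) == 0L) abort("all simulated sites were monomorphic.")
      sim
    } else {
      sites
    }
    y <- center_phenotype(simulate_phenotype(
      s, carrier_effect = carrier_effect, noise_sd = noise_sd,
      seed = seeds$phenotype[r], effect_model = effect_model
    ))
    permutation_test(y, s, kernel = kernel, weights = weights, B = B,
                     seed = seeds$permutation[r], keep_null = FALSE)$p_value
  }, numeric(1))

  rejections <- sum(p_values <= alpha)
  structure(
    list(kernel = kernel, rejections = rejections, replicates = replicates,
         alpha = alpha, B = as.integer(B), n = as.integer(n),
         master_seed = as.integer(master_seed), p_values = p_values,
         freqs = freqs, carrier_effect = carrier_effect,
         noise_sd = noise_sd, effect_model = effect_model,
         resimulate_genotypes = resimulate_genotypes),
    class = "gvd_power"
  )
}

#' @export
print.gvd_power <- function(x, ...) {
  cat(sprintf(
    "%s kernel power experiment: %d of %d tests reject at alpha = %g\n  (n = %d, B = %d, effect = %g, noise sd = %g, master seed %d)\n",
    x$kernel, x$rejections, x$replicates, x$alpha, x$n, x$B,
    x$carrier_effect, x$noise_sd, x$master_seed
  ))
  invisible(x)
}

#' @rdname power_experiment
#' @param x,object A `gvd_power` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.gvd_power <- function(x, ...) {
  tibble(kernel = x$kernel, rejections = x$rejections,
         replicates = x$replicates, rate = x$rejections / x$replicates,
         alpha = x$alpha, B = x$B, n = x$n,
         carrier_effect = x$carrier_effect, noise_sd = x$noise_sd,
         master_seed = x$master_seed)
}

#' @rdname power_experiment
#' @exportS3Method generics::tidy
#' @export
tidy.gvd_power <- function(x, ...) {
  tibble(replicate = seq_len(x$replicates), p_value = x$p_values,
         reject = x$p_values <= x$alpha)
}

#' @rdname power_experiment
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.gvd_power <- function(object, ...) {
  d <- tidy.gvd_power(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                            boundary = 0, closed = "left") +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed") +
    ggplot2::labs(
      x = "permutation p-value", y = "replicates",
      title = sprintf("%s kernel: %d/%d rejections at alpha = %g",
                      object$kernel, object$rejections, object$replicates,
                      object$alpha)
    ) +
    ggplot2::theme_minimal()
}
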